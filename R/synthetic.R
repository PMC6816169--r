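# Synthetic two-species proteome evolution with known domain-level history.
#
# An ancestral proteome is assembled from a shared alphabet of domain
# families joined by linker regions; each protein may undergo one
# architecture-level event (fusion, fission, duplication, domain loss)
# distinguishing the two descendant species, and every residue then evolves
# by independent substitutions along each lineage. True domain- and
# protein-level orthology is recorded event by event, so the whole pipeline
# can be validated against a known answer.

#' Describe a synthetic evolution scenario
#'
#' @param n_ancestral_domains Size of the ancestral domain-family alphabet.
#' @param domain_length_range Two integers: min/max family length
#'   (residues).
#' @param linker_length_range Two integers: min/max ancestral linker length.
#'   The default straddles the 30-residue UNK threshold so that both
#'   emitted and discarded unannotated regions are exercised.
#' @param n_proteins Number of ancestral proteins (before events).
#' @param p_fusion,p_fission,p_duplication,p_loss Per-protein probabilities
#'   of each architecture event; at most one event per protein, the
#'   remainder evolve by substitution only.
#' @param substitution_rate Expected fraction of residues substituted along
#'   each species lineage (i.i.d. per residue; a substituted residue is
#'   replaced by a uniformly chosen different one, so lengths and
#'   coordinates are exact).
#' @param paralog_divergence Substitution fraction applied to each drawn
#'   domain instance relative to its family consensus at assembly time.
#'   This models the ancestral divergence of paralogous copies of a family,
#'   keeping within-family instances on different proteins distinguishable
#'   from the vertical (orthologous) copies.
#' @param min_unknown_len UNK threshold assumed when recording truth; keep
#'   equal to the analysis config.
#' @param rng_seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `domorth_scenario`.
#' @export
evolution_scenario <- function(n_ancestral_domains = 20,
                               domain_length_range = c(60, 120),
                               linker_length_range = c(15, 60),
                               n_proteins = 30,
                               p_fusion = 0.05, p_fission = 0.05,
                               p_duplication = 0.05, p_loss = 0.05,
                               substitution_rate = 0.1,
                               paralog_divergence = 0.3,
                               min_unknown_len = 30,
                               rng_seed = 1L) {
  sc <- list(n_ancestral_domains = as.integer(n_ancestral_domains),
             domain_length_range = as.integer(domain_length_range),
             linker_length_range = as.integer(linker_length_range),
             n_proteins = as.integer(n_proteins),
             p_fusion = p_fusion, p_fission = p_fission,
             p_duplication = p_duplication, p_loss = p_loss,
             substitution_rate = substitution_rate,
             paralog_divergence = paralog_divergence,
             min_unknown_len = as.integer(min_unknown_len),
             rng_seed = as.integer(rng_seed))
  probs <- c(sc$p_fusion, sc$p_fission, sc$p_duplication, sc$p_loss,
             substitution_rate, paralog_divergence)
  if (any(probs < 0 | probs > 1)) {
    stop("event probabilities and rates must lie in [0, 1]")
  }
  if (sum(probs[1:4]) > 1) stop("event probabilities must sum to at most 1")
  if (sc$n_ancestral_domains < 1 || sc$n_proteins < 1) {
    stop("n_ancestral_domains and n_proteins must be positive")
  }
  if (any(sc$domain_length_range < 1) ||
      diff(sc$domain_length_range) < 0 ||
      any(sc$linker_length_range < 0) ||
      diff(sc$linker_length_range) < 0) {
    stop("length ranges must be positive and ordered")
  }
  class(sc) <- "domorth_scenario"
  sc
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# i.i.d. substitution: each residue is replaced, with probability `rate`,
# by a uniformly chosen different residue.
mutate_sequence <- function(seq, rate) {
  if (rate == 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(AA_ALPHABET20, ch), 1)
    }, "")
  }
  paste(chars, collapse = "")
}

#' Generate two synthetic proteomes with ground-truth orthology
#'
#' Runs the evolutionary process described in [evolution_scenario()] and
#' returns proteomes, PfamScan-style annotations and the true orthology.
#' Ground-truth domain pairs are recorded for annotated domain instances
#' (linker-derived UNK regions also descend from common ancestors but are
#' deliberately kept out of the truth bookkeeping: short, fast-evolving
#' linkers are not reliably identifiable targets). A fused protein is a true
#' discordant primary with one partner per ancestral architecture; a
#' fissioned ancestor makes the intact partner the discordant primary.
#'
#' @param scenario An [evolution_scenario()].
#' @return A list: `proteome_a`, `proteome_b` (protein tables as
#'   [read_fasta()]), `annotations_a`, `annotations_b` (annotation tables as
#'   [read_pfamscan()]), and `truth`, itself a list of `true_domain_pairs`
#'   (`domain_a`, `domain_b` extraction-scheme ids), `true_protein_pairs`
#'   (`protein_a`, `protein_b`), `true_discordant_primaries` (character),
#'   and `events` (per-ancestral-protein event table).
#' @export
synthesize_proteomes <- function(scenario = evolution_scenario()) {
  stopifnot(inherits(scenario, "domorth_scenario"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(scenario$rng_seed)

  n_fam <- scenario$n_ancestral_domains
  fam_ids <- sprintf("DOM%02d", seq_len(n_fam))
  fam_len <- resample(seq(scenario$domain_length_range[1],
                          scenario$domain_length_range[2]),
                      n_fam, replace = TRUE)
  fam_seq <- vapply(fam_len, random_aa, "")

  n <- scenario$n_proteins
  rand_linker <- function() {
    random_aa(resample(seq(scenario$linker_length_range[1],
                           scenario$linker_length_range[2])))
  }
  # ancestral architectures: 1-3 distinct families per protein, with a
  # linker before, between and after the domains
  arch <- vector("list", n)
  for (i in seq_len(n)) {
    k <- resample(1:3)
    fams <- resample(seq_len(n_fam), min(k, n_fam))
    domains <- lapply(seq_along(fams), function(j) {
      list(instance_id = sprintf("P%03d.d%d", i, j),
           family = fam_ids[fams[j]],
           seq = mutate_sequence(fam_seq[fams[j]],
                                 scenario$paralog_divergence))
    })
    linkers <- replicate(length(fams) + 1, rand_linker())
    arch[[i]] <- list(domains = domains, linkers = linkers)
  }

  events <- sample(c("fusion", "fission", "duplication", "loss", "none"), n,
                   replace = TRUE,
                   prob = c(scenario$p_fusion, scenario$p_fission,
                            scenario$p_duplication, scenario$p_loss,
                            1 - scenario$p_fusion - scenario$p_fission -
                              scenario$p_duplication - scenario$p_loss))
  if (scenario$p_fission > 0 &&
      !any(vapply(arch, function(a) length(a$domains) >= 2, TRUE))) {
    stop("fission requested but every architecture has a single domain")
  }
  # fission and loss need at least two domains
  k_of <- vapply(arch, function(a) length(a$domains), 1L)
  events[events %in% c("fission", "loss") & k_of < 2] <- "none"
  # pair each fusion with the next unconsumed event-free protein
  fused_with <- rep(NA_integer_, n)
  consumed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (events[i] != "fusion" || consumed[i]) next
    j <- which(events == "none" & !consumed & seq_len(n) > i)[1]
    if (is.na(j)) {
      events[i] <- "none"
    } else {
      fused_with[i] <- j
      consumed[j] <- TRUE
      events[j] <- "fused_partner"
    }
  }

  # species protein specifications: list of elements, each either
  # list(kind = "domain", instance_id, family, seq) or
  # list(kind = "linker", seq)
  elements_of <- function(a) {
    out <- list(list(kind = "linker", seq = a$linkers[1]))
    for (j in seq_along(a$domains)) {
      d <- a$domains[[j]]
      out <- c(out, list(list(kind = "domain", instance_id = d$instance_id,
                              family = d$family, seq = d$seq)),
               list(list(kind = "linker", seq = a$linkers[j + 1])))
    }
    out
  }
  merge_linkers <- function(elems) {
    # concatenate adjacent linkers, drop empty ones
    out <- list()
    for (e in elems) {
      last <- if (length(out) > 0) out[[length(out)]] else NULL
      if (e$kind == "linker" && !is.null(last) && last$kind == "linker") {
        out[[length(out)]]$seq <- paste0(last$seq, e$seq)
      } else {
        out <- c(out, list(e))
      }
    }
    Filter(function(e) e$kind != "linker" || nchar(e$seq) > 0, out)
  }

  specs_a <- list(); specs_b <- list()
  ancestors_of <- list()  # species protein id -> ancestral protein indices
  add_spec <- function(side, id, elems, anc) {
    spec <- list(id = id, elements = merge_linkers(elems))
    if (side == "a") specs_a[[length(specs_a) + 1]] <<- spec
    else specs_b[[length(specs_b) + 1]] <<- spec
    ancestors_of[[id]] <<- anc
  }
  for (i in seq_len(n)) {
    ev <- events[i]
    base_a <- sprintf("A_P%03d", i)
    base_b <- sprintf("B_P%03d", i)
    if (ev == "fused_partner") {
      # species A copy lives inside the fusion product; B copy is intact
      add_spec("b", base_b, elements_of(arch[[i]]), i)
      next
    }
    if (ev == "fusion") {
      j <- fused_with[i]
      add_spec("a", sprintf("A_P%03dx%03d", i, j),
               c(elements_of(arch[[i]]), elements_of(arch[[j]])), c(i, j))
      add_spec("b", base_b, elements_of(arch[[i]]), i)
    } else if (ev == "fission") {
      k <- length(arch[[i]]$domains)
      b_at <- resample(seq_len(k - 1))
      el <- elements_of(arch[[i]])
      # element index of domain j is 2j (linkers interleave)
      first <- el[seq_len(2 * b_at + 1)]
      second <- el[seq(2 * b_at + 2, length(el))]
      add_spec("a", paste0(base_a, "a"), first, i)
      add_spec("a", paste0(base_a, "b"), second, i)
      add_spec("b", base_b, elements_of(arch[[i]]), i)
    } else if (ev == "duplication") {
      add_spec("a", base_a, elements_of(arch[[i]]), i)
      add_spec("b", paste0(base_b, "a"), elements_of(arch[[i]]), i)
      add_spec("b", paste0(base_b, "b"), elements_of(arch[[i]]), i)
    } else if (ev == "loss") {
      drop_j <- resample(seq_along(arch[[i]]$domains))
      el <- elements_of(arch[[i]])
      add_spec("a", base_a, el[-(2 * drop_j)], i)
      add_spec("b", base_b, elements_of(arch[[i]]), i)
    } else {
      add_spec("a", base_a, elements_of(arch[[i]]), i)
      add_spec("b", base_b, elements_of(arch[[i]]), i)
    }
  }

  # realise one species copy: mutate every element, lay out coordinates
  realise <- function(spec, species) {
    pos <- 0L
    seq_parts <- character(0)
    ann <- list(); placed <- list()
    for (e in spec$elements) {
      s <- mutate_sequence(e$seq, scenario$substitution_rate)
      start <- pos + 1L
      pos <- pos + nchar(s)
      seq_parts <- c(seq_parts, s)
      if (e$kind == "domain") {
        ann[[length(ann) + 1]] <-
          data.frame(protein_id = spec$id, start = start, end = pos,
                     name = e$family, family_type = "Domain",
                     source = "synthetic", stringsAsFactors = FALSE)
        placed[[length(placed) + 1]] <-
          data.frame(instance_id = e$instance_id,
                     cut_id = domain_seq_id(spec$id, e$family, start, pos),
                     protein_id = spec$id, stringsAsFactors = FALSE)
      }
    }
    list(protein = data.frame(id = spec$id, species = species,
                              sequence = paste(seq_parts, collapse = ""),
                              length = pos, stringsAsFactors = FALSE),
         annotations = do.call(rbind, ann),
         placed = do.call(rbind, placed))
  }

  side <- function(specs, species) {
    real <- lapply(specs, realise, species = species)
    list(proteome = do.call(rbind, lapply(real, `[[`, "protein")),
         annotations = do.call(rbind, lapply(real, `[[`, "annotations")),
         placed = do.call(rbind, lapply(real, `[[`, "placed")))
  }
  a <- side(specs_a, "spA")
  b <- side(specs_b, "spB")

  # truth: every A/B placement pair of the same ancestral domain instance
  placed_a <- split(a$placed, a$placed$instance_id)
  placed_b <- split(b$placed, b$placed$instance_id)
  tdp <- list()
  for (inst in intersect(names(placed_a), names(placed_b))) {
    grid <- expand.grid(domain_a = placed_a[[inst]]$cut_id,
                        domain_b = placed_b[[inst]]$cut_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tdp[[length(tdp) + 1]] <- grid
  }
  true_domain_pairs <- do.call(rbind, tdp) %||%
    empty_df(domain_a = character(0), domain_b = character(0))
  true_domain_pairs <- canonical_pairs(true_domain_pairs,
                                       "domain_a", "domain_b")

  # protein pairs: cross-species proteins sharing an ancestral protein
  tpp <- list()
  for (pa in a$proteome$id) {
    for (pb in b$proteome$id) {
      if (length(intersect(ancestors_of[[pa]], ancestors_of[[pb]])) > 0) {
        tpp[[length(tpp) + 1]] <- data.frame(protein_a = pa, protein_b = pb,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  true_protein_pairs <- do.call(rbind, tpp) %||%
    empty_df(protein_a = character(0), protein_b = character(0))
  true_protein_pairs <- canonical_pairs(true_protein_pairs,
                                        "protein_a", "protein_b")

  prim <- character(0)
  for (i in seq_len(n)) {
    if (events[i] == "fusion") {
      prim <- c(prim, sprintf("A_P%03dx%03d", i, fused_with[i]))
    } else if (events[i] == "fission") {
      prim <- c(prim, sprintf("B_P%03d", i))
    }
  }

  event_table <- data.frame(ancestral_protein = seq_len(n), event = events,
                            fused_with = fused_with,
                            stringsAsFactors = FALSE)
  list(proteome_a = a$proteome, proteome_b = b$proteome,
       annotations_a = a$annotations, annotations_b = b$annotations,
       truth = list(true_domain_pairs = true_domain_pairs,
                    true_protein_pairs = true_protein_pairs,
                    true_discordant_primaries = sort(prim),
                    events = event_table),
       scenario = scenario)
}

#' Precision and recall of inferred pairs against ground truth
#'
#' Both arguments are sets of unordered id pairs (data.frames whose first
#' two columns hold the ids). Precision is defined as 1.0 when nothing was
#' inferred; an empty truth set is an error.
#'
#' @param inferred_pairs,truth_pairs Two-column (or wider) data.frames.
#' @return Named numeric vector `c(precision = ..., recall = ...)`.
#' @export
score_recovery <- function(inferred_pairs, truth_pairs) {
  tk <- unique(pair_key(as.character(truth_pairs[[1]]),
                        as.character(truth_pairs[[2]])))
  if (length(tk) == 0) stop("truth pair set is empty")
  ik <- unique(pair_key(as.character(inferred_pairs[[1]]),
                        as.character(inferred_pairs[[2]])))
  tp <- length(intersect(ik, tk))
  c(precision = if (length(ik) == 0) 1.0 else tp / length(ik),
    recall = tp / length(tk))
}
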