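# Projection of domain-level ortholog groups onto proteins: the alpha
# statistic, discordant domain orthology, merging with full-length calls,
# and consensus statistics against a full-length method.

# id -> protein and group lookup tables used by several operations
domain_group_index <- function(groups, domain_map) {
  prot <- stats::setNames(domain_map$protein_id, domain_map$id)
  sp <- stats::setNames(domain_map$species, domain_map$id)
  gid <- stats::setNames(groups$group_id, groups$member_id)
  list(prot = prot, sp = sp, gid = gid)
}

#' Alpha statistic for one protein pair
#'
#' The alpha value of a cross-species protein pair is the fraction of the
#' pair's domain-equivalent instances that are orthologous between the two
#' proteins: an instance counts as shared when its ortholog group also
#' contains at least one instance from the partner protein; the denominator
#' counts every domain-equivalent instance on both proteins, including UNK
#' regions and orphan sequences, grouped or not.
#'
#' @param protein_a,protein_b Protein ids (from different species).
#' @param domain_map Domain-sequence table for both species
#'   ([extract_proteome()] output, `domain_seqs`).
#' @param groups Disjoint group table ([infer_ortholog_groups()] output).
#' @return One-row data.frame: `protein_a`, `protein_b`, `n_shared`,
#'   `n_total`, `alpha`, `supporting_groups` (comma-joined shared group
#'   ids).
#' @export
#' @examples
#' # a three-domain protein X {A,B,C} and a two-domain protein Y {A,C} whose
#' # A and C instances are co-grouped share 4 of their 5 instances:
#' dm <- data.frame(id = c("X/A", "X/B", "X/C", "Y/A", "Y/C"),
#'                  protein_id = c("X", "X", "X", "Y", "Y"),
#'                  species = c("hs", "hs", "hs", "ec", "ec"))
#' gr <- data.frame(group_id = c(1L, 1L, 2L, 2L),
#'                  member_id = c("X/A", "Y/A", "X/C", "Y/C"))
#' compute_alpha("X", "Y", dm, gr)  # n_shared 4, n_total 5, alpha 0.8
compute_alpha <- function(protein_a, protein_b, domain_map, groups) {
  dom_a <- domain_map$id[domain_map$protein_id == protein_a]
  dom_b <- domain_map$id[domain_map$protein_id == protein_b]
  if (length(dom_a) == 0 || length(dom_b) == 0) {
    stop(sprintf("protein %s has no domain-equivalent sequences",
                 if (length(dom_a) == 0) protein_a else protein_b))
  }
  gid <- stats::setNames(groups$group_id, groups$member_id)
  g_a <- gid[dom_a]; g_b <- gid[dom_b]
  shared_groups <- sort(unique(stats::na.omit(intersect(g_a, g_b))))
  n_shared <- sum(g_a %in% shared_groups) + sum(g_b %in% shared_groups)
  n_total <- length(dom_a) + length(dom_b)
  data.frame(protein_a = protein_a, protein_b = protein_b,
             n_shared = as.integer(n_shared), n_total = as.integer(n_total),
             alpha = n_shared / n_total,
             supporting_groups = paste(shared_groups, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Project ortholog groups onto protein-level ortholog pairs
#'
#' Candidate pairs are cross-species protein pairs sharing at least one
#' ortholog group; pairs whose alpha reaches the threshold are reported.
#'
#' @param groups Disjoint group table.
#' @param domain_map Domain-sequence table for both species.
#' @param alpha_threshold Minimum alpha in `[0, 1]` (default 0.3).
#' @return Data.frame of pairs (columns as [compute_alpha()]), sorted by
#'   `protein_a`, `protein_b`; `protein_a` is the lexicographically smaller
#'   id.
#' @export
project_protein_pairs <- function(groups, domain_map, alpha_threshold = 0.3) {
  if (is.na(alpha_threshold) || alpha_threshold < 0 || alpha_threshold > 1) {
    stop("alpha_threshold must lie in [0, 1]")
  }
  empty <- empty_df(protein_a = character(0), protein_b = character(0),
                    n_shared = integer(0), n_total = integer(0),
                    alpha = numeric(0), supporting_groups = character(0))
  if (nrow(groups) == 0) return(empty)
  idx <- domain_group_index(groups, domain_map)
  cand <- lapply(split(groups, groups$group_id), function(g) {
    species <- sort(unique(g$species))
    pa <- unique(idx$prot[g$member_id[g$species == species[1]]])
    pb <- unique(idx$prot[g$member_id[g$species == species[2]]])
    expand.grid(p = pa, q = pb, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  })
  cand <- unique(do.call(rbind, cand))
  if (nrow(cand) == 0) return(empty)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    compute_alpha(cand$p[i], cand$q[i], domain_map, groups)
  })
  out <- do.call(rbind, rows)
  out <- out[out$alpha >= alpha_threshold, , drop = FALSE]
  canonical_pairs(out, "protein_a", "protein_b")
}

#' Detect discordant domain orthology
#'
#' A primary protein is one whose domains are orthologous to domains on
#' more than one distinct partner protein in the other species. Each record
#' lists the partners and the subset of the primary's domains each partner
#' matches. Under the default `strict` mode the record is flagged
#' discordant when at least two partners hold mutually exclusive (disjoint)
#' subsets -- the signature of gene fusion/fission or domain shuffling; the
#' `weak` mode flags any two partners with differing subsets.
#'
#' @param groups Disjoint group table.
#' @param domain_map Domain-sequence table for both species.
#' @param mode `"strict"` (disjoint subsets, default) or `"weak"`
#'   (different subsets).
#' @return Data.frame with one row per (primary, secondary): `primary`,
#'   `secondary`, `primary_domains` (comma-joined domain ids of the primary
#'   matched by this secondary), `n_secondaries`, `is_discordant`
#'   (per-primary flag), sorted by `primary`, `secondary`.
#' @export
find_discordant <- function(groups, domain_map, mode = c("strict", "weak")) {
  mode <- match.arg(mode)
  empty <- empty_df(primary = character(0), secondary = character(0),
                    primary_domains = character(0),
                    n_secondaries = integer(0), is_discordant = logical(0))
  if (nrow(groups) == 0) return(empty)
  idx <- domain_group_index(groups, domain_map)
  pairs <- groups_to_domain_pairs(groups)
  if (nrow(pairs) == 0) return(empty)
  # directed view: every domain pair seen from each side
  directed <- rbind(
    data.frame(p_dom = pairs$domain_a, s_dom = pairs$domain_b,
               stringsAsFactors = FALSE),
    data.frame(p_dom = pairs$domain_b, s_dom = pairs$domain_a,
               stringsAsFactors = FALSE))
  directed$primary <- unname(idx$prot[directed$p_dom])
  directed$secondary <- unname(idx$prot[directed$s_dom])

  out <- lapply(split(directed, directed$primary), function(d) {
    partners <- split(d$p_dom, d$secondary)
    if (length(partners) < 2) return(NULL)
    partners <- lapply(partners, function(x) sort(unique(x)))
    flag <- FALSE
    np <- length(partners)
    for (i in seq_len(np - 1)) {
      for (j in seq(i + 1, np)) {
        if (mode == "strict") {
          if (length(intersect(partners[[i]], partners[[j]])) == 0) flag <- TRUE
        } else {
          if (!setequal(partners[[i]], partners[[j]])) flag <- TRUE
        }
      }
    }
    data.frame(primary = d$primary[1], secondary = names(partners),
               primary_domains = vapply(partners, paste, "", collapse = ","),
               n_secondaries = np, is_discordant = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$primary, out$secondary), , drop = FALSE]
  rownames(out) <- NULL
  out
}

fulllength_pairs_from_groups <- function(fulllength_groups) {
  out <- lapply(split(fulllength_groups, fulllength_groups$group_id),
                function(g) {
    species <- sort(unique(g$species))
    if (length(species) < 2) return(NULL)
    a <- unique(g$member_id[g$species == species[1]])
    b <- unique(g$member_id[g$species == species[2]])
    expand.grid(protein_a = a, protein_b = b, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    return(empty_df(protein_a = character(0), protein_b = character(0)))
  }
  canonical_pairs(out, "protein_a", "protein_b")
}

# assignment of each protein id to its full-length group(s)
fulllength_assignment <- function(fulllength_groups) {
  split(fulllength_groups$group_id, fulllength_groups$member_id)
}

#' Merge domain-based pairs with a full-length ortholog set
#'
#' All full-length co-membership pairs enter the merged set; domain-based
#' pairs are added when they are not in conflict with the full-length
#' assignment. A conflict means both proteins were assigned to full-length
#' groups but never to a common one -- in that case only the full-length
#' pairs are kept, as full-length inferences are the benchmark-validated
#' reference.
#'
#' @param domain_pairs Protein-pair data.frame (e.g.
#'   [project_protein_pairs()] at the merge alpha threshold).
#' @param fulllength_groups Full-length group table (`group_id`,
#'   `member_id`, `species`).
#' @return Data.frame `protein_a`, `protein_b`, `origin` with origin one of
#'   `both`, `fulllength_only`, `domain_only`; always a superset of the
#'   full-length pair set.
#' @export
merge_with_fulllength <- function(domain_pairs, fulllength_groups) {
  fl <- fulllength_pairs_from_groups(fulllength_groups)
  dp <- canonical_pairs(domain_pairs[, c("protein_a", "protein_b"),
                                     drop = FALSE],
                        "protein_a", "protein_b")
  fl_keys <- pair_key(fl$protein_a, fl$protein_b)
  dp_keys <- pair_key(dp$protein_a, dp$protein_b)
  assign_map <- fulllength_assignment(fulllength_groups)

  fl$origin <- ifelse(fl_keys %in% dp_keys, "both", "fulllength_only")
  add <- dp[!(dp_keys %in% fl_keys), , drop = FALSE]
  if (nrow(add) > 0) {
    conflicting <- vapply(seq_len(nrow(add)), function(i) {
      ga <- assign_map[[add$protein_a[i]]]
      gb <- assign_map[[add$protein_b[i]]]
      !is.null(ga) && !is.null(gb) && length(intersect(ga, gb)) == 0
    }, TRUE)
    add <- add[!conflicting, , drop = FALSE]
    if (nrow(add) > 0) add$origin <- "domain_only"
  }
  out <- rbind(fl, if (nrow(add) > 0) add else NULL)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify protein pairs against a full-length method
#'
#' Every pair found by either approach is assigned exactly one category:
#' `both` (found by both), `fulllength_only`, or for domain-only pairs a
#' subdivision by how the pair maps onto the full-length assignment --
#' `domain_conflicting` (both proteins assigned, to groups that never place
#' them together), `domain_one_missing` (exactly one protein unassigned),
#' `domain_two_missing` (neither protein assigned).
#'
#' @inheritParams merge_with_fulllength
#' @return Data.frame `protein_a`, `protein_b`, `category`; the categories
#'   partition the union of the two pair sets.
#' @export
classify_pairs <- function(domain_pairs, fulllength_groups) {
  fl <- fulllength_pairs_from_groups(fulllength_groups)
  dp <- canonical_pairs(domain_pairs[, c("protein_a", "protein_b"),
                                     drop = FALSE],
                        "protein_a", "protein_b")
  fl_keys <- pair_key(fl$protein_a, fl$protein_b)
  dp_keys <- pair_key(dp$protein_a, dp$protein_b)
  assign_map <- fulllength_assignment(fulllength_groups)

  fl$category <- ifelse(fl_keys %in% dp_keys, "both", "fulllength_only")
  only_d <- dp[!(dp_keys %in% fl_keys), , drop = FALSE]
  if (nrow(only_d) > 0) {
    only_d$category <- vapply(seq_len(nrow(only_d)), function(i) {
      a_in <- !is.null(assign_map[[only_d$protein_a[i]]])
      b_in <- !is.null(assign_map[[only_d$protein_b[i]]])
      if (a_in && b_in) "domain_conflicting"
      else if (a_in || b_in) "domain_one_missing"
      else "domain_two_missing"
    }, "")
  }
  out <- rbind(fl, if (nrow(only_d) > 0) only_d else NULL)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard index of two protein-pair sets
#'
#' Intersection over union of two sets of unordered protein-id pairs.
#'
#' @param pairs_a,pairs_b Data.frames with columns `protein_a`,
#'   `protein_b`.
#' @return A fraction in `[0, 1]`. Two empty sets are an error.
#' @export
jaccard_consensus <- function(pairs_a, pairs_b) {
  ka <- unique(pair_key(as.character(pairs_a$protein_a),
                        as.character(pairs_a$protein_b)))
  kb <- unique(pair_key(as.character(pairs_b$protein_a),
                        as.character(pairs_b$protein_b)))
  if (length(ka) == 0 && length(kb) == 0) {
    stop("Jaccard index is undefined for two empty pair sets")
  }
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Sweep the alpha threshold against a full-length pair set
#'
#' Re-projects protein pairs at each threshold and tabulates agreement with
#' the full-length method: counts of pairs found by both, by the
#' domain-based projection only, by the full-length method only, and the
#' Jaccard index.
#'
#' @param groups Disjoint group table.
#' @param domain_map Domain-sequence table for both species.
#' @param fulllength_groups Full-length group table.
#' @param thresholds Sorted vector of alpha thresholds in `[0, 1]`
#'   (default the eleven values 0.0, 0.1, ..., 1.0).
#' @return Data.frame with one row per threshold: `threshold`,
#'   `n_domain_pairs`, `n_fulllength_pairs`, `n_both`, `n_domain_only`,
#'   `n_fulllength_only`, `jaccard`. The domain-based pair count is
#'   non-increasing in the threshold.
#' @export
alpha_sweep <- function(groups, domain_map, fulllength_groups,
                        thresholds = seq(0, 1, by = 0.1)) {
  if (is.unsorted(thresholds) || any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must be sorted and lie in [0, 1]")
  }
  fl <- fulllength_pairs_from_groups(fulllength_groups)
  fl_keys <- pair_key(fl$protein_a, fl$protein_b)
  all_pairs <- project_protein_pairs(groups, domain_map, alpha_threshold = 0)
  rows <- lapply(thresholds, function(th) {
    dp <- all_pairs[all_pairs$alpha >= th, , drop = FALSE]
    dp_keys <- pair_key(dp$protein_a, dp$protein_b)
    n_both <- length(intersect(dp_keys, fl_keys))
    jac <- if (length(dp_keys) == 0 && length(fl_keys) == 0) NA_real_ else
      n_both / length(union(dp_keys, fl_keys))
    data.frame(threshold = th,
               n_domain_pairs = length(dp_keys),
               n_fulllength_pairs = length(fl_keys),
               n_both = n_both,
               n_domain_only = length(dp_keys) - n_both,
               n_fulllength_only = length(fl_keys) - n_both,
               jaccard = jac)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
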