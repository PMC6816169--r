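# Independent oracles, written before the implementations they check and
# kept deliberately naive: quadratic Gotoh DP for local alignment, residue
# marking for coverage, and a matrix-based re-implementation of the
# seed/recruitment/conflict clustering rules.

# Smith-Waterman raw score with affine gaps (a gap of length L costs
# open + L * ext), straightforward O(nm) Gotoh recurrences.
sw_oracle_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      diag_s <- H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, diag_s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# per-residue marking oracle for the union coverage of segments
coverage_oracle <- function(starts, ends, len) {
  hit <- rep(FALSE, len)
  for (k in seq_along(starts)) hit[starts[k]:ends[k]] <- TRUE
  sum(hit) / len
}

# ---- brute-force clustering oracle -----------------------------------------
# Inputs are score matrices: `cross` (rows = species A ids, cols = species B
# ids) and symmetric `wa`, `wb` within-species matrices; NA means no hit.
# Returns a canonical string encoding of the final groups.

oracle_seeds <- function(cross) {
  seeds <- list()
  for (a in rownames(cross)) {
    sa <- stats::setNames(cross[a, ], colnames(cross))
    if (all(is.na(sa))) next
    best <- max(sa, na.rm = TRUE)
    b <- sort(names(sa)[!is.na(sa) & sa == best])[1]  # tie: smallest id
    sb <- stats::setNames(cross[, b], rownames(cross))
    bestb <- max(sb, na.rm = TRUE)
    aa <- sort(names(sb)[!is.na(sb) & sb == bestb])[1]
    if (aa == a) seeds[[length(seeds) + 1]] <- list(a = a, b = b, s = best)
  }
  seeds
}

oracle_recruit <- function(seed, wa, wb) {
  mem_a <- seed$a
  for (x in setdiff(rownames(wa), seed$a)) {
    s <- wa[x, seed$a]
    if (!is.na(s) && s >= seed$s) mem_a <- c(mem_a, x)
  }
  mem_b <- seed$b
  for (y in setdiff(rownames(wb), seed$b)) {
    s <- wb[y, seed$b]
    if (!is.na(s) && s >= seed$s) mem_b <- c(mem_b, y)
  }
  list(a = sort(mem_a), b = sort(mem_b), seed = seed)
}

oracle_groups <- function(cross, wa, wb) {
  seeds <- oracle_seeds(cross)
  groups <- lapply(seeds, oracle_recruit, wa = wa, wb = wb)
  if (length(groups) == 0) return(character(0))
  rank_key <- vapply(groups, function(g)
    sprintf("%020.6f|%s", 1e9 - g$seed$s,
            paste(sort(c(g$seed$a, g$seed$b)), collapse = "\t")), "")
  groups <- groups[order(rank_key)]
  taken <- character(0)
  out <- character(0)
  for (g in groups) {
    a <- setdiff(g$a, taken)
    b <- setdiff(g$b, taken)
    if (length(a) == 0 || length(b) == 0) next  # deleted, claims nothing
    taken <- c(taken, a, b)
    out <- c(out, paste(sort(c(a, b)), collapse = ","))
  }
  sort(out)
}

# Random score-matrix scenario; discrete scores force frequent ties.
random_score_scenario <- function(seed, max_n = 8) {
  set.seed(seed)
  na <- sample(1:max_n, 1); nb <- sample(1:max_n, 1)
  ids_a <- sprintf("a%02d", seq_len(na))
  ids_b <- sprintf("b%02d", seq_len(nb))
  rand_mat <- function(rows, cols, symmetric = FALSE) {
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    for (i in seq_along(rows)) {
      for (j in seq_along(cols)) {
        if (symmetric && j <= i) next
        if (stats::runif(1) < 0.7) {
          m[i, j] <- sample(seq(40, 100, by = 5), 1)
        }
      }
    }
    if (symmetric) {
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- NA
    }
    m
  }
  list(cross = rand_mat(ids_a, ids_b),
       wa = rand_mat(ids_a, ids_a, symmetric = TRUE),
       wb = rand_mat(ids_b, ids_b, symmetric = TRUE),
       ids_a = ids_a, ids_b = ids_b)
}

# Convert a score-matrix scenario to the filtered pair-level hit tables and
# domain map that infer_ortholog_groups() consumes.
scenario_to_hits <- function(sc, shuffle_seed = NULL) {
  mat_to_hits <- function(m) {
    idx <- which(!is.na(m), arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(data.frame(query_id = character(0), subject_id = character(0),
                        bitscore = numeric(0), stringsAsFactors = FALSE))
    }
    data.frame(query_id = rownames(m)[idx[, 1]],
               subject_id = colnames(m)[idx[, 2]],
               bitscore = m[idx], stringsAsFactors = FALSE)
  }
  cross <- mat_to_hits(sc$cross)
  within <- rbind(mat_to_hits(sc$wa), mat_to_hits(sc$wb))
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    cross <- cross[sample(nrow(cross)), , drop = FALSE]
    within <- within[sample(nrow(within)), , drop = FALSE]
  }
  dm <- data.frame(id = c(sc$ids_a, sc$ids_b),
                   protein_id = c(sc$ids_a, sc$ids_b),
                   species = rep(c("spA", "spB"),
                                 c(length(sc$ids_a), length(sc$ids_b))),
                   stringsAsFactors = FALSE)
  list(cross = cross, within = within, domain_map = dm)
}

# canonical encoding of implementation groups, comparable to oracle_groups()
groups_to_canonical <- function(groups) {
  if (nrow(groups) == 0) return(character(0))
  sort(unname(vapply(split(groups$member_id, groups$group_id),
                     function(m) paste(sort(m), collapse = ","), "")))
}
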