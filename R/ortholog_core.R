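# InParanoid-style clustering of domain sequences: reciprocal best hits
# seed ortholog groups, within-species sequences scoring at least the seed
# score are recruited as inparalogs, and overlapping groups are resolved in
# favour of the stronger seed.

# Collapse directional/segment-level filtered hits into a symmetric
# pair-score lookup: unordered pair key -> max bitscore over orientations.
pair_score_map <- function(hits) {
  if (nrow(hits) == 0) return(new.env(parent = emptyenv()))
  keys <- pair_key(hits$query_id, hits$subject_id)
  agg <- tapply(hits$bitscore, keys, max)
  env <- new.env(parent = emptyenv())
  for (k in names(agg)) assign(k, unname(agg[[k]]), envir = env)
  env
}

get_pair_score <- function(env, a, b) {
  k <- pair_key(a, b)
  if (exists(k, envir = env, inherits = FALSE)) {
    get(k, envir = env, inherits = FALSE)
  } else {
    NA_real_
  }
}

#' Find seed ortholog pairs (reciprocal best hits)
#'
#' A cross-species pair (a, b) is a seed ortholog iff b is a's best-scoring
#' partner and a is b's. Scores are symmetrised over hit orientation by
#' taking the maximum; best-partner ties are broken towards the
#' lexicographically smallest partner id, making the result deterministic.
#'
#' @param cross_hits Filtered cross-species hits ([apply_hit_filters()]
#'   output; only `query_id`, `subject_id`, `bitscore` are used).
#' @param domain_map Domain-sequence table giving each id's `species`.
#' @return Data.frame with columns `member_a`, `member_b`, `score`, one row
#'   per seed pair, sorted by `member_a`. `member_a` carries the species tag
#'   that sorts first.
#' @export
find_seed_orthologs <- function(cross_hits, domain_map) {
  if (nrow(cross_hits) == 0) {
    return(empty_df(member_a = character(0), member_b = character(0),
                    score = numeric(0)))
  }
  sp <- stats::setNames(domain_map$species, domain_map$id)
  ids <- unique(c(cross_hits$query_id, cross_hits$subject_id))
  if (anyNA(sp[ids])) {
    stop(sprintf("hit id(s) missing from domain map: %s",
                 paste(utils::head(ids[is.na(sp[ids])], 5), collapse = ", ")))
  }
  species <- sort(unique(sp[ids]))
  if (length(species) != 2) {
    stop("cross hits must involve exactly two species")
  }
  env <- pair_score_map(cross_hits)
  # symmetric edge list, one row per unordered pair
  u <- unique(data.frame(a = pmin(cross_hits$query_id, cross_hits$subject_id),
                         b = pmax(cross_hits$query_id, cross_hits$subject_id),
                         stringsAsFactors = FALSE))
  u$score <- mapply(get_pair_score, a = u$a, b = u$b,
                    MoreArgs = list(env = env))
  drop_self_species <- sp[u$a] != sp[u$b]
  u <- u[drop_self_species, , drop = FALSE]
  if (nrow(u) == 0) {
    return(empty_df(member_a = character(0), member_b = character(0),
                    score = numeric(0)))
  }
  edges <- rbind(data.frame(from = u$a, to = u$b, score = u$score,
                            stringsAsFactors = FALSE),
                 data.frame(from = u$b, to = u$a, score = u$score,
                            stringsAsFactors = FALSE))
  best_partner <- vapply(split(edges, edges$from), function(e) {
    e <- e[order(-e$score, e$to), , drop = FALSE]
    e$to[1]
  }, "")
  seeds <- u[best_partner[u$a] == u$b & best_partner[u$b] == u$a, ,
             drop = FALSE]
  # orient: member_a belongs to the first species in sort order
  swap <- sp[seeds$a] != species[1]
  out <- data.frame(member_a = ifelse(swap, seeds$b, seeds$a),
                    member_b = ifelse(swap, seeds$a, seeds$b),
                    score = seeds$score, stringsAsFactors = FALSE)
  out <- out[order(out$member_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recruit inparalogs around one seed ortholog pair
#'
#' A within-species sequence joins the group of a seed member from its own
#' species iff its bitscore with that seed member does not fall below the
#' seed pair's score (inclusive boundary: a score exactly equal to the seed
#' score recruits).
#'
#' @param seed One-row data.frame from [find_seed_orthologs()].
#' @param within_hits Filtered within-species hits for both species (one
#'   combined data.frame is accepted; species are resolved via the seed
#'   members).
#' @param domain_map Domain-sequence table giving each id's `species`.
#' @return Group membership data.frame with columns `member_id`, `species`,
#'   `score_to_seed`, `is_seed` (seed members carry the seed score).
#' @export
recruit_inparalogs <- function(seed, within_hits, domain_map) {
  sp <- stats::setNames(domain_map$species, domain_map$id)
  env <- pair_score_map(within_hits)
  members <- data.frame(member_id = c(seed$member_a, seed$member_b),
                        species = unname(sp[c(seed$member_a, seed$member_b)]),
                        score_to_seed = c(seed$score, seed$score),
                        is_seed = TRUE, stringsAsFactors = FALSE)
  if (nrow(within_hits) > 0) {
    cand_ids <- setdiff(unique(c(within_hits$query_id,
                                 within_hits$subject_id)),
                        members$member_id)
    for (anchor in c(seed$member_a, seed$member_b)) {
      anchor_sp <- sp[[anchor]]
      for (cand in cand_ids) {
        if (is.na(sp[cand]) || sp[[cand]] != anchor_sp) next
        s <- get_pair_score(env, cand, anchor)
        if (!is.na(s) && s >= seed$score) {
          members <- rbind(members,
                           data.frame(member_id = cand, species = anchor_sp,
                                      score_to_seed = s, is_seed = FALSE,
                                      stringsAsFactors = FALSE))
        }
      }
    }
  }
  members <- members[!duplicated(members$member_id), , drop = FALSE]
  members <- members[order(!members$is_seed, members$species,
                           members$member_id), , drop = FALSE]
  rownames(members) <- NULL
  members
}

#' Resolve member overlaps between ortholog groups
#'
#' Groups are ranked by decreasing seed score (ties: lexicographically
#' smaller seed pair). In rank order, each group keeps only members not yet
#' claimed by a surviving stronger group; a group left without at least one
#' member in each species is deleted and claims nothing, releasing its
#' members to weaker groups.
#'
#' @param groups Group table with columns `group_id`, `seed_score`,
#'   `member_id`, `species`, `score_to_seed`, `is_seed`; groups may share
#'   members.
#' @return The same table with every member in at most one group, group ids
#'   renumbered 1..n in rank order.
#' @export
resolve_group_conflicts <- function(groups) {
  if (nrow(groups) == 0) return(groups)
  seed_key <- vapply(split(groups, groups$group_id), function(g) {
    paste(sort(g$member_id[g$is_seed]), collapse = "\t")
  }, "")
  info <- data.frame(group_id = as.integer(names(seed_key)),
                     seed_key = unname(seed_key), stringsAsFactors = FALSE)
  info$seed_score <- groups$seed_score[match(info$group_id, groups$group_id)]
  info <- info[order(-info$seed_score, info$seed_key), , drop = FALSE]

  claimed <- character(0)
  out <- vector("list", nrow(info))
  new_id <- 0L
  for (i in seq_len(nrow(info))) {
    g <- groups[groups$group_id == info$group_id[i], , drop = FALSE]
    g <- g[!(g$member_id %in% claimed), , drop = FALSE]
    if (length(unique(g$species)) < 2) next  # deleted: a species side is gone
    new_id <- new_id + 1L
    g$group_id <- new_id
    claimed <- c(claimed, g$member_id)
    out[[i]] <- g
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(groups[0, , drop = FALSE])
  res <- res[order(res$group_id, !res$is_seed, res$species, res$member_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Infer disjoint ortholog groups from filtered hits
#'
#' Full clustering pass: seeds from reciprocal best cross-species hits,
#' inparalog recruitment around each seed, then conflict resolution.
#'
#' @param cross_hits,within_hits Filtered hits (within-species hits for both
#'   species may be concatenated).
#' @param domain_map Domain-sequence table giving each id's `species`.
#' @return Group table with columns `group_id`, `seed_score`, `member_id`,
#'   `species`, `score_to_seed`, `is_seed`; members are disjoint across
#'   groups and every group has both species represented.
#' @export
infer_ortholog_groups <- function(cross_hits, within_hits, domain_map) {
  seeds <- find_seed_orthologs(cross_hits, domain_map)
  if (nrow(seeds) == 0) {
    return(empty_df(group_id = integer(0), seed_score = numeric(0),
                    member_id = character(0), species = character(0),
                    score_to_seed = numeric(0), is_seed = logical(0)))
  }
  all_groups <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    m <- recruit_inparalogs(seeds[i, , drop = FALSE], within_hits, domain_map)
    m$group_id <- i
    m$seed_score <- seeds$score[i]
    all_groups[[i]] <- m
  }
  g <- do.call(rbind, all_groups)
  g <- g[, c("group_id", "seed_score", "member_id", "species",
             "score_to_seed", "is_seed")]
  resolve_group_conflicts(g)
}

#' Expand ortholog groups into cross-species domain pairs
#'
#' Every pair of co-grouped members from different species is an orthologous
#' domain pair.
#'
#' @param groups Disjoint group table ([infer_ortholog_groups()] output).
#' @return Data.frame with columns `domain_a`, `domain_b`, `group_id`
#'   (`domain_a` is the lexicographically smaller id), sorted.
#' @export
groups_to_domain_pairs <- function(groups) {
  if (nrow(groups) == 0) {
    return(empty_df(domain_a = character(0), domain_b = character(0),
                    group_id = integer(0)))
  }
  out <- lapply(split(groups, groups$group_id), function(g) {
    species <- sort(unique(g$species))
    a <- sort(g$member_id[g$species == species[1]])
    b <- sort(g$member_id[g$species == species[2]])
    grid <- expand.grid(domain_a = a, domain_b = b,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$group_id <- g$group_id[1]
    grid
  })
  out <- do.call(rbind, out)
  out <- canonical_pairs(out, "domain_a", "domain_b")
  out[order(out$group_id, out$domain_a, out$domain_b), , drop = FALSE]
}
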