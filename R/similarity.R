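#' Scoring parameters for the built-in local aligner
#'
#' BLOSUM62 with affine gaps (open 11, extend 1) and the gapped
#' Karlin-Altschul constants lambda = 0.267, K = 0.041 used by BLASTP for
#' this scheme; raw Smith-Waterman scores S are converted to bits as
#' (lambda * S - ln K) / ln 2.
#'
#' @param matrix Substitution matrix name available in Biostrings.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param lambda,K Karlin-Altschul constants for the bit conversion.
#' @return A list of class `domorth_scoring`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  p <- list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
            lambda = lambda, K = K)
  class(p) <- "domorth_scoring"
  p
}

get_subst_matrix <- function(params) {
  e <- new.env()
  utils::data(list = params$matrix, package = "Biostrings", envir = e)
  get(params$matrix, envir = e)
}

raw_to_bits <- function(S, params) {
  (params$lambda * S - log(params$K)) / log(2)
}

#' Local alignment bitscore between two domain sequences
#'
#' Smith-Waterman local alignment under the scheme in [scoring_params()].
#' Returns `NULL` when no positive-scoring local alignment exists. The score
#' is symmetric: swapping the two sequences swaps the matched-segment
#' orientation but not the bitscore.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param params A [scoring_params()] list.
#' @return `NULL`, or a one-row segment-level hit data.frame (columns
#'   `query_id` = "a", `subject_id` = "b", `qstart`, `qend`, `sstart`,
#'   `send`, `bitscore`); the single segment is the local alignment extent.
#' @export
local_align_bitscore <- function(seq_a, seq_b, params = scoring_params()) {
  check_aa_sequence(seq_a, "seq_a")
  check_aa_sequence(seq_b, "seq_b")
  mat <- get_subst_matrix(params)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  S <- Biostrings::score(al)
  if (S <= 0) return(NULL)
  data.frame(query_id = "a", subject_id = "b",
             qstart = Biostrings::start(Biostrings::pattern(al)),
             qend = Biostrings::end(Biostrings::pattern(al)),
             sstart = Biostrings::start(Biostrings::subject(al)),
             send = Biostrings::end(Biostrings::subject(al)),
             bitscore = raw_to_bits(S, params), stringsAsFactors = FALSE)
}

# Vectorised inner loop: one subject against a set of patterns, returning
# segment rows for positive raw scores only.
align_set_vs_one <- function(pat_ids, pat_set, sub_id, sub_seq, mat, params) {
  al <- Biostrings::pairwiseAlignment(
    pat_set, Biostrings::AAString(sub_seq), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  S <- Biostrings::score(al)
  pos <- which(S > 0)
  if (length(pos) == 0) return(NULL)
  data.frame(query_id = pat_ids[pos], subject_id = sub_id,
             qstart = Biostrings::start(Biostrings::pattern(al))[pos],
             qend = Biostrings::end(Biostrings::pattern(al))[pos],
             sstart = Biostrings::start(Biostrings::subject(al))[pos],
             send = Biostrings::end(Biostrings::subject(al))[pos],
             bitscore = raw_to_bits(S[pos], params),
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity search over two domain-sequence sets
#'
#' Scores every cross-set pair (query from set A, subject from set B) and,
#' within each set, every ordered pair excluding self-pairs (the
#' within-species searches that score candidate inparalogs). Output ordering
#' is deterministic and independent of input row order.
#'
#' @param domain_seqs_a,domain_seqs_b Domain-sequence tables from
#'   [extract_proteome()] (only `id` and `sequence` are used).
#' @param params A [scoring_params()] list.
#' @param min_bitscore Hits below this bitscore are not materialised
#'   (default 0: keep every positive-scoring alignment). The pipeline passes
#'   its bitscore cutoff here purely to keep the hit tables small; the
#'   actual filtering contract lives in [apply_hit_filters()].
#' @return A list of three segment-level hit data.frames: `cross`,
#'   `within_a`, `within_b`.
#' @export
all_vs_all <- function(domain_seqs_a, domain_seqs_b,
                       params = scoring_params(), min_bitscore = 0) {
  stopifnot(nrow(domain_seqs_a) > 0, nrow(domain_seqs_b) > 0)
  mat <- get_subst_matrix(params)
  a <- domain_seqs_a[order(domain_seqs_a$id), , drop = FALSE]
  b <- domain_seqs_b[order(domain_seqs_b$id), , drop = FALSE]
  set_a <- Biostrings::AAStringSet(stats::setNames(a$sequence, a$id))

  run <- function(pat_ids, pat_set, sub_ids, sub_seqs) {
    out <- vector("list", length(sub_ids))
    for (i in seq_along(sub_ids)) {
      out[[i]] <- align_set_vs_one(pat_ids, pat_set, sub_ids[i], sub_seqs[i],
                                   mat, params)
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- empty_hits()
    res <- res[res$bitscore >= min_bitscore, , drop = FALSE]
    res <- res[order(res$query_id, res$subject_id), , drop = FALSE]
    rownames(res) <- NULL
    res
  }

  cross <- run(a$id, set_a, b$id, b$sequence)

  # Within-set: align each subject against the earlier-sorted ids only, then
  # mirror the rows (the scheme is symmetric) to obtain both ordered pairs.
  run_within <- function(d) {
    out <- vector("list", nrow(d))
    full <- Biostrings::AAStringSet(stats::setNames(d$sequence, d$id))
    for (i in seq_len(nrow(d))[-1]) {
      out[[i]] <- align_set_vs_one(d$id[seq_len(i - 1)],
                                   full[seq_len(i - 1)],
                                   d$id[i], d$sequence[i], mat, params)
    }
    res <- do.call(rbind, out)
    if (is.null(res)) return(empty_hits())
    mirrored <- data.frame(query_id = res$subject_id,
                           subject_id = res$query_id,
                           qstart = res$sstart, qend = res$send,
                           sstart = res$qstart, send = res$qend,
                           bitscore = res$bitscore, stringsAsFactors = FALSE)
    res <- rbind(res, mirrored)
    res <- res[res$bitscore >= min_bitscore, , drop = FALSE]
    res <- res[order(res$query_id, res$subject_id), , drop = FALSE]
    rownames(res) <- NULL
    res
  }

  list(cross = cross, within_a = run_within(a), within_b = run_within(b))
}

#' Filter similarity hits on bitscore and coverage of the longer sequence
#'
#' Aggregates segment-level hits per (query, subject) pair -- the pair
#' bitscore is the maximum over its segments, coverage is computed on the
#' longer of the two sequences -- and keeps pairs with
#' `bitscore >= bitscore_cutoff`, union-of-segments coverage
#' `>= segment_coverage_cutoff`, and summed aligned span
#' `>= seq_overlap_cutoff`. With both coverage cutoffs at 0 only the
#' bitscore filter applies.
#'
#' @param hits Segment-level hit data.frame ([all_vs_all()] element or
#'   [read_blast_tabular()] output).
#' @param lengths Named integer vector: sequence id -> residue length, for
#'   every id occurring in `hits`.
#' @param config A [domorth_config()].
#' @return Pair-level hit data.frame with columns `query_id`, `subject_id`,
#'   `bitscore`, `coverage_longer`, `seq_overlap`, `n_segments`, sorted by
#'   the id pair.
#' @export
apply_hit_filters <- function(hits, lengths, config = domorth_config()) {
  if (nrow(hits) == 0) {
    return(empty_df(query_id = character(0), subject_id = character(0),
                    bitscore = numeric(0), coverage_longer = numeric(0),
                    seq_overlap = numeric(0), n_segments = integer(0)))
  }
  ids <- unique(c(hits$query_id, hits$subject_id))
  unknown <- setdiff(ids, names(lengths))
  if (length(unknown) > 0) {
    stop(sprintf("hit references id(s) with unknown length: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  key <- paste(hits$query_id, hits$subject_id, sep = "\t")
  parts <- split(seq_len(nrow(hits)), key)
  rows <- lapply(parts, function(ix) {
    h <- hits[ix, , drop = FALSE]
    qlen <- lengths[[h$query_id[1]]]
    slen <- lengths[[h$subject_id[1]]]
    if (qlen >= slen) {
      starts <- h$qstart; ends <- h$qend
    } else {
      starts <- h$sstart; ends <- h$send
    }
    longer <- max(qlen, slen)
    cov_union <- interval_union_length(starts, ends) / longer
    cov_sum <- min(1, sum(ends - starts + 1L) / longer)
    data.frame(query_id = h$query_id[1], subject_id = h$subject_id[1],
               bitscore = max(h$bitscore),
               coverage_longer = cov_union, seq_overlap = cov_sum,
               n_segments = nrow(h), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$bitscore >= config$bitscore_cutoff &
               out$coverage_longer >= config$segment_coverage_cutoff &
               out$seq_overlap >= config$seq_overlap_cutoff, , drop = FALSE]
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
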