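random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

test_that("bitscores agree with an independent quadratic DP oracle", {
  params <- scoring_params()
  e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  set.seed(101)
  for (rep in 1:12) {
    a <- random_peptide(sample(20:50, 1))
    b <- if (rep %% 3 == 0) a else random_peptide(sample(20:50, 1))
    hit <- local_align_bitscore(a, b, params)
    raw_oracle <- sw_oracle_score(a, b, mat, params$gap_open,
                                  params$gap_extend)
    if (is.null(hit)) {
      expect_lte(raw_oracle, 0)
    } else {
      bits_oracle <- (params$lambda * raw_oracle - log(params$K)) / log(2)
      expect_equal(hit$bitscore, bits_oracle, tolerance = 1e-10)
    }
  }
})

test_that("the scorer is symmetric and rejects bad input", {
  set.seed(7)
  for (rep in 1:5) {
    a <- random_peptide(30); b <- random_peptide(40)
    ha <- local_align_bitscore(a, b)
    hb <- local_align_bitscore(b, a)
    expect_equal(ha$bitscore, hb$bitscore)
    # segments swap orientation
    expect_equal(c(ha$qstart, ha$qend), c(hb$sstart, hb$send))
  }
  expect_error(local_align_bitscore("", "MKV"), "non-empty")
  expect_error(local_align_bitscore("MK9V", "MKV"), "non-amino-acid")
})

test_that("sequences with no positive-scoring alignment return nothing", {
  # single opposing residues with a negative substitution score
  expect_null(local_align_bitscore("W", "G"))
})

test_that("all-vs-all emits cross and within hits deterministically", {
  set.seed(11)
  base <- random_peptide(60)
  mutate1 <- function(s) { substr(s, 5, 5) <- "A"; s }
  dsa <- data.frame(id = c("a1", "a2"),
                    sequence = c(base, mutate1(base)),
                    stringsAsFactors = FALSE)
  dsb <- data.frame(id = c("b1", "b2", "b3"),
                    sequence = c(base, mutate1(base), random_peptide(60)),
                    stringsAsFactors = FALSE)
  hits <- all_vs_all(dsa, dsb)
  expect_lte(nrow(hits$cross), 6L)      # |A| x |B| ordered query->subject
  expect_lte(nrow(hits$within_a), 2L)   # both directions, self excluded
  expect_lte(nrow(hits$within_b), 6L)
  expect_false(any(hits$within_a$query_id == hits$within_a$subject_id))
  expect_false(any(hits$within_b$query_id == hits$within_b$subject_id))

  # invariant under row permutation of the inputs
  hits2 <- all_vs_all(dsa[2:1, ], dsb[c(3, 1, 2), ])
  expect_identical(hits, hits2)

  # pairwise agreement with the direct scorer
  direct <- local_align_bitscore(dsa$sequence[1], dsb$sequence[2])
  row <- hits$cross[hits$cross$query_id == "a1" &
                      hits$cross$subject_id == "b2", ]
  expect_equal(row$bitscore, direct$bitscore)
})

test_that("hit filters apply bitscore and both coverage cutoffs", {
  lens <- c(q = 100L, s = 100L)
  mk <- function(bits, qs = 1L, qe = 50L) {
    data.frame(query_id = "q", subject_id = "s", qstart = qs, qend = qe,
               sstart = qs, send = qe, bitscore = bits,
               stringsAsFactors = FALSE)
  }
  # bitscore 39.5 at the default 40-bit cutoff: dropped
  expect_equal(nrow(apply_hit_filters(mk(39.5), lens)), 0L)
  # coverage exactly 0.50 is kept ("at least 50%")
  expect_equal(nrow(apply_hit_filters(mk(60), lens)), 1L)
  # coverage below 0.5 at defaults: dropped
  expect_equal(nrow(apply_hit_filters(mk(60, 1L, 10L), lens)), 0L)
  # with both coverage cutoffs 0 only the bitscore filter applies
  loose <- domorth_config(seq_overlap_cutoff = 0, segment_coverage_cutoff = 0)
  expect_equal(nrow(apply_hit_filters(mk(60, 1L, 10L), lens, loose)), 1L)
  expect_equal(nrow(apply_hit_filters(mk(39.5, 1L, 10L), lens, loose)), 0L)
  # unknown id
  expect_error(apply_hit_filters(mk(60), c(q = 100L)), "unknown length")
})

test_that("multi-segment coverage equals the residue-marking oracle", {
  set.seed(33)
  for (rep in 1:20) {
    len_long <- sample(80:200, 1)
    n_seg <- sample(1:4, 1)
    qs <- sort(sample(seq_len(len_long - 10), n_seg))
    qe <- pmin(len_long, qs + sample(5:60, n_seg, replace = TRUE))
    hits <- data.frame(query_id = "q", subject_id = "s", qstart = qs,
                       qend = qe, sstart = qs, send = qe,
                       bitscore = 50 + seq_len(n_seg),
                       stringsAsFactors = FALSE)
    lens <- c(q = len_long, s = 40L)
    loose <- domorth_config(seq_overlap_cutoff = 0,
                            segment_coverage_cutoff = 0)
    out <- apply_hit_filters(hits, lens, loose)
    expect_equal(out$coverage_longer, coverage_oracle(qs, qe, len_long))
    expect_equal(out$bitscore, max(hits$bitscore))  # max-HSP pair score
    expect_equal(out$n_segments, n_seg)
  }
})

test_that("filtering is monotone in every cutoff", {
  set.seed(55)
  hits <- do.call(rbind, lapply(1:30, function(i) {
    qe <- sample(20:100, 1)
    data.frame(query_id = sprintf("q%d", i), subject_id = "s",
               qstart = 1L, qend = qe, sstart = 1L, send = qe,
               bitscore = runif(1, 20, 90), stringsAsFactors = FALSE)
  }))
  lens <- c(stats::setNames(rep(100L, 30), sprintf("q%d", 1:30)), s = 100L)
  base_n <- nrow(apply_hit_filters(hits, lens, domorth_config(
    bitscore_cutoff = 30, seq_overlap_cutoff = 0.2,
    segment_coverage_cutoff = 0.2)))
  for (cfg in list(domorth_config(bitscore_cutoff = 50,
                                  seq_overlap_cutoff = 0.2,
                                  segment_coverage_cutoff = 0.2),
                   domorth_config(bitscore_cutoff = 30,
                                  seq_overlap_cutoff = 0.6,
                                  segment_coverage_cutoff = 0.2),
                   domorth_config(bitscore_cutoff = 30,
                                  seq_overlap_cutoff = 0.2,
                                  segment_coverage_cutoff = 0.6))) {
    expect_lte(nrow(apply_hit_filters(hits, lens, cfg)), base_n)
  }
})

test_that("imported BLAST hits flow through the same filter contract", {
  lines <- c("a1\tb1\t95.0\t60\t3\t0\t1\t60\t1\t60\t1e-30\t80.0",
             "a1\tb2\t90.0\t20\t2\t0\t1\t20\t1\t20\t1e-5\t40.0")
  path <- tempfile(); writeLines(lines, path)
  imported <- read_blast_tabular(path)
  lens <- c(a1 = 60L, b1 = 60L, b2 = 80L)
  filtered <- apply_hit_filters(imported, lens)
  # same column structure as the built-in scorer route
  dsa <- data.frame(id = "a1", sequence = random_peptide(60),
                    stringsAsFactors = FALSE)
  dsb <- data.frame(id = "b1", sequence = random_peptide(60),
                    stringsAsFactors = FALSE)
  builtin <- apply_hit_filters(all_vs_all(dsa, dsb)$cross,
                               c(a1 = 60L, b1 = 60L))
  expect_identical(names(filtered), names(builtin))
  expect_equal(filtered$query_id, "a1")
  expect_equal(filtered$subject_id, "b1")  # b2 hit fails coverage
})
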