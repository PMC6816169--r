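#' Analysis configuration
#'
#' Bundles every tunable cutoff of the pipeline. Defaults follow the
#' InParanoid post-processing conventions for the similarity filters and the
#' recommended thresholds for the alpha projection.
#'
#' @param bitscore_cutoff Minimum bitscore (bits) for a similarity hit to be
#'   used at all. Default 40.
#' @param seq_overlap_cutoff Minimum fraction of the longer sequence covered
#'   by aligned residues (summed over matched segments). Default 0.5.
#' @param segment_coverage_cutoff Minimum fraction of the longer sequence
#'   covered by the union of matched segments. Default 0.5. With a single
#'   matched segment the two coverage measures coincide; they differ only for
#'   imported multi-segment (multi-HSP) hits.
#' @param min_unknown_len Unannotated regions must be strictly longer than
#'   this many residues to be kept as UNK domain-equivalents. Default 30.
#' @param overlap_discard_fraction Two domain annotations overlapping by more
#'   than this fraction of the shorter one trigger discarding of the shorter.
#'   Default 0.5.
#' @param alpha_threshold Minimum alpha (shared-domain fraction) for a
#'   protein pair to be called orthologous. Default 0.3.
#' @param alpha_threshold_merge Alpha threshold recommended when domain-based
#'   pairs are used to enrich a full-length ortholog set. Default 0.4.
#' @param rng_seed Integer seed for any stochastic component (only the
#'   synthetic generator draws random numbers; inference is deterministic).
#'
#' @return A list of class `domorth_config`.
#' @export
#' @examples
#' cfg <- domorth_config(alpha_threshold = 0.5)
#' cfg$bitscore_cutoff
domorth_config <- function(bitscore_cutoff = 40,
                           seq_overlap_cutoff = 0.5,
                           segment_coverage_cutoff = 0.5,
                           min_unknown_len = 30,
                           overlap_discard_fraction = 0.5,
                           alpha_threshold = 0.3,
                           alpha_threshold_merge = 0.4,
                           rng_seed = 1L) {
  cfg <- list(
    bitscore_cutoff = as.numeric(bitscore_cutoff),
    seq_overlap_cutoff = as.numeric(seq_overlap_cutoff),
    segment_coverage_cutoff = as.numeric(segment_coverage_cutoff),
    min_unknown_len = as.integer(min_unknown_len),
    overlap_discard_fraction = as.numeric(overlap_discard_fraction),
    alpha_threshold = as.numeric(alpha_threshold),
    alpha_threshold_merge = as.numeric(alpha_threshold_merge),
    rng_seed = as.integer(rng_seed)
  )
  for (f in c("seq_overlap_cutoff", "segment_coverage_cutoff",
              "overlap_discard_fraction", "alpha_threshold",
              "alpha_threshold_merge")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("config field '%s' must be a fraction in [0, 1]", f))
    }
  }
  if (is.na(cfg$bitscore_cutoff) || cfg$bitscore_cutoff < 0) {
    stop("bitscore_cutoff must be >= 0")
  }
  if (is.na(cfg$min_unknown_len) || cfg$min_unknown_len < 0) {
    stop("min_unknown_len must be >= 0")
  }
  class(cfg) <- "domorth_config"
  cfg
}

#' @export
print.domorth_config <- function(x, ...) {
  cat("domorth configuration\n")
  for (f in names(x)) cat(sprintf("  %-25s %s\n", f, format(x[[f]])))
  invisible(x)
}
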