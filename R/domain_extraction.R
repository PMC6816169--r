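#' Filter domain annotations of one protein
#'
#' Applies the two annotation-level exclusion rules before cutting:
#' annotations typed as Pfam repeats are removed, then overlapping
#' annotations are resolved. If two annotations overlap by more than
#' `overlap_discard_fraction` of the shorter one's length, the shorter is
#' discarded and the longer kept; resolution proceeds in order of
#' decreasing length (ties: smaller start coordinate first) so the longest
#' annotation always survives and the outcome does not depend on input
#' order.
#'
#' @param annotations Data.frame of annotations for a single protein
#'   (columns as in [read_pfamscan()]).
#' @param config A [domorth_config()].
#' @return A list with `kept` (the surviving annotations, sorted by start),
#'   `n_repeats_excluded` and `n_overlap_excluded`.
#' @export
filter_annotations <- function(annotations, config = domorth_config()) {
  if (nrow(annotations) == 0) {
    return(list(kept = annotations, n_repeats_excluded = 0L,
                n_overlap_excluded = 0L))
  }
  if (length(unique(annotations$protein_id)) > 1) {
    stop("filter_annotations() expects annotations of a single protein")
  }
  is_repeat <- tolower(annotations$family_type) == "repeat"
  ann <- annotations[!is_repeat, , drop = FALSE]
  n_repeats <- sum(is_repeat)

  if (nrow(ann) > 1) {
    len <- ann$end - ann$start + 1L
    ord <- order(-len, ann$start, ann$end, ann$name)
    ann <- ann[ord, , drop = FALSE]
    len <- len[ord]
    keep <- logical(nrow(ann))
    for (i in seq_len(nrow(ann))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- min(ann$end[i], ann$end[j]) - max(ann$start[i], ann$start[j]) + 1L
        if (ov > 0 && ov > config$overlap_discard_fraction * min(len[i], len[j])) {
          ok <- FALSE
          break
        }
      }
      keep[i] <- ok
    }
    n_overlap <- sum(!keep)
    ann <- ann[keep, , drop = FALSE]
  } else {
    n_overlap <- 0L
  }
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  list(kept = ann, n_repeats_excluded = as.integer(n_repeats),
       n_overlap_excluded = as.integer(n_overlap))
}

domain_seq_id <- function(protein_id, label, start, end) {
  sprintf("%s/%s/%d-%d", protein_id, label, start, end)
}

#' Cut one protein into domain-equivalent sequences
#'
#' Emits one `pfam_domain` cut per kept annotation; every maximal
#' unannotated region (terminal regions included) strictly longer than
#' `min_unknown_len` becomes an `unknown_region` labelled UNK1, UNK2, ... in
#' N-to-C order; a protein with no kept annotation is emitted whole as a
#' single `orphan`. Shorter unannotated regions are treated as linkers and
#' dropped.
#'
#' @param protein One-row protein data.frame (columns `id`, `species`,
#'   `sequence`, `length`).
#' @param kept_annotations Annotations surviving [filter_annotations()].
#' @param config A [domorth_config()].
#' @return A list with `cuts` (domain-sequence data.frame with columns `id`,
#'   `protein_id`, `species`, `start`, `end`, `label`, `category`,
#'   `sequence`) and region accounting: `n_regions_considered`,
#'   `n_regions_emitted`, `n_regions_discarded`.
#' @export
extract_domain_sequences <- function(protein, kept_annotations,
                                     config = domorth_config()) {
  stopifnot(nrow(protein) == 1)
  plen <- protein$length
  ann <- kept_annotations
  if (nrow(ann) > 0 && any(ann$start < 1 | ann$end > plen)) {
    bad <- ann[ann$start < 1 | ann$end > plen, , drop = FALSE][1, ]
    stop(sprintf("annotation %d..%d outside bounds of protein %s (length %d)",
                 bad$start, bad$end, protein$id, plen))
  }

  cut_row <- function(start, end, label, category) {
    data.frame(id = domain_seq_id(protein$id, label, start, end),
               protein_id = protein$id, species = protein$species,
               start = start, end = end, label = label, category = category,
               sequence = substr(protein$sequence, start, end),
               stringsAsFactors = FALSE)
  }

  if (nrow(ann) == 0) {
    return(list(cuts = cut_row(1L, plen, "ORPHAN", "orphan"),
                n_regions_considered = 0L, n_regions_emitted = 0L,
                n_regions_discarded = 0L))
  }

  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  dom_cuts <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    cut_row(ann$start[i], ann$end[i], ann$name[i], "pfam_domain")
  }))

  gaps <- interval_gaps(ann$start, ann$end, plen)
  emit <- gaps$end - gaps$start + 1L > config$min_unknown_len
  unk_cuts <- NULL
  if (any(emit)) {
    kept_gaps <- gaps[emit, , drop = FALSE]
    unk_cuts <- do.call(rbind, lapply(seq_len(nrow(kept_gaps)), function(i) {
      cut_row(kept_gaps$start[i], kept_gaps$end[i],
              sprintf("UNK%d", i), "unknown_region")
    }))
  }
  cuts <- rbind(dom_cuts, unk_cuts)
  cuts <- cuts[order(cuts$start, cuts$end), , drop = FALSE]
  rownames(cuts) <- NULL
  list(cuts = cuts,
       n_regions_considered = nrow(gaps),
       n_regions_emitted = sum(emit),
       n_regions_discarded = sum(!emit))
}

#' Extract domain-equivalent sequences from a whole proteome
#'
#' Runs [filter_annotations()] and [extract_domain_sequences()] on every
#' protein and aggregates the per-species accounting (orphans, UNK regions,
#' repeat and overlap exclusions).
#'
#' @param proteome Protein data.frame from [read_fasta()].
#' @param annotations Annotation data.frame from [read_pfamscan()]. Every
#'   `protein_id` must occur in `proteome`.
#' @param config A [domorth_config()].
#' @return A list with `domain_seqs` (all cuts for the proteome) and
#'   `report`, a one-row data.frame: `species`, `n_proteins`,
#'   `n_proteins_without_annotation`, `n_domains`, `n_unknown_regions`,
#'   `n_repeats_excluded`, `n_overlap_excluded`, `n_regions_considered`,
#'   `n_regions_discarded`.
#' @export
extract_proteome <- function(proteome, annotations,
                             config = domorth_config()) {
  missing_ids <- setdiff(unique(annotations$protein_id), proteome$id)
  if (length(missing_ids) > 0) {
    stop(sprintf("annotations reference unknown protein id(s): %s",
                 paste(missing_ids, collapse = ", ")))
  }
  ann_by_prot <- split(annotations, annotations$protein_id)
  all_cuts <- vector("list", nrow(proteome))
  rep_x <- 0L; ov_x <- 0L; reg_cons <- 0L; reg_emit <- 0L; reg_disc <- 0L
  n_orphan <- 0L
  for (i in seq_len(nrow(proteome))) {
    p <- proteome[i, , drop = FALSE]
    ann <- ann_by_prot[[p$id]]
    if (is.null(ann)) {
      ann <- annotations[0, , drop = FALSE]
    }
    filt <- filter_annotations(ann, config)
    ext <- extract_domain_sequences(p, filt$kept, config)
    rep_x <- rep_x + filt$n_repeats_excluded
    ov_x <- ov_x + filt$n_overlap_excluded
    reg_cons <- reg_cons + ext$n_regions_considered
    reg_emit <- reg_emit + ext$n_regions_emitted
    reg_disc <- reg_disc + ext$n_regions_discarded
    if (any(ext$cuts$category == "orphan")) n_orphan <- n_orphan + 1L
    all_cuts[[i]] <- ext$cuts
  }
  domain_seqs <- do.call(rbind, all_cuts)
  rownames(domain_seqs) <- NULL
  report <- data.frame(
    species = proteome$species[1],
    n_proteins = nrow(proteome),
    n_proteins_without_annotation = n_orphan,
    n_domains = sum(domain_seqs$category == "pfam_domain"),
    n_unknown_regions = sum(domain_seqs$category == "unknown_region"),
    n_repeats_excluded = rep_x,
    n_overlap_excluded = ov_x,
    n_regions_considered = reg_cons,
    n_regions_discarded = reg_disc,
    stringsAsFactors = FALSE
  )
  list(domain_seqs = domain_seqs, report = report)
}
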