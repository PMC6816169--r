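# End-to-end orchestration: extract -> score -> infer -> project /
# discordant (/ merge / sweep), with deterministic outputs and a run
# manifest.

stage_error <- function(stage, e) {
  stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

digest_file <- function(path) unname(tools::md5sum(path))

digest_table <- function(df) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  digest_file(tmp)
}

#' Run the full domain-orthology pipeline on two proteomes
#'
#' Stages: domain extraction for both species, all-vs-all similarity search
#' (or import of precomputed BLAST tabular hits), hit filtering,
#' InParanoid-style group inference, domain-pair expansion, protein-level
#' projection at `config$alpha_threshold` and discordance detection. When a
#' full-length group table is supplied, a merged pair set (at
#' `config$alpha_threshold_merge`), a pair classification and an
#' 11-threshold alpha sweep are added. Inference is deterministic: two runs
#' on the same inputs produce byte-identical outputs.
#'
#' @param config A [domorth_config()].
#' @param proteome_a,proteome_b Protein tables ([read_fasta()]) or FASTA
#'   file paths. Species tags must differ.
#' @param annotations_a,annotations_b Annotation tables ([read_pfamscan()])
#'   or PfamScan file paths.
#' @param fulllength_groups Optional full-length group table
#'   ([read_fulllength_groups()]) or path.
#' @param blast_cross,blast_self_a,blast_self_b Optional precomputed hits in
#'   BLAST tabular format (tables or paths); when given, the built-in
#'   aligner is skipped. Supply all three or none.
#' @param out_dir Optional directory; when given, every stage output is
#'   written as TSV/FASTA plus a JSON run manifest (written last).
#' @param scoring A [scoring_params()] for the built-in aligner.
#' @return A list: `domain_seqs`, `reports`, `hits` (filtered cross/within),
#'   `groups`, `domain_pairs`, `protein_pairs`, `discordance`, and when
#'   full-length groups were supplied `merged_pairs`, `pair_classes`,
#'   `sweep`; plus `manifest`.
#' @export
run_pipeline <- function(config = domorth_config(),
                         proteome_a, proteome_b,
                         annotations_a, annotations_b,
                         fulllength_groups = NULL,
                         blast_cross = NULL, blast_self_a = NULL,
                         blast_self_b = NULL,
                         out_dir = NULL,
                         scoring = scoring_params()) {
  load_stage <- function(x, reader, stage, ...) {
    if (is.character(x) && length(x) == 1) {
      tryCatch(reader(x, ...), error = function(e) stage_error(stage, e))
    } else x
  }
  proteome_a <- load_stage(proteome_a, read_fasta, "extract", species = "spA")
  proteome_b <- load_stage(proteome_b, read_fasta, "extract", species = "spB")
  annotations_a <- load_stage(annotations_a, read_pfamscan, "extract")
  annotations_b <- load_stage(annotations_b, read_pfamscan, "extract")
  if (proteome_a$species[1] == proteome_b$species[1]) {
    stage_error("extract", simpleError("species tags must be distinct"))
  }
  if (any(proteome_a$id %in% proteome_b$id)) {
    stage_error("extract",
                simpleError("protein ids must be unique across species"))
  }

  ext_a <- tryCatch(extract_proteome(proteome_a, annotations_a, config),
                    error = function(e) stage_error("extract", e))
  ext_b <- tryCatch(extract_proteome(proteome_b, annotations_b, config),
                    error = function(e) stage_error("extract", e))
  domain_seqs <- rbind(ext_a$domain_seqs, ext_b$domain_seqs)
  reports <- rbind(ext_a$report, ext_b$report)

  use_blast <- !is.null(blast_cross)
  if (use_blast && (is.null(blast_self_a) || is.null(blast_self_b))) {
    stage_error("score", simpleError(
      "supply all three BLAST hit tables (cross, self A, self B) or none"))
  }
  if (use_blast) {
    raw <- list(cross = load_stage(blast_cross, read_blast_tabular, "score"),
                within_a = load_stage(blast_self_a, read_blast_tabular,
                                      "score"),
                within_b = load_stage(blast_self_b, read_blast_tabular,
                                      "score"))
  } else {
    raw <- tryCatch(
      all_vs_all(ext_a$domain_seqs, ext_b$domain_seqs, params = scoring,
                 min_bitscore = config$bitscore_cutoff),
      error = function(e) stage_error("score", e))
  }
  lens <- stats::setNames(nchar(domain_seqs$sequence), domain_seqs$id)
  hits <- tryCatch(
    lapply(raw, apply_hit_filters, lengths = lens, config = config),
    error = function(e) stage_error("filter", e))

  groups <- tryCatch(
    infer_ortholog_groups(hits$cross, rbind(hits$within_a, hits$within_b),
                          domain_seqs),
    error = function(e) stage_error("infer", e))
  domain_pairs <- groups_to_domain_pairs(groups)
  protein_pairs <- tryCatch(
    project_protein_pairs(groups, domain_seqs, config$alpha_threshold),
    error = function(e) stage_error("project", e))
  discordance <- tryCatch(find_discordant(groups, domain_seqs),
                          error = function(e) stage_error("discordant", e))

  res <- list(domain_seqs = domain_seqs, reports = reports, hits = hits,
              groups = groups, domain_pairs = domain_pairs,
              protein_pairs = protein_pairs, discordance = discordance)

  if (!is.null(fulllength_groups)) {
    fulllength_groups <- load_stage(fulllength_groups,
                                    read_fulllength_groups, "merge")
    merge_pairs <- project_protein_pairs(groups, domain_seqs,
                                         config$alpha_threshold_merge)
    res$merged_pairs <- tryCatch(
      merge_with_fulllength(merge_pairs, fulllength_groups),
      error = function(e) stage_error("merge", e))
    res$pair_classes <- classify_pairs(protein_pairs, fulllength_groups)
    res$sweep <- alpha_sweep(groups, domain_seqs, fulllength_groups)
  }

  counts <- c(proteins_a = nrow(proteome_a), proteins_b = nrow(proteome_b),
              domain_seqs = nrow(domain_seqs),
              unknown_regions = sum(domain_seqs$category == "unknown_region"),
              orphans = sum(domain_seqs$category == "orphan"),
              repeats_excluded = sum(reports$n_repeats_excluded),
              overlap_excluded = sum(reports$n_overlap_excluded),
              cross_hits = nrow(hits$cross),
              groups = length(unique(groups$group_id)),
              domain_pairs = nrow(domain_pairs),
              protein_pairs = nrow(protein_pairs))
  res$manifest <- list(
    tool = "domorth", version = as.character(utils::packageVersion("domorth")),
    config = unclass(config),
    hits_source = if (use_blast) "imported_blast_tabular" else "builtin_sw",
    input_digests = list(proteome_a = digest_table(proteome_a),
                         proteome_b = digest_table(proteome_b),
                         annotations_a = digest_table(annotations_a),
                         annotations_b = digest_table(annotations_b)),
    counts = as.list(counts))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_domain_fasta(domain_seqs, p("domain_sequences.fasta"))
    utils::write.table(reports, p("extraction_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (h in names(hits)) {
      utils::write.table(hits[[h]], p(sprintf("hits_%s.tsv", h)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_group_table(groups, p("ortholog_groups.tsv"))
    utils::write.table(domain_pairs, p("domain_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_pair_table(protein_pairs, p("protein_pairs.tsv"))
    utils::write.table(discordance, p("discordance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(res$merged_pairs)) {
      utils::write.table(res$merged_pairs, p("merged_pairs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(res$pair_classes, p("pair_classes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(res$sweep, p("alpha_sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  res
}
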