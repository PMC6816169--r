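#' Read a proteome from a FASTA file
#'
#' Parses a multi-FASTA file into a protein table. The record id is the first
#' whitespace-delimited token of the header; sequences are uppercased and
#' stripped of stop (`*`) and gap (`-`, `.`) characters.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag attached to every record.
#' @return A data.frame with columns `id`, `species`, `sequence`, `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 desc", "MKV"), fa)
#' read_fasta(fa, species = "ecoli")
read_fasta <- function(path, species) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  stopifnot(is.character(species), length(species) == 1, nzchar(species))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop(sprintf("failed to parse FASTA %s: %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0) stop(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate protein id(s) in %s: %s",
                 path, paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[*.\\-]", "", seqs)
  if (any(nchar(seqs) == 0)) {
    stop(sprintf("zero-length sequence(s) in %s: %s", path,
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  data.frame(id = unname(ids), species = species, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

# Column layout of pfam_scan.pl tabular output (15 whitespace-separated
# fields after comments). Envelope coordinates (cols 4-5) define the domain
# extent used downstream.
PFAMSCAN_NCOL <- 15L

#' Read domain annotations in PfamScan tabular format
#'
#' Consumes the whitespace-delimited table written by `pfam_scan.pl`:
#' seq_id, aln_start, aln_end, env_start, env_end, hmm_acc, hmm_name,
#' type, hmm_start, hmm_end, hmm_length, bit_score, E-value, significance,
#' clan. Lines starting with `#` and blank lines are skipped. The envelope
#' coordinates become the annotation extent.
#'
#' @param path Path to a PfamScan output file.
#' @param source Provenance tag stored with each annotation.
#' @return A data.frame with columns `protein_id`, `start`, `end`, `name`,
#'   `family_type`, `source`. Rows may reference proteins absent from a
#'   proteome; such rows are rejected later, at extraction time.
#' @export
read_pfamscan <- function(path, source = "pfamscan") {
  if (!file.exists(path)) stop(sprintf("PfamScan file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(empty_df(protein_id = character(0), start = integer(0),
                    end = integer(0), name = character(0),
                    family_type = character(0), source = character(0)))
  }
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != PFAMSCAN_NCOL) {
      stop(sprintf("%s line %d: expected %d columns, got %d",
                   path, i, PFAMSCAN_NCOL, length(f)))
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("%s line %d: non-numeric envelope coordinates", path, i))
    }
    if (end < start || start < 1) {
      stop(sprintf("%s line %d: invalid envelope %d..%d", path, i, start, end))
    }
    data.frame(protein_id = f[1], start = start, end = end, name = f[7],
               family_type = f[8], source = source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotations in PfamScan tabular format
#'
#' Emits the 15-column layout accepted by [read_pfamscan()]. Alignment and
#' envelope coordinates are written identically; HMM-level columns are
#' filled with placeholders. Used by the synthetic generator and for
#' fixtures.
#'
#' @param annotations Data.frame as returned by [read_pfamscan()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pfamscan <- function(annotations, path) {
  header <- "# <seq id> <alignment start> <alignment end> <envelope start> <envelope end> <hmm acc> <hmm name> <type> <hmm start> <hmm end> <hmm length> <bit score> <E-value> <significance> <clan>"
  lines <- header
  if (nrow(annotations) > 0) {
    body <- sprintf("%s %d %d %d %d PF00000.0 %s %s 1 %d %d 100.0 1e-10 1 No_clan",
                    annotations$protein_id, annotations$start, annotations$end,
                    annotations$start, annotations$end, annotations$name,
                    annotations$family_type,
                    annotations$end - annotations$start + 1L,
                    annotations$end - annotations$start + 1L)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read similarity hits in BLAST tabular format (outfmt 6)
#'
#' Parses the standard 12-column tabular hit format (query, subject, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Each row becomes one matched segment (HSP); multiple rows for the same
#' (query, subject) pair are retained so that coverage can be computed from
#' all segments. Self-hits (query == subject) are dropped.
#'
#' @param path Path to a BLAST `-outfmt 6` file.
#' @return A segment-level hit data.frame with columns `query_id`,
#'   `subject_id`, `qstart`, `qend`, `sstart`, `send`, `bitscore`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop(sprintf("BLAST tabular file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_hits())
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 12) f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 12) {
      stop(sprintf("%s line %d: expected 12 columns, got %d", path, i, length(f)))
    }
    bits <- suppressWarnings(as.numeric(f[12]))
    if (is.na(bits)) stop(sprintf("%s line %d: non-numeric bitscore '%s'", path, i, f[12]))
    qs <- as.integer(f[7]); qe <- as.integer(f[8])
    ss <- as.integer(f[9]); se <- as.integer(f[10])
    if (anyNA(c(qs, qe, ss, se))) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    }
    data.frame(query_id = f[1], subject_id = f[2],
               qstart = min(qs, qe), qend = max(qs, qe),
               sstart = min(ss, se), send = max(ss, se),
               bitscore = bits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$query_id != out$subject_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  empty_df(query_id = character(0), subject_id = character(0),
           qstart = integer(0), qend = integer(0),
           sstart = integer(0), send = integer(0), bitscore = numeric(0))
}

#' Write / read the ortholog group table
#'
#' Deterministic TSV with columns `group_id`, `seed_score`, `species`,
#' `member_id`, `is_seed`, `score_to_seed`, sorted by group id then species
#' then member id. `write_group_table()` and `read_group_table()` round-trip.
#'
#' @param groups Group membership data.frame (see [infer_ortholog_groups()]).
#' @param path Output path.
#' @return Invisibly `path`; for the reader, the group data.frame.
#' @export
write_group_table <- function(groups, path) {
  cols <- c("group_id", "seed_score", "species", "member_id", "is_seed",
            "score_to_seed")
  g <- groups[, cols, drop = FALSE]
  g <- g[order(g$group_id, g$species, g$member_id), , drop = FALSE]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_table
#' @export
read_group_table <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(group_id = "integer",
                                        seed_score = "numeric",
                                        species = "character",
                                        member_id = "character",
                                        is_seed = "logical",
                                        score_to_seed = "numeric"))
  g
}

#' Write / read protein-pair tables
#'
#' Deterministic TSV with columns `protein_a`, `protein_b`, `alpha`,
#' `n_shared`, `n_total`, `supporting_groups`, sorted by the id pair.
#'
#' @param pairs Protein-pair data.frame (see [project_protein_pairs()]).
#' @param path Output path.
#' @return Invisibly `path`; for the reader, the pair data.frame.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c("protein_a", "protein_b", "alpha", "n_shared", "n_total",
            "supporting_groups")
  p <- pairs[, cols, drop = FALSE]
  p <- p[order(p$protein_a, p$protein_b), , drop = FALSE]
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(protein_a = "character",
                                   protein_b = "character",
                                   alpha = "numeric",
                                   n_shared = "integer",
                                   n_total = "integer",
                                   supporting_groups = "character"))
}

#' Read a full-length ortholog group table
#'
#' Minimal InParanoid-style group membership table for merging: TSV with
#' columns `group_id`, `member_id`, `species` (header required).
#'
#' @param path Input path.
#' @return A data.frame with the three columns above.
#' @export
read_fulllength_groups <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("group_id", "member_id", "species")
  if (!all(need %in% names(g))) {
    stop(sprintf("full-length group table %s must have columns: %s",
                 path, paste(need, collapse = ", ")))
  }
  g[, need]
}

#' Write domain-equivalent sequences as FASTA
#'
#' @param domain_seqs Domain-sequence table from [extract_proteome()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_domain_fasta <- function(domain_seqs, path) {
  d <- domain_seqs[order(domain_seqs$id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(d))) {
    writeLines(c(paste0(">", d$id[i]), d$sequence[i]), con)
  }
  invisible(path)
}
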