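# Internal helpers shared across modules.

# Canonical key for an unordered pair of identifiers.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Canonicalise a two-column pair data.frame: lexicographically smaller id in
# the first column, rows sorted, duplicates removed. Extra columns are kept
# from the first occurrence of each pair.
canonical_pairs <- function(df, col_a, col_b) {
  if (nrow(df) == 0) {
    df <- df[order(character(0)), , drop = FALSE]
    return(df)
  }
  a <- as.character(df[[col_a]])
  b <- as.character(df[[col_b]])
  swap <- a > b
  df[[col_a]] <- ifelse(swap, b, a)
  df[[col_b]] <- ifelse(swap, a, b)
  df <- df[!duplicated(pair_key(df[[col_a]], df[[col_b]])), , drop = FALSE]
  df <- df[order(df[[col_a]], df[[col_b]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# All residue codes with a BLOSUM62 row (stop '*' excluded on purpose).
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA_ALPHABET20, "B", "Z", "X", "U", "O", "J")

check_aa_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop(sprintf("%s must be a non-empty amino-acid string", what))
  }
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, AA_ALLOWED)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-amino-acid characters: %s",
                 what, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# Total length of the union of 1-based inclusive intervals.
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

# Gaps (maximal uncovered runs) of [1, len] not covered by the intervals.
interval_gaps <- function(starts, ends, len) {
  covered <- rep(FALSE, len)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  pos <- cumsum(c(1L, r$lengths))
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) {
      out_s <- c(out_s, pos[i])
      out_e <- c(out_e, pos[i] + r$lengths[i] - 1L)
    }
  }
  data.frame(start = out_s, end = out_e)
}

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
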