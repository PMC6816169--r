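# Small in-code fixtures shared across test files.

pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

write_temp_fasta <- function(entries) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

# one well-formed 15-column PfamScan row
pfamscan_row <- function(id = "P1", aln_start = 7, aln_end = 118,
                         env_start = 5, env_end = 120, name = "TestDom",
                         type = "Domain") {
  sprintf("%s %d %d %d %d PF00001.21 %s %s 1 100 100 55.0 1e-20 1 CL0001",
          id, aln_start, aln_end, env_start, env_end, name, type)
}

write_temp_pfamscan <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# pfam_scan.pl output", "", rows), path)
  path
}

make_annotation <- function(protein_id, start, end, name = "Dom",
                            family_type = "Domain") {
  data.frame(protein_id = protein_id, start = start, end = end, name = name,
             family_type = family_type, source = "test",
             stringsAsFactors = FALSE)
}

make_protein <- function(id, length, species = "spA") {
  set.seed(sum(utf8ToInt(id)) + length)
  data.frame(id = id, species = species,
             sequence = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                              "")[[1]],
                                     length, replace = TRUE), collapse = ""),
             length = length, stringsAsFactors = FALSE)
}

# minimal domain map / group tables for the protein-level operations
make_domain_map <- function(ids, protein_ids, species) {
  data.frame(id = ids, protein_id = protein_ids, species = species,
             stringsAsFactors = FALSE)
}

make_groups <- function(member_lists, seed_scores = NULL) {
  rows <- lapply(seq_along(member_lists), function(i) {
    m <- member_lists[[i]]
    data.frame(group_id = i,
               seed_score = if (is.null(seed_scores)) 100 else seed_scores[i],
               member_id = m, species = NA_character_,
               score_to_seed = 100, is_seed = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# attach species to a group table from a domain map
with_species <- function(groups, domain_map) {
  groups$species <- domain_map$species[match(groups$member_id,
                                             domain_map$id)]
  groups
}

# the three-domain vs two-domain worked example: protein X carries
# instances of families A, B, C; protein Y carries A and C; the two A
# instances and the two C instances are co-grouped.
alpha_worked_example <- function() {
  dm <- make_domain_map(
    ids = c("X/A/1-100", "X/B/101-200", "X/C/201-300",
            "Y/A/1-100", "Y/C/101-200"),
    protein_ids = c("X", "X", "X", "Y", "Y"),
    species = c("hs", "hs", "hs", "ec", "ec"))
  gr <- with_species(make_groups(list(c("X/A/1-100", "Y/A/1-100"),
                                      c("X/C/201-300", "Y/C/101-200"))), dm)
  list(domain_map = dm, groups = gr)
}
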