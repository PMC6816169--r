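test_that("alpha counts shared and total domain instances over both proteins", {
  ex <- alpha_worked_example()
  p <- compute_alpha("X", "Y", ex$domain_map, ex$groups)
  expect_equal(p$n_shared, 4L)   # X:A, X:C, Y:A, Y:C
  expect_equal(p$n_total, 5L)    # X's B has no partner group
  expect_equal(p$alpha, 4 / 5)
  expect_equal(p$supporting_groups, "1,2")

  # no shared groups -> alpha 0
  lone <- make_groups(list(c("X/A/1-100", "Z/A/1-100")))
  expect_equal(compute_alpha("X", "Y", ex$domain_map, lone)$alpha, 0)

  # single-domain proteins co-grouped -> alpha 1
  dm1 <- make_domain_map(c("U/D/1-50", "V/D/1-50"), c("U", "V"),
                         c("hs", "ec"))
  g1 <- with_species(make_groups(list(c("U/D/1-50", "V/D/1-50"))), dm1)
  expect_equal(compute_alpha("U", "V", dm1, g1)$alpha, 1)

  expect_error(compute_alpha("X", "NOPE", ex$domain_map, ex$groups),
               "no domain-equivalent")
})

test_that("alpha responds monotonically to shared and unshared instances", {
  ex <- alpha_worked_example()
  base <- compute_alpha("X", "Y", ex$domain_map, ex$groups)
  # add a third shared group (pair the B instance with a new Y instance)
  dm_plus <- rbind(ex$domain_map,
                   data.frame(id = "Y/B/201-250", protein_id = "Y",
                              species = "ec", stringsAsFactors = FALSE))
  g_plus <- with_species(rbind(ex$groups,
                               make_groups(list(c("X/B/101-200",
                                                  "Y/B/201-250")))[, ],
                               make.row.names = FALSE), dm_plus)
  g_plus$group_id[g_plus$member_id %in% c("X/B/101-200", "Y/B/201-250")] <- 3L
  more_shared <- compute_alpha("X", "Y", dm_plus, g_plus)
  expect_gt(more_shared$alpha, base$alpha)

  # add an ungrouped instance to X: alpha can only drop
  dm_extra <- rbind(ex$domain_map,
                    data.frame(id = "X/E/301-350", protein_id = "X",
                               species = "hs", stringsAsFactors = FALSE))
  diluted <- compute_alpha("X", "Y", dm_extra, ex$groups)
  expect_lt(diluted$alpha, base$alpha)
})

test_that("projection thresholds candidate pairs on alpha", {
  ex <- alpha_worked_example()
  at03 <- project_protein_pairs(ex$groups, ex$domain_map, 0.3)
  expect_equal(nrow(at03), 1L)
  expect_equal(at03$alpha, 0.8)
  expect_equal(nrow(project_protein_pairs(ex$groups, ex$domain_map, 0.9)), 0L)
  # threshold 0 reports every candidate pair
  at0 <- project_protein_pairs(ex$groups, ex$domain_map, 0)
  expect_equal(nrow(at0), 1L)
  expect_error(project_protein_pairs(ex$groups, ex$domain_map, 1.2),
               "alpha_threshold")
})

test_that("discordance flags partners with mutually exclusive domain subsets", {
  # fused primary F carries d1 orthologous to S1 and d2 orthologous to S2
  dm <- make_domain_map(c("F/d1/1-100", "F/d2/101-200",
                          "S1/d1/1-100", "S2/d2/1-100"),
                        c("F", "F", "S1", "S2"),
                        c("hs", "hs", "ec", "ec"))
  gr <- with_species(make_groups(list(c("F/d1/1-100", "S1/d1/1-100"),
                                      c("F/d2/101-200", "S2/d2/1-100"))), dm)
  d <- find_discordant(gr, dm)
  rec <- d[d$primary == "F", ]
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$is_discordant))
  subsets <- strsplit(rec$primary_domains, ",")
  expect_length(intersect(subsets[[1]], subsets[[2]]), 0L)

  # single partner -> no record at all
  single <- with_species(make_groups(list(c("F/d1/1-100", "S1/d1/1-100"))),
                         dm)
  expect_false("F" %in% find_discordant(single, dm)$primary)
})

test_that("overlapping domain subsets are recorded but not flagged", {
  # two secondaries both matching only d1
  dm <- make_domain_map(c("F/d1/1-100", "S1/d1/1-100", "S2/d1/1-100"),
                        c("F", "S1", "S2"), c("hs", "ec", "ec"))
  gr <- with_species(make_groups(list(c("F/d1/1-100", "S1/d1/1-100",
                                        "S2/d1/1-100"))), dm)
  d <- find_discordant(gr, dm)
  rec <- d[d$primary == "F", ]
  expect_equal(nrow(rec), 2L)
  expect_false(any(rec$is_discordant))
  # the weak mode flags only genuinely different subsets, so also nothing
  expect_false(any(find_discordant(gr, dm, mode = "weak")$is_discordant))
})

test_that("weak mode flags different but non-disjoint subsets", {
  # S1 matches {d1}, S2 matches {d1, d2}: different but overlapping
  dm <- make_domain_map(c("F/d1/1-100", "F/d2/101-200",
                          "S1/d1/1-100", "S2/d1/1-100", "S2/d2/101-200"),
                        c("F", "F", "S1", "S2", "S2"),
                        c("hs", "hs", "ec", "ec", "ec"))
  gr <- with_species(make_groups(list(c("F/d1/1-100", "S1/d1/1-100",
                                        "S2/d1/1-100"),
                                      c("F/d2/101-200", "S2/d2/101-200"))),
                     dm)
  expect_false(any(find_discordant(gr, dm, "strict")$is_discordant))
  expect_true(all(find_discordant(gr, dm, "weak")$is_discordant))
})

test_that("discordance flags depend only on the bipartite structure", {
  dm <- make_domain_map(c("F/d1/1-100", "F/d2/101-200",
                          "S1/d1/1-100", "S2/d2/1-100"),
                        c("F", "F", "S1", "S2"),
                        c("hs", "hs", "ec", "ec"))
  gr <- with_species(make_groups(list(c("F/d1/1-100", "S1/d1/1-100"),
                                      c("F/d2/101-200", "S2/d2/1-100"))), dm)
  relabeled <- gr
  relabeled$group_id <- c(7L, 7L, 3L, 3L)[match(relabeled$member_id,
                                                gr$member_id)]
  expect_equal(find_discordant(gr, dm)$is_discordant,
               find_discordant(relabeled, dm)$is_discordant)
})

test_that("merging keeps full-length pairs and adds non-conflicting ones", {
  fl <- data.frame(group_id = c(1L, 1L, 2L, 2L),
                   member_id = c("P", "Q", "R", "S"),
                   species = c("hs", "ec", "hs", "ec"),
                   stringsAsFactors = FALSE)
  # pair present in both routes
  both <- data.frame(protein_a = "P", protein_b = "Q",
                     stringsAsFactors = FALSE)
  m1 <- merge_with_fulllength(both, fl)
  expect_equal(m1$origin[m1$protein_a == "P" & m1$protein_b == "Q"], "both")
  expect_equal(nrow(m1[m1$protein_a == "P" & m1$protein_b == "Q", ]), 1L)

  # conflicting pair (P, S): both assigned, never together -> dropped
  confl <- data.frame(protein_a = "P", protein_b = "S",
                      stringsAsFactors = FALSE)
  m2 <- merge_with_fulllength(confl, fl)
  expect_false(any(pair_key_test(m2$protein_a, m2$protein_b) ==
                     pair_key_test("P", "S")))
  expect_setequal(m2$origin, "fulllength_only")

  # pair with an unassigned protein -> added as domain_only
  new <- data.frame(protein_a = "P", protein_b = "Znew",
                    stringsAsFactors = FALSE)
  m3 <- merge_with_fulllength(new, fl)
  expect_true(any(m3$origin == "domain_only"))
  # the merged set always contains every full-length pair
  for (m in list(m1, m2, m3)) {
    expect_true(all(c("P", "R") %in% m$protein_a))
    expect_equal(nrow(m) >= 2, TRUE)
  }
})

test_that("pair classification partitions the union of both pair sets", {
  fl <- data.frame(group_id = c(1L, 1L, 2L, 2L),
                   member_id = c("P", "Q", "R", "S"),
                   species = c("hs", "ec", "hs", "ec"),
                   stringsAsFactors = FALSE)
  dp <- data.frame(protein_a = c("P", "P", "P", "X"),
                   protein_b = c("Q", "S", "Ynew", "Ynew"),
                   stringsAsFactors = FALSE)
  cl <- classify_pairs(dp, fl)
  cat_of <- stats::setNames(cl$category,
                            pair_key_test(cl$protein_a, cl$protein_b))
  expect_equal(unname(cat_of[pair_key_test("P", "Q")]), "both")
  expect_equal(unname(cat_of[pair_key_test("R", "S")]), "fulllength_only")
  expect_equal(unname(cat_of[pair_key_test("P", "S")]), "domain_conflicting")
  expect_equal(unname(cat_of[pair_key_test("P", "Ynew")]),
               "domain_one_missing")
  expect_equal(unname(cat_of[pair_key_test("X", "Ynew")]),
               "domain_two_missing")
  # partition: one category per pair, counts sum to the union size
  expect_equal(nrow(cl), 5L)
  expect_false(any(duplicated(pair_key_test(cl$protein_a, cl$protein_b))))
})

test_that("jaccard consensus equals brute-force set computation", {
  mk <- function(a, b) data.frame(protein_a = a, protein_b = b,
                                  stringsAsFactors = FALSE)
  same <- mk(c("A", "B"), c("X", "Y"))
  expect_equal(jaccard_consensus(same, same), 1.0)
  expect_equal(jaccard_consensus(mk("A", "X"), mk("B", "Y")), 0.0)
  # |A|=|B|=3 sharing 2 -> 2/4
  a <- mk(c("p1", "p2", "p3"), c("q1", "q2", "q3"))
  b <- mk(c("p1", "p2", "p9"), c("q1", "q2", "q9"))
  expect_equal(jaccard_consensus(a, b), 0.5)
  # order of ids within a pair does not matter
  flipped <- mk(b$protein_b, b$protein_a)
  expect_equal(jaccard_consensus(a, flipped), 0.5)
  expect_error(jaccard_consensus(mk(character(0), character(0)),
                                 mk(character(0), character(0))),
               "undefined")

  set.seed(9)
  for (rep in 1:10) {
    pa <- unique(mk(sample(letters, 8, TRUE), sample(LETTERS, 8, TRUE)))
    pb <- unique(mk(sample(letters, 8, TRUE), sample(LETTERS, 8, TRUE)))
    ka <- unique(pair_key_test(pa$protein_a, pa$protein_b))
    kb <- unique(pair_key_test(pb$protein_a, pb$protein_b))
    expect_equal(jaccard_consensus(pa, pb),
                 length(intersect(ka, kb)) / length(union(ka, kb)))
  }
})

test_that("the alpha sweep is monotone and self-consistent", {
  ex <- alpha_worked_example()
  fl <- data.frame(group_id = 1L, member_id = c("X", "Y"),
                   species = c("hs", "ec"), stringsAsFactors = FALSE)
  sweep <- alpha_sweep(ex$groups, ex$domain_map, fl)
  expect_equal(nrow(sweep), 11L)
  expect_equal(sweep$threshold, seq(0, 1, by = 0.1))
  expect_true(all(diff(sweep$n_domain_pairs) <= 0))
  expect_equal(sweep$n_domain_pairs[1], max(sweep$n_domain_pairs))
  # jaccard column matches an independent recomputation per row
  for (i in seq_len(nrow(sweep))) {
    dp <- project_protein_pairs(ex$groups, ex$domain_map,
                                sweep$threshold[i])
    expected <- if (nrow(dp) == 0) 0 else jaccard_consensus(dp, data.frame(
      protein_a = "X", protein_b = "Y", stringsAsFactors = FALSE))
    expect_equal(sweep$jaccard[i], expected)
  }
})
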