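test_that("database parsing validates, collapses duplicates, reports line numbers", {
  dir <- withr::local_tempdir()
  rec <- data.frame(record_id = paste0("R", 1:5),
                    taxon_a_key = c("Tripos", "group i", "Phaeocystis",
                                    "Tripos", "teleaulax"),
                    taxon_a_rank = c("genus", "syndiniales_group", "genus",
                                     "genus", "genus"),
                    taxon_b_key = c("Teleaulax", "Gymnodinium",
                                    "Chaetoceros", "Teleaulax",
                                    "tripos"),
                    taxon_b_rank = "genus",
                    interaction_type = c("predation", "parasitism",
                                         "symbiosis", "predation",
                                         "predation"))
  p <- file.path(dir, "db.tsv")
  write.table(rec, p, sep = "\t", quote = FALSE, row.names = FALSE)
  db <- parseInteractionDB(p)
  # R1, R4 duplicate; R5 is R1 reversed with different case -> same record
  expect_identical(nrow(dbRecords(db)), 3L)
  expect_identical(dbRecords(db)$multiplicity[
    dbRecords(db)$record_id == "R1"], 3L)

  bad <- rec
  bad$interaction_type[3] <- "commensalism"
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parseInteractionDB(p), "'commensalism' at line 4")

  bad2 <- rec
  bad2$taxon_a_rank[2] <- "order"
  write.table(bad2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parseInteractionDB(p), "unknown taxon rank at line 3")
})

test_that("all four matching rules fire with the right precedence and type folding", {
  keys <- ruleFixtureTaxonomy()
  db <- ruleFixtureDb(withr::local_tempdir())
  edges <- data.frame(
    asv_a = c("synd", "acanth", "mast", "dino", "tripos", "stub"),
    asv_b = c("tripos", "phaeo", "chaeto", "tele", "tele", "phaeo"))
  ann <- matchEdges(edges, keys, db)

  expect_identical(ann$status,
                   c("supported", "supported", "supported", "supported",
                     "novel", "novel"))
  expect_identical(ann$match_rule[1:4],
                   c("syndiniales_group_host_genus",
                     "radiolarian_class_symbiont_genus",
                     "mast_clade_symbiont_genus", "genus_genus"))
  expect_identical(ann$reported_type[1:4],
                   c("parasitism", "other_symbioses", "other_symbioses",
                     "other_symbioses"))
  expect_identical(ann$reason[6], "rank-unresolvable")
  # never report the raw "unresolved"/"symbiosis" labels
  expect_false(any(grepl("unresolved|^symbiosis",
                         na.omit(ann$reported_type))))
  # partition: supported + novel = all edges
  expect_identical(sum(ann$status == "supported") +
                     sum(ann$status == "novel"), nrow(edges))

  # symmetry in edge orientation
  annRev <- matchEdges(data.frame(asv_a = edges$asv_b,
                                  asv_b = edges$asv_a), keys, db)
  expect_identical(annRev$status, ann$status)
  expect_identical(annRev$match_rule, ann$match_rule)
  expect_identical(annRev$reported_type, ann$reported_type)

  expect_error(matchEdges(data.frame(asv_a = "ghost", asv_b = "tripos"),
                          keys, db), "missing from taxonomy")
})

test_that("recall summary counts records, realizable records, and found edges", {
  keys <- ruleFixtureTaxonomy()
  dir <- withr::local_tempdir()
  rec <- data.frame(
    record_id = paste0("R", 1:4),
    taxon_a_key = c("group ii", "Dinophysis", "Absentia", "Nullomonas"),
    taxon_a_rank = c("syndiniales_group", "genus", "genus", "genus"),
    taxon_b_key = c("Tripos", "Teleaulax", "Tripos", "Vacuopsis"),
    taxon_b_rank = "genus",
    interaction_type = c("parasitism", "parasitism", "parasitism",
                         "predation"))
  p <- file.path(dir, "db.tsv")
  write.table(rec, p, sep = "\t", quote = FALSE, row.names = FALSE)
  db <- parseInteractionDB(p)
  # network found only the Syndiniales edge
  ann <- matchEdges(data.frame(asv_a = "synd", asv_b = "tripos"), keys, db)
  summ <- summarizeRecall(ann, db, keys)
  para <- summ[summ$type == "parasitism", ]
  expect_identical(c(para$db_records, para$db_records_realizable,
                     para$supported_edges), c(3L, 2L, 1L))
  expect_identical(summ$supported_edges[summ$type == "predation"], 0L)

  # empty database -> all zeros
  empty <- new("InteractionDB",
               records = dbRecords(db)[0, ], provenance = "empty")
  ann0 <- matchEdges(data.frame(asv_a = "synd", asv_b = "tripos"), keys,
                     empty)
  s0 <- summarizeRecall(ann0, empty, keys)
  expect_true(all(s0$db_records == 0 & s0$supported_edges == 0))
})

test_that("SCC ranking: oracle value, inclusive threshold, constant exclusion", {
  # frozen from the rank-difference formula: 1 - 6*4/(5*24) = 0.8
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(oracleSpearman(x, y), 0.8, tolerance = 1e-12)

  clr <- cbind(a = x, b = y, c = 2 * x + 1, d = rep(1, 5),
               e = c(5, 4, 3, 1, 2))
  ann <- data.frame(asv_a = c("a", "a", "a", "a"),
                    asv_b = c("b", "c", "d", "e"),
                    status = "novel", match_rule = NA, matched_records = NA,
                    reported_type = NA, scc = NA_real_,
                    partial_cor = NA_real_, reason = NA)
  ranked <- novelEdgeScc(ann, clr, report_threshold = 0.8)
  # constant-series edge excluded, rest sorted by |SCC| descending
  expect_identical(nrow(ranked), 3L)
  expect_identical(nrow(attr(ranked, "excluded")), 1L)
  expect_identical(ranked$asv_b, c("c", "e", "b"))
  expect_equal(ranked$scc, c(1, -0.9, 0.8), tolerance = 1e-12)
  # inclusive bound: |SCC| >= 0.8 flags the monotone pair AND the 0.8 tie,
  # and the -0.9 on magnitude
  expect_identical(ranked$strong, c(TRUE, TRUE, TRUE))
  ranked2 <- novelEdgeScc(ann, clr, report_threshold = 0.85)
  expect_identical(ranked2$strong, c(TRUE, TRUE, FALSE))
})
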