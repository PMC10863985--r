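test_that("essential set requires presence in at least two species", {
  orth <- c(a1 = "G1", a2 = "G1", b1 = "G2", c1 = "G3", c2 = "G3")
  rec <- data.frame(
    species_id = c("spA", "spB", "spA", "spA", "spB"),
    accession = c("a1", "a2", "b1", "c1", "c2"))
  ess <- compile_essential_set(rec, orth, 2)
  expect_setequal(ess, c("G1", "G3"))   # G2 only in one species
  # unresolvable accessions are reported and skipped
  rec2 <- rbind(rec, data.frame(species_id = "spA", accession = "zz"))
  expect_warning(ess2 <- compile_essential_set(rec2, orth, 2),
                 "not resolvable")
  expect_setequal(ess2, ess)
  # duplicated rows do not inflate species counts
  rec3 <- rbind(rec, rec[3, ], rec[3, ])
  expect_false("G2" %in% compile_essential_set(rec3, orth, 2))
  expect_warning(out <- compile_essential_set(rec[0, ], orth, 2), "empty")
  expect_length(out, 0)
})

test_that("edge filter applies strict and/or thresholds, essentiality and family exclusion", {
  ess <- c("G1", "G2", "G3", "G4", "G5")
  fam <- c(G1 = "other", G2 = "other", G3 = "ribosomal", G4 = "other",
           G5 = "other", G9 = "other")
  e <- candidate_edges(
    group_a = c("G1", "G1", "G1", "G1", "G2", "G4"),
    group_b = c("G2", "G4", "G3", "G9", "G4", "G5"),
    combined_score = c(0.8, 0.5, 0.9, 0.9, 0.7, 0.71),
    experimental_score = c(0.0, 0.10, 0.0, 0.0, 0.15, 0.0),
    species_support = "sp1")
  kept <- filter_string_edges(e, ess, edge_filter_config(), fam)
  key <- paste(kept$group_a, kept$group_b)
  expect_true("G1 G2" %in% key)          # combined 0.8 > 0.7
  expect_false("G1 G4" %in% key)         # fails both thresholds
  expect_false("G1 G3" %in% key)         # ribosomal endpoint
  expect_false("G1 G9" %in% key)         # G9 not essential
  expect_false("G2 G4" %in% key)         # 0.7 / 0.15 exactly: strict ">"
  expect_true("G4 G5" %in% key)          # 0.71 just above the threshold
})

test_that("edge filter is idempotent and invariant to row/endpoint order", {
  set.seed(42)
  ess <- sprintf("G%d", 1:10)
  ga <- sample(ess, 30, TRUE); gb <- sample(ess, 30, TRUE)
  sel <- ga != gb
  e <- candidate_edges(ga[sel], gb[sel],
                       combined_score = runif(sum(sel)),
                       experimental_score = runif(sum(sel), 0, 0.3),
                       species_support = "sp1")
  f1 <- filter_string_edges(e, ess, edge_filter_config())
  f2 <- filter_string_edges(f1, ess, edge_filter_config())
  expect_equal(f1, f2)
  # shuffle rows and swap endpoints: same result
  es <- e[sample(nrow(e)), ]
  tmp <- es$group_a; es$group_a <- es$group_b; es$group_b <- tmp
  f3 <- filter_string_edges(es, ess, edge_filter_config())
  expect_equal(f1, f3)
})

test_that("consensus keeps edges supported by enough species and unions support", {
  e1 <- candidate_edges("G1", "G2", 0.9, 0, "sp1")
  e2 <- candidate_edges("G2", "G1", 0.8, 0, "sp2")
  e3 <- candidate_edges("G3", "G4", 0.9, 0, "sp1")
  cons <- consensus_edges(list(sp1 = rbind(e1, e3), sp2 = e2), 2)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$species_support, "sp1;sp2")
  expect_equal(cons$combined_score, 0.9)  # max kept
  # min support 1 is a deduplicating union
  cons1 <- consensus_edges(list(sp1 = rbind(e1, e3), sp2 = e2), 1)
  expect_equal(nrow(cons1), 2)
})

test_that("synthetic-lethal pairs bypass essentiality and merge with duplicates", {
  orth <- c(x1 = "G7", y1 = "G8", z1 = "G1")
  base <- candidate_edges("G1", "G7", 0.9, 0, "sp1")
  out <- merge_synthetic_lethal(base, data.frame(a = "x1", b = "y1"), orth)
  expect_equal(nrow(out), 2)
  expect_true("synthetic_lethal" %in% out$origin)
  # duplicate against an existing edge merges origins
  out2 <- merge_synthetic_lethal(base, data.frame(a = "z1", b = "x1"), orth)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$origin, "string_evidence;synthetic_lethal")
  # empty list unchanged; self-pair is an error
  expect_equal(merge_synthetic_lethal(base, NULL, orth), base)
  orth2 <- c(x1 = "G7", y1 = "G7")
  expect_error(merge_synthetic_lethal(base, data.frame(a = "x1", b = "y1"),
                                      orth2), "self-pair")
  # sl edges survive both the essentiality filter and the consensus rule
  kept <- filter_string_edges(out, essential = "G1", edge_filter_config())
  expect_true("synthetic_lethal" %in% kept$origin)
  cons <- consensus_edges(list(sp1 = out), 2)
  expect_true(any(grepl("synthetic_lethal", cons$origin)))
})

test_that("random negatives enumerate the feasible complement and are seeded", {
  pos <- data.frame(a = "a", b = "b")
  neg <- generate_random_negatives(c("a", "b", "c"), 2, pos, seed = 3)
  expect_setequal(paste(neg$group_a, neg$group_b), c("a c", "b c"))
  expect_equal(nrow(generate_random_negatives(c("a", "b", "c"), 0)), 0)
  expect_error(generate_random_negatives(c("a", "b", "c"), 3, pos),
               "only 2")
  n1 <- generate_random_negatives(letters[1:10], 5, seed = 11)
  n2 <- generate_random_negatives(letters[1:10], 5, seed = 11)
  expect_identical(n1, n2)
})

test_that("negatives never intersect positives over many random instances", {
  for (s in 1:20) {
    set.seed(s)
    prots <- sprintf("P%02d", 1:12)
    pairs <- t(combn(prots, 2))
    pos <- as.data.frame(pairs[sample(nrow(pairs), 20), ])
    neg <- generate_random_negatives(prots, 30, pos, seed = s)
    expect_equal(nrow(neg), 30)
    expect_length(intersect(paste(neg$group_a, neg$group_b),
                            paste(pmin(pos[[1]], pos[[2]]),
                                  pmax(pos[[1]], pos[[2]]))), 0)
    expect_true(all(neg$group_a != neg$group_b))
  }
})

test_that("STRING reader normalizes 0-1000 integer scores and maps accessions", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(protein1 = c("a1", "a1"), protein2 = c("b1", "c1"),
                         experimental = c(200L, 0L), combined = c(950L, 400L)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  orth <- c(a1 = "G1", b1 = "G2", c1 = "G3")
  e <- read_string_edges(f, "sp1", orth)
  expect_equal(sort(e$combined_score), c(0.40, 0.95))
  expect_equal(max(e$experimental_score), 0.20)
  # real-valued dialect passes through unchanged
  write.table(data.frame(protein1 = "a1", protein2 = "b1",
                         experimental = 0.2, combined = 0.95),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  e2 <- read_string_edges(f, "sp1", orth)
  expect_equal(e2$combined_score, 0.95)
  # edge TSV round trip
  out <- tempfile(fileext = ".tsv")
  write_edges_tsv(e, out)
  expect_equal(read_edges_tsv(out), as.data.frame(e), ignore_attr = TRUE)
})
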