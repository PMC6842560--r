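test_that("identical sequences across species form a reciprocal best pair", {
  set.seed(67)
  s <- random_peptide(80)
  pairs <- bbh_orthologs(c(x = s), c(xp = s), evalue_threshold = 1e-3)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$id_a, "x")
  expect_equal(pairs$id_b, "xp")
})

test_that("non-reciprocal best hits yield no pair", {
  # a's best is b, but b's best is c (b == c region is longer/stronger)
  set.seed(71)
  core <- random_peptide(60)
  a <- paste0(core, random_peptide(20))
  c_seq <- paste0(core, random_peptide(60))
  b <- c_seq  # b's best in {a, c} is c (full-length identity), a's best is b
  pairs <- bbh_orthologs(c(a = a, c = c_seq), c(b = b), evalue_threshold = 1)
  expect_false("a" %in% pairs$id_a)
  expect_true(all(pairs$id_a == "c"))
})

test_that("equal-score best-hit ties disqualify the gene", {
  set.seed(73)
  s <- random_peptide(70)
  other <- random_peptide(70)
  pairs <- bbh_orthologs(c(x = s), c(y1 = s, y2 = s, z = other),
                         evalue_threshold = 1)
  expect_equal(nrow(pairs), 0)
  expect_true("x" %in% attr(pairs, "ties"))
})

test_that("orthology is symmetric and monotone in the E-value threshold", {
  g <- generate_family_data(small_config(seed = 6))
  members <- g$proteins[g$manifest$members$id]
  fwd <- bbh_orthologs(members, g$species_b)
  rev <- bbh_orthologs(g$species_b, members)
  expect_setequal(paste(fwd$id_a, fwd$id_b), paste(rev$id_b, rev$id_a))
  loose <- bbh_orthologs(members, g$species_b, evalue_threshold = 1e-5)
  tight <- bbh_orthologs(members, g$species_b, evalue_threshold = 1e-60)
  expect_true(all(paste(tight$id_a, tight$id_b) %in% paste(loose$id_a, loose$id_b)))
})

test_that("planted ortholog pairs are recovered exactly", {
  g <- generate_family_data(small_config(seed = 7))
  members <- g$proteins[g$manifest$members$id]
  pairs <- bbh_orthologs(members, g$species_b)
  expect_setequal(paste(pairs$id_a, pairs$id_b),
                  paste(g$manifest$ortholog_pairs$id_a, g$manifest$ortholog_pairs$id_b))
})

test_that("the 65/65 rule keeps identical pairs and is strict at the boundary", {
  set.seed(79)
  s <- random_peptide(100)
  kept <- duplication_pairs(c(a = s, b = s))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$coverage_longer, 1)
  expect_equal(kept$similarity_fraction, 1)
  # engineered boundary: identical 13-residue prefix within a 20-residue
  # sequence gives coverage exactly 13/20 = 0.65 -> rejected (strict)
  um <- unit_matrix()
  prefix <- random_peptide(13)
  long <- paste0(prefix, random_peptide(7))
  short <- prefix
  aln <- local_align(long, short, matrix = um, gap_open = 10, gap_extend = 5)
  expect_equal(aln$coverage_longer, 0.65)
  expect_equal(nrow(duplication_pairs(c(a = long, b = short), matrix = um,
                                      gap_open = 10, gap_extend = 5)), 0)
  # one more shared residue tips coverage to 14/20 = 0.70 -> kept
  prefix14 <- random_peptide(14)
  long2 <- paste0(prefix14, random_peptide(6))
  kept2 <- duplication_pairs(c(a = long2, b = prefix14), matrix = um,
                             gap_open = 10, gap_extend = 5)
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$coverage_longer, 0.7)
})

test_that("planted duplicates pass and unrelated members fail the 65/65 rule", {
  g <- generate_family_data(small_config(seed = 8))
  man <- g$manifest
  dp <- duplication_pairs(g$proteins[man$members$id])
  expect_setequal(pair_key(dp$id_a, dp$id_b),
                  pair_key(man$duplicate_pairs$id_a, man$duplicate_pairs$id_b))
})

test_that("duplication categories follow the placement rules", {
  gm <- list(
    a = gene_model("a", "chr01", 10000, 11000, "+", cbind(10000, 11000)),
    b = gene_model("b", "chr01", 20000, 21000, "+", cbind(20000, 21000)),
    c = gene_model("c", "chr05", 10000, 11000, "+", cbind(10000, 11000)),
    d = gene_model("d", "chr01", 5200000, 5201000, "+", cbind(5200000, 5201000)),
    e = gene_model("e", NA, 1, 1000, "+", cbind(1, 1000))
  )
  pairs <- data.frame(id_a = c("a", "a", "a"), id_b = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  out <- classify_duplication(pairs, gm)
  expect_equal(out$category, c("tandem", "segmental", "proximal"))
  expect_error(classify_duplication(data.frame(id_a = "a", id_b = "e"), gm),
               "unplaced")
  # a second family gene in between: still tandem with one intervening,
  # proximal once max_intervening = 0
  out1 <- classify_duplication(data.frame(id_a = "a", id_b = "b"), gm,
                               family_ids = c("a", "b", "f"))
  expect_equal(out1$category, "tandem")
  gm$f <- gene_model("f", "chr01", 15000, 15500, "+", cbind(15000, 15500))
  out2 <- classify_duplication(data.frame(id_a = "a", id_b = "b"), gm,
                               family_ids = c("a", "b", "f"),
                               max_intervening = 0)
  expect_equal(out2$category, "proximal")
})

test_that("planted tandem and segmental pairs are categorized as planted", {
  g <- generate_family_data(small_config(seed = 9))
  man <- g$manifest
  dp <- duplication_pairs(g$proteins[man$members$id])
  dc <- classify_duplication(dp, g$gene_models, family_ids = man$members$id)
  truth <- man$duplicate_pairs
  found_cat <- setNames(dc$category, pair_key(dc$id_a, dc$id_b))
  truth_key <- pair_key(truth$id_a, truth$id_b)
  expect_true(all(truth_key %in% names(found_cat)))
  expect_equal(unname(found_cat[truth_key]), truth$category)
})

test_that("cluster chaining follows start-to-start gaps", {
  mk <- function(id, chr, start) gene_model(id, chr, start, start + 1000, "+",
                                            cbind(start, start + 1000))
  # gap 150 kb: one cluster of two
  cl <- detect_clusters(list(a = mk("a", "chr01", 100000), b = mk("b", "chr01", 250000)))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c("a", "b"))
  # gap 250 kb: no cluster
  expect_length(detect_clusters(list(a = mk("a", "chr01", 100000),
                                     b = mk("b", "chr01", 350000))), 0)
  # chaining: 0 / 150k / 300k all in one cluster of three
  cl3 <- detect_clusters(list(a = mk("a", "chr01", 1), b = mk("b", "chr01", 150001),
                              c = mk("c", "chr01", 300001)))
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$members, c("a", "b", "c"))
  # different chromosomes never merge; unplaced genes are ignored
  mixed <- detect_clusters(list(a = mk("a", "chr01", 1), b = mk("b", "chr02", 50000),
                                u = gene_model("u", NA, 1, 100, "+", cbind(1, 100))))
  expect_length(mixed, 0)
})

test_that("every gene lands in at most one detected cluster", {
  g <- generate_family_data(small_config(seed = 10))
  cl <- detect_clusters(g$gene_models[g$manifest$members$id])
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0)
  # and the planted clusters are recovered exactly
  found <- sort(vapply(cl, function(x) paste(sort(x$members), collapse = ","), ""))
  planted <- sort(vapply(g$manifest$clusters,
                         function(x) paste(sort(x$members), collapse = ","), ""))
  expect_equal(found, planted)
})
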