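make_seed <- function(rows) seed_alignment(sprintf("s%d", seq_along(rows)), rows)

test_that("PSSM scores follow the pseudocount log-odds formula", {
  # column of 4 M and one gap, beta = 1, uniform background:
  # p_hat = (4 + 0.05) / 5, score = log2(p_hat / 0.05)
  seed <- make_seed(c("M", "M", "M", "M", "-"))
  # a single all-gap-minority column is a match column
  pssm <- build_pssm(seed, pseudocount_weight = 1)
  expect_equal(unname(pssm$scores[1, "M"]), log2(((4 + 0.05) / 5) / 0.05),
               tolerance = 1e-12)
  expect_equal(round(unname(pssm$scores[1, "M"]), 3), 4.018)
  # unobserved residue: p_hat = (0 + 0.05)/5
  expect_equal(unname(pssm$scores[1, "A"]), log2((0.05 / 5) / 0.05), tolerance = 1e-12)
})

test_that("PSSM probability estimates normalize in every column", {
  set.seed(7)
  rows <- replicate(6, random_peptide(12))
  pssm <- build_pssm(make_seed(rows), pseudocount_weight = 2)
  for (w in seq_len(nrow(pssm$scores))) {
    p_hat <- 2^pssm$scores[w, ] * pssm$background
    expect_equal(sum(p_hat), 1, tolerance = 1e-9)
  }
})

test_that("column counts at background expectation give vanishing scores", {
  # 20 rows, one of each residue == exact background composition; with a
  # large pseudocount the estimate is pinned to the background
  rows <- as.list(genefamkit:::AA20)
  pssm <- build_pssm(make_seed(unlist(rows)), pseudocount_weight = 1e9)
  expect_true(all(abs(pssm$scores) < 1e-6))
})

test_that("build_pssm validates its inputs", {
  expect_error(build_pssm(make_seed(c("M"))), "2 rows")
  bad_bg <- setNames(rep(0.06, 20), genefamkit:::AA20)
  expect_error(build_pssm(make_seed(c("MM", "MM")), background = bad_bg),
               "sum to 1")
})

test_that("profile scanning finds the consensus and rejects noise", {
  set.seed(11)
  rows <- replicate(8, random_peptide(20))
  pssm <- build_pssm(make_seed(rows))
  cons <- setNames(pssm$consensus, "cons")
  hits <- scan_protein(cons, pssm, min_bits = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$start, hits$end), c(1L, 20L))
  expect_equal(hits$bit_score, pssm$max_score, tolerance = 1e-9)
  # all-X protein scores 0 everywhere: rejected at any positive threshold
  xs <- setNames(strrep("X", 30), "xs")
  expect_equal(nrow(scan_protein(xs, pssm, min_bits = 1e-9)), 0)
  expect_equal(scan_protein(xs, pssm, min_bits = -1)$bit_score[1], 0)
  # shorter than the profile: empty result, not an error
  expect_equal(nrow(scan_protein(c(p = "MKV"), pssm, 0)), 0)
})

test_that("scanning a planted domain recovers the recorded offset", {
  g <- generate_family_data(small_config(seed = 5))
  pssm <- build_pssm(g$seed_mads)
  man <- g$manifest$members
  for (i in seq_len(nrow(man))) {
    hits <- scan_protein(setNames(g$proteins[man$id[i]], man$id[i]), pssm,
                         min_bits = 0.5 * pssm$max_score)
    expect_equal(hits$start[which.max(hits$bit_score)], man$domain_offset[i])
  }
})

test_that("reversed consensus scores strictly below the consensus", {
  set.seed(13)
  pssm <- build_pssm(make_seed(replicate(8, random_peptide(15))))
  fwd <- scan_protein(c(a = pssm$consensus), pssm, min_bits = -Inf)
  rev_seq <- paste(rev(strsplit(pssm$consensus, "")[[1]]), collapse = "")
  bwd <- scan_protein(c(b = rev_seq), pssm, min_bits = -Inf)
  expect_lt(max(bwd$bit_score), max(fwd$bit_score))
})

test_that("local alignment matches the spec identities on toy cases", {
  um <- unit_matrix()
  aln <- local_align("ACDEFG", "ACDEFG", matrix = um, gap_open = 2, gap_extend = 1)
  expect_equal(aln$score, 6)
  expect_equal(aln$identity_fraction, 1)
  expect_equal(aln$coverage_longer, 1)
  # nothing aligns: empty alignment at score 0
  none <- local_align("ACG", "TTT", matrix = um, gap_open = 2, gap_extend = 1)
  expect_equal(none$score, 0)
  expect_equal(none$n_columns, 0L)
  expect_equal(none$identity_fraction, 0)
})

test_that("local alignment equals independent oracles on random pairs", {
  um <- unit_matrix()
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(17)
  reduced <- c("A", "C", "D", "G")
  for (rep in 1:12) {
    a <- random_peptide(sample(3:6, 1), reduced)
    b <- random_peptide(sample(3:6, 1), reduced)
    enum <- oracle_local_enum(a, b, um, open = 2, ext = 1)
    gotoh <- oracle_local_gotoh(a, b, um, open = 2, ext = 1)
    mine <- local_align(a, b, matrix = um, gap_open = 2, gap_extend = 1)
    expect_equal(enum, gotoh)
    expect_equal(mine$score, enum)
  }
  # longer pairs against the Gotoh oracle, under BLOSUM62
  for (rep in 1:10) {
    a <- random_peptide(sample(8:12, 1))
    b <- random_peptide(sample(8:12, 1))
    gotoh <- oracle_local_gotoh(a, b, BLOSUM62, open = 11, ext = 1)
    mine <- local_align(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1)
    expect_equal(mine$score, gotoh)
  }
})

test_that("local alignment score is symmetric", {
  set.seed(19)
  for (rep in 1:5) {
    a <- random_peptide(30); b <- random_peptide(25)
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("E-values honor the Karlin-Altschul identities", {
  expect_equal(evalue(1e6, 100, 100), 100 * 100 * 2^-1e6)
  expect_equal(evalue(log2(100 * 100), 100, 100), 1)
  # frozen regression value for fixed constants, computed once by hand:
  # bits = (26.7 + 3.194183)/0.6931472 = 43.12829; E = 1e4 * 2^-bits
  bits <- raw_to_bits(100)
  expect_equal(bits, (0.267 * 100 - log(0.041)) / log(2))
  expect_equal(evalue(bits, 100, 100) / 1.040210e-09, 1, tolerance = 1e-6)
})

test_that("family identification recovers exactly the planted members", {
  g <- generate_family_data(small_config(seed = 2))
  pssm <- build_pssm(g$seed_mads)
  res <- identify_family(g$proteins, pssm, g$refs)
  expect_setequal(res$ids, g$manifest$members$id)
  # truncated-domain plants are excluded
  expect_false(any(g$manifest$truncated %in% res$ids))
})

test_that("raising thresholds never enlarges the identified set", {
  g <- generate_family_data(small_config(seed = 4))
  pssm <- build_pssm(g$seed_mads)
  base <- identify_family(g$proteins, pssm, g$refs,
                          config = list(profile_min_bits = 0.3 * pssm$max_score,
                                        blast_evalue = 1e-2))
  stricter_bits <- identify_family(g$proteins, pssm, g$refs,
                                   config = list(profile_min_bits = 0.6 * pssm$max_score,
                                                 blast_evalue = 1e-2))
  stricter_e <- identify_family(g$proteins, pssm, g$refs,
                                config = list(profile_min_bits = 0.3 * pssm$max_score,
                                              blast_evalue = 1e-30))
  expect_true(all(stricter_bits$ids %in% base$ids))
  expect_true(all(stricter_e$ids %in% base$ids))
})

test_that("positional renaming orders by chromosome then start, unplaced last", {
  gm <- list(
    a = gene_model("a", "chr2", 500, 600, "+", cbind(500, 600)),
    b = gene_model("b", "chr2", 100, 200, "+", cbind(100, 200)),
    c = gene_model("c", "chr10", 50, 80, "+", cbind(50, 80)),
    d = gene_model("d", NA, 1, 10, "+", cbind(1, 10)),
    e = gene_model("e", NA, 1, 10, "+", cbind(1, 10))
  )
  map <- rename_by_position(c("a", "b", "c", "d", "e"), gm, "FAM")
  # natural sort: chr2 before chr10; within chr2 by start; unplaced by id
  expect_equal(map, c(b = "FAM1", a = "FAM2", c = "FAM3", d = "FAM4", e = "FAM5"))
  # input order never matters
  map2 <- rename_by_position(c("e", "c", "a", "d", "b"), gm, "FAM")
  expect_equal(map2, map)
  expect_error(rename_by_position(c("a", "a"), gm, "FAM"), "duplicate")
  expect_error(rename_by_position(c("a", "zz"), gm, "FAM"), "zz")
})

test_that("56 placed plus 4 unplaced genes number 1..60 with unplaced last", {
  gm <- list()
  ids <- sprintf("g%02d", 1:60)
  set.seed(23)
  for (i in 1:56) {
    st <- sample(1e6, 1)
    gm[[ids[i]]] <- gene_model(ids[i], sprintf("chr%02d", ((i - 1) %% 19) + 1),
                               st, st + 100, "+", cbind(st, st + 100))
  }
  for (i in 57:60) gm[[ids[i]]] <- gene_model(ids[i], NA, 1, 100, "+", cbind(1, 100))
  map <- rename_by_position(ids, gm, "FAM")
  expect_equal(unname(map[ids[57:60]]), paste0("FAM", 57:60))
  expect_equal(sort(as.integer(sub("FAM", "", map))), 1:60)
})
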