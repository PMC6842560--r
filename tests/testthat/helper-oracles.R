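# Independent oracles and small fixtures used across the suite.

# full 21-letter unit substitution matrix: match +1, mismatch -1, X neutral
unit_matrix <- function(match = 1, mismatch = -1) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  m <- matrix(mismatch, 21, 21, dimnames = list(aa, aa))
  diag(m) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

# Brute-force local alignment score by exhaustive enumeration over all
# strictly increasing matched-pair sets; unmatched residues between
# consecutive pairs form one gap run per sequence, each costing
# open + ext * length. Exponential: only for short sequences.
oracle_local_enum <- function(a, b, M, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  rec <- function(pi, pj, sc) {
    if (sc > best) best <<- sc
    if (pi >= n || pj >= m) return()
    for (ii in (pi + 1):n) {
      for (jj in (pj + 1):m) {
        da <- ii - pi - 1; db <- jj - pj - 1
        g <- (da > 0) * (open + ext * da) + (db > 0) * (open + ext * db)
        rec(ii, jj, sc + M[av[ii], bv[jj]] - g)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, M[av[i], bv[j]])
  max(best, 0)
}

# Gotoh three-state dynamic program, coded from the recurrences; a second,
# independent route to the local alignment score for medium lengths
oracle_local_gotoh <- function(a, b, M, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + M[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# dense grid search for the isoelectric point
oracle_pi_grid <- function(protein, n_grid = 1e5) {
  grid <- seq(0, 14, length.out = n_grid)
  q <- genefamkit::protein_charge(protein, grid)
  grid[which.min(abs(q))]
}

# positional enumeration of fixed-motif matches
oracle_motif_positions <- function(seq, pattern_chars) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(pattern_chars)
  if (length(chars) < len) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(length(chars) - len + 1)) {
    win <- chars[s:(s + len - 1)]
    ok <- all(pattern_chars == "." | pattern_chars == win)
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_peptide <- function(n, alphabet = genefamkit:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small, fast generator configuration for unit tests
small_config <- function(seed = 1, ...) {
  generator_config(
    seed = seed,
    n_per_class = setNames(c(2L, 1L, 1L, 4L, 1L), family_classes()),
    n_decoys = 8L, n_truncated = 1L,
    n_chromosomes = 4L,
    n_tandem_dups = 1L, n_segmental_dups = 1L,
    cluster_sizes = c(2L),
    n_b_decoys = 5L, n_qpcr_genes = 2L,
    ...
  )
}

fixture_table_path <- function() {
  system.file("extdata", "willow_family_table.tsv", package = "genefamkit")
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
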