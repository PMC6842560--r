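# Family-member identification: position-specific scoring matrix built from
# a seed alignment, gapless profile scanning, Smith-Waterman local alignment
# with Karlin-Altschul E-values, intersection of the two evidence sources,
# a domain-completeness filter, and positional renaming.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# gapped Karlin-Altschul constants for BLOSUM62 with gap open 11 / extend 1,
# the BLASTp defaults
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Log-odds profile over the seed's match columns. For residue \eqn{a} in
#' column \eqn{c}, the score in bits is \eqn{\log_2(\hat p / q_a)} with
#' \eqn{\hat p = (n_{c,a} + \beta q_a) / (n_c + \beta)}, where \eqn{n_c} is
#' the number of residues observed in the column and \eqn{\beta} the
#' pseudocount weight. A gapless profile scan over a compact, strongly
#' conserved domain is the discriminative core of family identification;
#' truncated domains are caught downstream by the completeness filter of
#' \code{\link{identify_family}}.
#'
#' @param seed A \code{\link{seed_alignment}}.
#' @param pseudocount_weight Positive pseudocount mass \eqn{\beta}.
#' @param background Named vector of 20 background probabilities summing to
#'   1; uniform by default.
#' @return An object of class \code{"pssm"}: list with \code{scores}
#'   (width x 20 matrix, bits), \code{background}, \code{pseudocount_weight},
#'   \code{consensus} and \code{max_score}.
#' @export
build_pssm <- function(seed, pseudocount_weight = 1,
                       background = setNames(rep(1 / 20, 20), AA20)) {
  stopifnot(inherits(seed, "seed_alignment"))
  if (length(seed$aligned) < 2) stop("seed alignment needs at least 2 rows")
  background <- background[AA20]
  if (anyNA(background) || any(background <= 0)) {
    stop("background must assign positive probability to all 20 residues")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (pseudocount_weight <= 0) stop("pseudocount_weight must be positive")
  mat <- do.call(rbind, strsplit(seed$aligned, ""))[, seed$match_columns, drop = FALSE]
  width <- ncol(mat)
  scores <- matrix(0, nrow = width, ncol = 20, dimnames = list(NULL, AA20))
  beta <- pseudocount_weight
  for (w in seq_len(width)) {
    col <- mat[, w]
    counts <- table(factor(col[col %in% AA20], levels = AA20))
    n_c <- sum(counts)
    p_hat <- (as.numeric(counts) + beta * background) / (n_c + beta)
    scores[w, ] <- log2(p_hat / background)
  }
  structure(list(scores = scores, background = background,
                 pseudocount_weight = beta,
                 consensus = paste(AA20[apply(scores, 1, which.max)], collapse = ""),
                 max_score = sum(apply(scores, 1, max))),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> width %d, max attainable score %.1f bits\n",
              nrow(x$scores), x$max_score))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Scan a protein with a PSSM
#'
#' Gapless sliding-window scan: every window of the profile width is scored
#' as the sum of per-column log-odds; \code{'X'} contributes 0 at every
#' column. Windows scoring at least \code{min_bits} are reported, with
#' chains of mutually overlapping windows merged down to the best-scoring
#' window of each chain. A sequence shorter than the profile yields no hits.
#'
#' @param protein Length-1 character vector (optionally named with the
#'   protein id).
#' @param pssm A \code{\link{build_pssm}} profile.
#' @param min_bits Score threshold in bits.
#' @return data.frame with columns \code{protein_id}, \code{start},
#'   \code{end} (1-based inclusive), \code{bit_score}, \code{source}.
#' @export
scan_protein <- function(protein, pssm, min_bits) {
  stopifnot(inherits(pssm, "pssm"), length(protein) == 1)
  id <- names(protein) %||% ""
  scores <- window_scores(protein, pssm)
  keep <- which(scores >= min_bits)
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), bit_score = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  width <- nrow(pssm$scores)
  # merge chains of overlapping windows, keeping the best window per chain
  chain_break <- c(TRUE, diff(keep) >= width)
  chain_id <- cumsum(chain_break)
  best <- vapply(split(keep, chain_id), function(idx) idx[which.max(scores[idx])],
                 numeric(1))
  data.frame(protein_id = id, start = as.integer(best),
             end = as.integer(best + width - 1),
             bit_score = unname(scores[best]), source = "profile",
             stringsAsFactors = FALSE, row.names = NULL)
}

# scores of every window position (length L - width + 1), 'X' scoring 0
window_scores <- function(protein, pssm) {
  chars <- strsplit(unname(protein), "")[[1]]
  width <- nrow(pssm$scores)
  nw <- length(chars) - width + 1
  if (nw < 1) return(numeric(0))
  idx <- match(chars, AA20)  # NA for 'X' and friends
  total <- numeric(nw)
  for (w in seq_len(width)) {
    col <- pssm$scores[w, ]
    sc <- col[idx[w:(w + nw - 1)]]
    sc[is.na(sc)] <- 0
    total <- total + sc
  }
  total
}

#' Substitution matrix lookup
#'
#' Returns a numeric substitution matrix: either a named matrix from
#' \pkg{Biostrings} (e.g. \code{"BLOSUM62"}) or the matrix given.
#' @param matrix Matrix name or numeric matrix.
#' @return Numeric substitution matrix.
#' @keywords internal
resolve_matrix <- function(matrix) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  } else {
    stopifnot(is.matrix(matrix))
    matrix
  }
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two proteins under an affine gap model in
#' which opening a gap costs \code{gap_open + gap_extend} and each further
#' gapped position \code{gap_extend}. Besides the raw score the result
#' carries the derived quantities used throughout the pipeline:
#' \describe{
#'   \item{identity_fraction}{identical aligned pairs / aligned columns}
#'   \item{similarity_fraction}{positive-scoring substitution pairs /
#'     aligned columns (the BLAST "positives" notion of similarity)}
#'   \item{coverage_longer}{aligned span on the longer sequence / length of
#'     the longer sequence}
#' }
#' An all-negative comparison yields the empty alignment with score 0.
#'
#' @param a,b Length-1 character vectors (optionally named).
#' @param matrix Substitution matrix or its \pkg{Biostrings} name.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return List of class \code{"alignment_result"}.
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b), gap_open >= 0, gap_extend >= 0)
  M <- resolve_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    unname(a), unname(b), type = "local", substitutionMatrix = M,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  alignment_result_from_pa(pa, a, b, M)
}

alignment_result_from_pa <- function(pa, a, b, M) {
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(structure(list(score = 0, bit_score = raw_to_bits(0),
                          identity_fraction = 0, similarity_fraction = 0,
                          coverage_longer = 0, n_columns = 0L,
                          a_span = c(NA_integer_, NA_integer_),
                          b_span = c(NA_integer_, NA_integer_)),
                     class = "alignment_result"))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(ap, "")[[1]]
  sc <- strsplit(as_, "")[[1]]
  ncol_aln <- length(pc)
  both <- pc != "-" & sc != "-"
  ident <- sum(both & pc == sc)
  pos <- sum(M[cbind(pc[both], sc[both])] > 0)
  a_span <- c(Biostrings::start(Biostrings::pattern(pa)),
              Biostrings::end(Biostrings::pattern(pa)))
  b_span <- c(Biostrings::start(Biostrings::subject(pa)),
              Biostrings::end(Biostrings::subject(pa)))
  longer_span <- if (nchar(a) >= nchar(b)) a_span else b_span
  structure(list(
    score = s, bit_score = raw_to_bits(s),
    identity_fraction = ident / ncol_aln,
    similarity_fraction = pos / ncol_aln,
    coverage_longer = (longer_span[2] - longer_span[1] + 1) / max(nchar(a), nchar(b)),
    n_columns = ncol_aln, a_span = a_span, b_span = b_span
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %.0f (%.1f bits), id %.2f, sim %.2f, cov %.2f\n",
              x$score, x$bit_score, x$identity_fraction,
              x$similarity_fraction, x$coverage_longer))
  invisible(x)
}

#' Convert a raw alignment score to bits
#'
#' \eqn{S' = (\lambda S - \ln K) / \ln 2} with gapped Karlin-Altschul
#' constants; the defaults are the BLOSUM62 11/1 values.
#'
#' @param score Raw alignment score.
#' @param lambda,K Karlin-Altschul constants.
#' @return Bit score.
#' @export
raw_to_bits <- function(score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * score - log(K)) / log(2)
}

#' Expected number of chance alignments (E-value)
#'
#' \eqn{E = m n 2^{-S'}} for a bit score \eqn{S'} in a search space of a
#' query of length \eqn{m} against a database of \eqn{n} residues.
#'
#' @param bit_score Bit score (see \code{\link{raw_to_bits}}).
#' @param m,n Query length and database size, both at least 1.
#' @return E-value.
#' @export
evalue <- function(bit_score, m, n) {
  stopifnot(m >= 1, n >= 1)
  m * n * 2^(-bit_score)
}

#' Identify family members by intersecting profile and alignment evidence
#'
#' A protein is a candidate member iff (i) it has a profile hit of at least
#' \code{profile_min_bits} and (ii) its best local alignment against any
#' reference protein reaches E-value \code{blast_evalue} or better. A
#' candidate survives the domain-completeness filter iff its alignment to
#' the best reference covers at least \code{completeness_fraction} of that
#' reference's own domain (the reference's best-scoring profile window), so
#' proteins carrying only part of the domain are removed even when their
#' window score clears the threshold.
#'
#' @param proteins Named character vector of the proteome.
#' @param pssm Profile from \code{\link{build_pssm}}.
#' @param references Named character vector of known family proteins.
#' @param config Optional list overriding \code{profile_min_bits} (default
#'   half the maximal attainable profile score), \code{blast_evalue}
#'   (default \code{1e-3}), \code{completeness_fraction} (default 0.8),
#'   \code{matrix}, \code{gap_open}, \code{gap_extend}.
#' @return List with \code{ids} (identified members) and \code{evidence}
#'   (per-candidate data.frame).
#' @export
identify_family <- function(proteins, pssm, references, config = list()) {
  validate_protein_set(proteins)
  validate_protein_set(references)
  if (!length(references)) stop("references must be non-empty")
  if (!length(proteins)) {
    return(list(ids = character(0), evidence = NULL))
  }
  cfg <- list(profile_min_bits = 0.5 * pssm$max_score, blast_evalue = 1e-3,
              completeness_fraction = 0.8, matrix = "BLOSUM62",
              gap_open = 11, gap_extend = 1)
  cfg[names(config)] <- config
  M <- resolve_matrix(cfg$matrix)
  width <- nrow(pssm$scores)
  n_db <- sum(nchar(references))

  # each reference's own domain region = its best-scoring profile window
  ref_dom <- lapply(references, function(r) {
    ws <- window_scores(r, pssm)
    if (!length(ws)) return(NULL)
    b <- which.max(ws)
    c(b, b + width - 1)
  })

  # best raw alignment score of every protein against every reference
  pat <- Biostrings::AAStringSet(proteins)
  score_mat <- vapply(references, function(r) {
    Biostrings::pairwiseAlignment(pat, r, type = "local",
                                  substitutionMatrix = M,
                                  gapOpening = cfg$gap_open,
                                  gapExtension = cfg$gap_extend,
                                  scoreOnly = TRUE)
  }, numeric(length(proteins)))
  score_mat <- matrix(score_mat, nrow = length(proteins),
                      dimnames = list(names(proteins), names(references)))

  rows <- lapply(names(proteins), function(id) {
    hits <- scan_protein(setNames(proteins[id], id), pssm, cfg$profile_min_bits)
    if (!nrow(hits)) return(NULL)
    best_hit <- hits[which.max(hits$bit_score), ]
    best_ref <- names(references)[which.max(score_mat[id, ])]
    best_raw <- max(score_mat[id, ])
    e <- evalue(raw_to_bits(best_raw), m = nchar(proteins[[id]]), n = n_db)
    if (e > cfg$blast_evalue) return(NULL)
    # completeness: overlap of the alignment footprint on the best reference
    # with that reference's domain window, as a fraction of profile width
    aln <- local_align(proteins[[id]], references[[best_ref]],
                       matrix = M, gap_open = cfg$gap_open,
                       gap_extend = cfg$gap_extend)
    dom <- ref_dom[[best_ref]]
    completeness <- if (is.null(dom) || aln$score <= 0) 0 else {
      ov <- min(aln$b_span[2], dom[2]) - max(aln$b_span[1], dom[1]) + 1
      max(0, ov) / width
    }
    data.frame(protein_id = id, profile_bits = best_hit$bit_score,
               start = best_hit$start, end = best_hit$end,
               best_reference = best_ref, best_evalue = e,
               completeness = completeness,
               complete = completeness >= cfg$completeness_fraction,
               stringsAsFactors = FALSE)
  })
  evidence <- do.call(rbind, rows)
  if (is.null(evidence)) {
    return(list(ids = character(0), evidence = NULL))
  }
  list(ids = evidence$protein_id[evidence$complete],
       evidence = evidence)
}

#' Rename family members by chromosomal position
#'
#' Members are numbered \code{prefix1, prefix2, ...} in the order
#' (chromosome in natural sort order, start position ascending); unplaced
#' genes follow all placed genes, ordered by their original id. Numbering
#' starts at 1 with no gaps.
#'
#' @param member_ids Character vector of gene ids to rename.
#' @param gene_models Named list of \code{\link{gene_model}} objects
#'   covering every member id.
#' @param prefix Name prefix for the new ids.
#' @return Named character vector mapping old id to new name, in renaming
#'   order.
#' @export
rename_by_position <- function(member_ids, gene_models, prefix) {
  if (anyDuplicated(member_ids)) stop("duplicate gene ids")
  missing <- setdiff(member_ids, names(gene_models))
  if (length(missing)) {
    stop("no gene model for: ", paste(missing, collapse = ", "))
  }
  chrom <- vapply(gene_models[member_ids], `[[`, character(1), "chromosome")
  start <- vapply(gene_models[member_ids], `[[`, numeric(1), "start")
  placed <- member_ids[!is.na(chrom)]
  unplaced <- member_ids[is.na(chrom)]
  if (length(placed)) {
    chr_rank <- setNames(seq_along(unique(chrom[placed])[natural_order(unique(chrom[placed]))]),
                         unique(chrom[placed])[natural_order(unique(chrom[placed]))])
    placed <- placed[order(chr_rank[chrom[placed]], start[placed])]
  }
  unplaced <- unplaced[order(unplaced)]
  ordered <- c(placed, unplaced)
  setNames(paste0(prefix, seq_along(ordered)), ordered)
}
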