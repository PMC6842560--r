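# Cross-species orthology by reciprocal best hit, duplication-pair calling
# under the 65/65 coverage-similarity rule with tandem/segmental/proximal
# categorization, and 200-kb gene-cluster detection.

# raw local-alignment score matrix set_a x set_b (vectorized per subject)
bbh_score_matrix <- function(set_a, set_b, M, gap_open, gap_extend) {
  pat <- Biostrings::AAStringSet(set_a)
  out <- vapply(names(set_b), function(b) {
    Biostrings::pairwiseAlignment(pat, set_b[[b]], type = "local",
                                  substitutionMatrix = M,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend,
                                  scoreOnly = TRUE)
  }, numeric(length(set_a)))
  matrix(out, nrow = length(set_a), dimnames = list(names(set_a), names(set_b)))
}

#' Reciprocal-best-hit orthologs between two protein sets
#'
#' A pair (a, b) is reported iff b is a's unique best hit in
#' \code{set_b}, a is b's unique best hit in \code{set_a}, and both
#' directions pass the E-value threshold. A best hit shared by equal raw
#' scores (a tie) disqualifies the gene; tied genes are returned in the
#' \code{ties} attribute.
#'
#' @param set_a,set_b Named character vectors of protein sequences.
#' @param evalue_threshold Maximum E-value in both directions.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return data.frame with columns \code{id_a}, \code{id_b}, \code{score},
#'   \code{bit_score}, \code{evalue_ab}, \code{evalue_ba}; genes
#'   disqualified by best-hit ties are in \code{attr(, "ties")}.
#' @export
bbh_orthologs <- function(set_a, set_b, evalue_threshold = 1e-20,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  validate_protein_set(set_a)
  validate_protein_set(set_b)
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  M <- resolve_matrix(matrix)
  S <- bbh_score_matrix(set_a, set_b, M, gap_open, gap_extend)
  n_a <- sum(nchar(set_a)); n_b <- sum(nchar(set_b))
  ties <- character(0)
  best_b_of <- vapply(rownames(S), function(a) {
    row <- S[a, ]
    top <- which(row == max(row))
    if (length(top) > 1) { ties <<- c(ties, a); return(NA_character_) }
    colnames(S)[top]
  }, character(1))
  best_a_of <- vapply(colnames(S), function(b) {
    col <- S[, b]
    top <- which(col == max(col))
    if (length(top) > 1) { ties <<- c(ties, b); return(NA_character_) }
    rownames(S)[top]
  }, character(1))
  rows <- lapply(names(set_a), function(a) {
    b <- best_b_of[[a]]
    if (is.na(b) || is.na(best_a_of[[b]]) || best_a_of[[b]] != a) return(NULL)
    s <- S[a, b]
    bits <- raw_to_bits(s)
    e_ab <- evalue(bits, m = nchar(set_a[[a]]), n = n_b)
    e_ba <- evalue(bits, m = nchar(set_b[[b]]), n = n_a)
    if (e_ab > evalue_threshold || e_ba > evalue_threshold) return(NULL)
    data.frame(id_a = a, id_b = b, score = s, bit_score = bits,
               evalue_ab = e_ab, evalue_ba = e_ba, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), bit_score = numeric(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0),
                      stringsAsFactors = FALSE)
  }
  attr(out, "ties") <- unique(ties)
  out
}

#' Candidate duplication pairs under the 65/65 rule
#'
#' Every unordered pair of members is aligned locally; a pair is kept iff
#' the proportion of the longer sequence covered by the alignment exceeds
#' 65 percent AND the similarity (positive-substitution fraction) of the
#' aligned region exceeds 65 percent. Both inequalities are strict: a pair
#' at exactly 0.65 is rejected.
#'
#' @param members Named character vector (>= 2 proteins).
#' @param threshold The 0.65 cutoff applied to both quantities.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return data.frame with columns \code{id_a}, \code{id_b},
#'   \code{coverage_longer}, \code{similarity_fraction},
#'   \code{identity_fraction}; zero rows when nothing qualifies.
#' @export
duplication_pairs <- function(members, threshold = 0.65, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  validate_protein_set(members)
  if (length(members) < 2) stop("need at least 2 members")
  M <- resolve_matrix(matrix)
  ids <- names(members)
  rows <- list()
  for (i in seq_len(length(ids) - 1)) {
    js <- (i + 1):length(ids)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(members[js]), members[[i]], type = "local",
      substitutionMatrix = M, gapOpening = gap_open, gapExtension = gap_extend)
    scores <- Biostrings::score(pa)
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    p_start <- Biostrings::start(Biostrings::pattern(pa))
    p_end <- Biostrings::end(Biostrings::pattern(pa))
    s_start <- Biostrings::start(Biostrings::subject(pa))
    s_end <- Biostrings::end(Biostrings::subject(pa))
    for (k in seq_along(js)) {
      if (scores[k] <= 0) next
      j <- js[k]
      pc <- strsplit(ap[k], "")[[1]]
      sc <- strsplit(as_[k], "")[[1]]
      both <- pc != "-" & sc != "-"
      ncol_aln <- length(pc)
      len_j <- nchar(members[[j]]); len_i <- nchar(members[[i]])
      span <- if (len_j >= len_i) p_end[k] - p_start[k] + 1 else s_end[k] - s_start[k] + 1
      coverage <- span / max(len_i, len_j)
      similarity <- sum(M[cbind(pc[both], sc[both])] > 0) / ncol_aln
      if (coverage > threshold && similarity > threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          id_a = ids[i], id_b = ids[j],
          coverage_longer = coverage,
          similarity_fraction = similarity,
          identity_fraction = sum(both & pc == sc) / ncol_aln,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      coverage_longer = numeric(0),
                      similarity_fraction = numeric(0),
                      identity_fraction = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Categorize duplication events as tandem, segmental or proximal
#'
#' Pairs on different chromosomes are segmental. Pairs on one chromosome
#' are tandem when they are adjacent: start positions within
#' \code{window_bp} and at most \code{max_intervening} family genes between
#' them; otherwise they are proximal, reported separately since the
#' adjacent/different-chromosome dichotomy does not cover them. A pair
#' involving an unplaced gene cannot be categorized and raises an error.
#'
#' @param pairs data.frame from \code{\link{duplication_pairs}}.
#' @param gene_models Named list of \code{\link{gene_model}} objects.
#' @param family_ids Family gene ids used when counting intervening genes;
#'   defaults to all of \code{gene_models}.
#' @param window_bp Tandem distance window (start-to-start).
#' @param max_intervening Maximum family genes between a tandem pair.
#' @return \code{pairs} with an added \code{category} column.
#' @export
classify_duplication <- function(pairs, gene_models, family_ids = NULL,
                                 window_bp = 200000, max_intervening = 1) {
  if (is.null(family_ids)) family_ids <- names(gene_models)
  get_model <- function(id) {
    gm <- gene_models[[id]]
    if (is.null(gm)) stop("no gene model for ", id)
    gm
  }
  category <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- get_model(pairs$id_a[k]); b <- get_model(pairs$id_b[k])
    if (is.na(a$chromosome) || is.na(b$chromosome)) {
      stop("pair (", a$gene_id, ", ", b$gene_id, ") involves an unplaced ",
           "gene; its duplication category is unknowable - map the gene or ",
           "drop the pair")
    }
    if (a$chromosome != b$chromosome) {
      category[k] <- "segmental"
      next
    }
    lo <- min(a$start, b$start); hi <- max(a$start, b$start)
    between <- vapply(setdiff(family_ids, c(a$gene_id, b$gene_id)), function(id) {
      gm <- gene_models[[id]]
      !is.null(gm) && !is.na(gm$chromosome) && gm$chromosome == a$chromosome &&
        gm$start > lo && gm$start < hi
    }, logical(1))
    category[k] <- if (hi - lo <= window_bp && sum(between) <= max_intervening) {
      "tandem"
    } else {
      "proximal"
    }
  }
  pairs$category <- category
  pairs
}

#' Detect gene clusters within a chromosomal window
#'
#' Per chromosome, genes are sorted by start position and chained by single
#' linkage: consecutive genes whose starts are at most \code{window_bp}
#' apart belong to one chain. Maximal chains with at least \code{min_genes}
#' members are clusters. Unplaced genes are ignored. Chaining is
#' start-to-start, so a cluster's total span may exceed the window.
#'
#' @param gene_models Named list of \code{\link{gene_model}} objects.
#' @param window_bp Maximum start-to-start gap inside a cluster.
#' @param min_genes Minimum cluster size.
#' @return List of clusters, each a list with \code{chromosome},
#'   \code{members} (ordered by start) and \code{span} (min start, max end).
#' @export
detect_clusters <- function(gene_models, window_bp = 200000, min_genes = 2) {
  placed <- Filter(function(gm) !is.na(gm$chromosome), gene_models)
  if (!length(placed)) return(list())
  chrom <- vapply(placed, `[[`, character(1), "chromosome")
  clusters <- list()
  for (chr in unique(chrom)[natural_order(unique(chrom))]) {
    gms <- placed[chrom == chr]
    starts <- vapply(gms, `[[`, numeric(1), "start")
    o <- order(starts)
    gms <- gms[o]; starts <- starts[o]
    chain_id <- cumsum(c(TRUE, diff(starts) > window_bp))
    for (cid in unique(chain_id)) {
      idx <- which(chain_id == cid)
      if (length(idx) < min_genes) next
      ends <- vapply(gms[idx], `[[`, numeric(1), "end")
      clusters[[length(clusters) + 1]] <- list(
        chromosome = chr,
        members = unname(vapply(gms[idx], `[[`, character(1), "gene_id")),
        span = c(min(starts[idx]), max(ends))
      )
    }
  }
  clusters
}
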