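# Distance-based phylogenetics: all-pairs global-alignment distances,
# Saitou-Nei neighbor joining, patristic distances, and nearest-reference
# subfamily classification.

#' All-pairs alignment distances between proteins
#'
#' For every pair, a global (Needleman-Wunsch) alignment is computed with
#' the same substitution matrix and affine gap costs used elsewhere, and the
#' distance is one minus the identity fraction over the aligned columns
#' (columns holding a residue in both sequences; gap columns are excluded).
#' Identical sequences are at distance 0.
#'
#' @param proteins Named character vector, at least two sequences.
#' @param matrix Substitution matrix or its \pkg{Biostrings} name.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Symmetric numeric matrix with zero diagonal and the protein ids
#'   as dimnames.
#' @export
pairwise_distances <- function(proteins, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  validate_protein_set(proteins)
  n <- length(proteins)
  if (n < 2) stop("need at least 2 proteins")
  M <- resolve_matrix(matrix)
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[js]), proteins[[i]],
      type = "global", substitutionMatrix = M,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    for (k in seq_along(js)) {
      d[i, js[k]] <- d[js[k], i] <- global_identity_distance(ap[k], as_[k])
    }
  }
  d
}

# 1 - identity over the aligned columns (columns with a residue in both
# sequences); gap columns, terminal or internal, carry no signal about
# substitution divergence and are excluded
global_identity_distance <- function(aln_a, aln_b) {
  a <- strsplit(aln_a, "")[[1]]
  b <- strsplit(aln_b, "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(1)
  1 - sum(a[both] == b[both]) / sum(both)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The agglomerative algorithm of Saitou and Nei: repeatedly join the pair
#' minimizing \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)},
#' attach the joined leaves with the standard two-point branch lengths, and
#' reduce the matrix; the final three nodes are resolved by the three-point
#' closed form. Negative branch-length estimates are clamped to zero with a
#' warning. On an additive matrix the generating tree and all its branch
#' lengths are recovered exactly.
#'
#' @param D Symmetric distance matrix with labels as dimnames (n >= 3).
#' @return An unrooted \code{ape} \code{phylo} tree.
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix needs dimnames")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa; a 2-leaf tree is trivial")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  if (any(grepl("[(),:;\\s]", labels, perl = TRUE))) {
    stop("labels may not contain Newick metacharacters or whitespace")
  }
  clamped <- FALSE
  fmt <- function(x) sprintf("%.12g", x)
  node <- labels  # newick fragment per active node
  d <- D
  while (length(node) > 3) {
    m <- length(node)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]  # first minimum: determinism
    i <- min(ij); j <- max(ij)
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0 || bj < 0) clamped <- TRUE
    bi <- max(bi, 0); bj <- max(bj, 0)
    merged <- paste0("(", node[i], ":", fmt(bi), ",", node[j], ":", fmt(bj), ")")
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], merged)
    dimnames(d_new) <- list(NULL, NULL)
    d <- d_new
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- d[1, 2] - v1
  v3 <- d[1, 3] - v1
  if (any(c(v1, v2, v3) < 0)) clamped <- TRUE
  v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0)
  if (clamped) warning("negative branch length estimate(s) clamped to 0")
  newick <- paste0("(", node[1], ":", fmt(v1), ",", node[2], ":", fmt(v2),
                   ",", node[3], ":", fmt(v3), ");")
  ape::read.tree(text = newick)
}

#' Patristic distances between the leaves of a tree
#'
#' Sum of branch lengths along the path between each pair of leaves.
#'
#' @param tree A \code{phylo} tree with branch lengths.
#' @return Symmetric matrix over the tip labels.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  stats::cophenetic(tree)
}

#' Classify query proteins by nearest labeled reference
#'
#' Each query is assigned the class of its nearest labeled reference under
#' patristic distance in the tree (or under the supplied distance matrix).
#' A tie among nearest references is broken by majority vote among the three
#' nearest references; a persisting tie falls back to the class of the
#' lexicographically smallest tied reference and is flagged ambiguous.
#'
#' @param tree_or_distances A \code{phylo} tree or a symmetric distance
#'   matrix whose labels include all references and queries.
#' @param ref_labels Named character vector: reference id to class label.
#' @param queries Query ids; defaults to all non-reference labels.
#' @param classes Optional character vector of classes that must each be
#'   represented by at least one reference (error otherwise).
#' @return data.frame with columns \code{query}, \code{class},
#'   \code{nearest_ref}, \code{distance}, \code{ambiguous}.
#' @export
classify_subfamilies <- function(tree_or_distances, ref_labels, queries = NULL,
                                 classes = NULL) {
  D <- if (inherits(tree_or_distances, "phylo")) {
    patristic_distances(tree_or_distances)
  } else {
    stopifnot(is.matrix(tree_or_distances))
    tree_or_distances
  }
  refs <- names(ref_labels)
  missing_refs <- setdiff(refs, rownames(D))
  if (length(missing_refs)) {
    stop("reference(s) absent from tree: ", paste(missing_refs, collapse = ", "))
  }
  if (!is.null(classes)) {
    absent <- setdiff(classes, unique(ref_labels))
    if (length(absent)) {
      stop("no labeled reference for class(es): ", paste(absent, collapse = ", "))
    }
  }
  if (is.null(queries)) queries <- setdiff(rownames(D), refs)
  missing_q <- setdiff(queries, rownames(D))
  if (length(missing_q)) {
    stop("query absent from tree: ", paste(missing_q, collapse = ", "))
  }
  tol <- 1e-12
  rows <- lapply(queries, function(q) {
    dist_q <- D[q, refs]
    o <- order(dist_q, refs)
    nearest_set <- refs[dist_q <= dist_q[o[1]] + tol]
    ambiguous <- FALSE
    if (length(nearest_set) == 1) {
      ref <- nearest_set
    } else {
      k3 <- refs[o[seq_len(min(3, length(o)))]]
      votes <- table(ref_labels[k3])
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1) {
        cands <- k3[ref_labels[k3] == top]
        ref <- sort(intersect(cands, nearest_set))[1]
        if (is.na(ref)) ref <- sort(cands)[1]
      } else {
        ref <- sort(nearest_set)[1]
        ambiguous <- TRUE
      }
    }
    data.frame(query = q, class = unname(ref_labels[ref]), nearest_ref = ref,
               distance = unname(D[q, ref]), ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
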