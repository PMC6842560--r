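# Expression quantification: RPKM from read counts with per-tissue library
# sizes, log2 standardization, tissue totals, and 2^-ddCt relative
# quantification for qPCR with technical-then-biological replicate
# aggregation.

#' Construct a count matrix with library sizes and gene lengths
#'
#' @param counts Integer matrix, genes x tissues, non-negative.
#' @param lib_sizes Per-tissue total mapped reads (named by tissue).
#' @param lengths_bp Per-gene exonic length in bp (named by gene).
#' @return List of class \code{"count_matrix"}.
#' @export
count_matrix <- function(counts, lib_sizes, lengths_bp) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  lib_sizes <- lib_sizes[colnames(counts)]
  lengths_bp <- lengths_bp[rownames(counts)]
  if (anyNA(lib_sizes)) stop("library size missing for some tissue")
  if (anyNA(lengths_bp)) stop("gene length missing for some gene")
  if (any(lengths_bp < 1)) stop("gene lengths must be >= 1 bp")
  if (any(lib_sizes < colSums(counts))) {
    stop("library sizes must be at least the column sums of the counts")
  }
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 lengths_bp = lengths_bp),
            class = "count_matrix")
}

#' Read and write the counts TSV
#'
#' Layout: a comment line \code{#library_sizes} carrying the per-tissue
#' totals, then a header \code{gene, length_bp, <tissue...>} and one row per
#' gene.
#'
#' @param path File path.
#' @return \code{read_counts_tsv}: a \code{\link{count_matrix}}.
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  lib_line <- grep("^#library_sizes", lines, value = TRUE)
  if (length(lib_line) != 1) stop("counts file needs one #library_sizes line")
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                           check.names = FALSE)
  tissues <- setdiff(names(tab), c("gene", "length_bp"))
  lib_vals <- as.numeric(strsplit(lib_line, "\t")[[1]][-(1:2)])
  if (length(lib_vals) != length(tissues)) {
    stop("#library_sizes must carry one value per tissue column")
  }
  counts <- as.matrix(tab[, tissues, drop = FALSE])
  rownames(counts) <- tab$gene
  count_matrix(counts, setNames(lib_vals, tissues),
               setNames(tab$length_bp, tab$gene))
}

#' @rdname read_counts_tsv
#' @param cm A \code{\link{count_matrix}}.
#' @export
write_counts_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste(c("#library_sizes", "", format(cm$lib_sizes, scientific = FALSE, trim = TRUE)),
                   collapse = "\t"), con)
  header <- paste(c("gene", "length_bp", colnames(cm$counts)), collapse = "\t")
  writeLines(header, con)
  for (g in rownames(cm$counts)) {
    writeLines(paste(c(g, format(cm$lengths_bp[[g]], scientific = FALSE, trim = TRUE),
                       cm$counts[g, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Reads per kilobase per million mapped reads
#'
#' \eqn{RPKM_{g,t} = 10^9 \, c_{g,t} / (N_t L_g)} for counts \eqn{c}, library
#' size \eqn{N_t} (total mapped reads in tissue \eqn{t}) and exonic length
#' \eqn{L_g} in bp.
#'
#' @param cm A \code{\link{count_matrix}}.
#' @return Genes x tissues numeric matrix with attribute
#'   \code{scale = "rpkm"}.
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$lib_sizes == 0)) stop("library size of 0")
  if (any(cm$lengths_bp == 0)) stop("gene length of 0")
  out <- cm$counts * 1e9 / outer(as.numeric(cm$lengths_bp), as.numeric(cm$lib_sizes))
  dimnames(out) <- dimnames(cm$counts)
  attr(out, "scale") <- "rpkm"
  out
}

#' Log2 standardization of an expression matrix
#'
#' Elementwise \eqn{\log_2(x + 1)}; the pseudocount keeps unexpressed genes
#' (RPKM 0) at 0 on the log scale.
#'
#' @param expr RPKM-scale matrix from \code{\link{rpkm}}.
#' @return Matrix with attribute \code{scale = "log"}.
#' @export
log_standardize <- function(expr) {
  if (identical(attr(expr, "scale"), "log")) stop("matrix is already log scale")
  if (any(expr < 0)) stop("negative expression values")
  out <- log2(expr + 1)
  attr(out, "scale") <- "log"
  out
}

#' Per-tissue expression totals
#'
#' Column sums of an RPKM-scale matrix; the per-tissue total expression of
#' the family.
#'
#' @param expr RPKM-scale matrix.
#' @return Named numeric vector.
#' @export
tissue_totals <- function(expr) {
  if (identical(attr(expr, "scale"), "log")) {
    stop("tissue totals are defined on the RPKM scale")
  }
  colSums(expr)
}

#' Read and write qPCR Ct tables
#'
#' Long-format TSV with columns \code{gene}, \code{tissue}, \code{bio_rep},
#' \code{tech_rep}, \code{ct}.
#'
#' @param path File path.
#' @return \code{read_ct_table}: a data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  needed <- c("gene", "tissue", "bio_rep", "tech_rep", "ct")
  if (!all(needed %in% names(tab))) {
    stop("Ct table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(tab$ct <= 0)) stop("Ct values must be positive")
  tab[, needed]
}

#' @rdname read_ct_table
#' @param ct A Ct data.frame.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are first averaged to one Ct per (gene, tissue,
#' biological replicate). Then per biological replicate
#' \eqn{\Delta Ct = Ct_{gene} - Ct_{ref}}, and
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator}},
#' where the calibrator baseline is the mean \eqn{\Delta Ct} of the
#' calibrator tissue across its biological replicates. The fold change is
#' \eqn{2^{-\Delta\Delta Ct}}, reported as mean and standard deviation over
#' biological replicates. The reference gene itself has fold exactly 1 in
#' every tissue.
#'
#' @param ct Ct table (see \code{\link{read_ct_table}}).
#' @param reference_gene Internal reference (housekeeping) gene id; must be
#'   measured in every (tissue, biological replicate).
#' @param calibrator_tissue Tissue whose mean \eqn{\Delta Ct} is the
#'   baseline.
#' @return data.frame with columns \code{gene}, \code{tissue}, \code{fold},
#'   \code{sd}.
#' @export
ddct_fold_changes <- function(ct, reference_gene, calibrator_tissue) {
  stopifnot(all(c("gene", "tissue", "bio_rep", "tech_rep", "ct") %in% names(ct)))
  if (!reference_gene %in% ct$gene) stop("reference gene not in table: ", reference_gene)
  if (!calibrator_tissue %in% ct$tissue) stop("calibrator tissue not in table: ", calibrator_tissue)
  tech <- stats::aggregate(ct ~ gene + tissue + bio_rep, data = ct, FUN = mean)
  ref <- tech[tech$gene == reference_gene, ]
  ref_key <- paste(ref$tissue, ref$bio_rep)
  cells <- unique(tech[, c("tissue", "bio_rep")])
  missing <- !(paste(cells$tissue, cells$bio_rep) %in% ref_key)
  if (any(missing)) {
    cell <- cells[which(missing)[1], ]
    stop(sprintf("reference gene '%s' not measured in tissue '%s', bio_rep %s",
                 reference_gene, cell$tissue, cell$bio_rep))
  }
  ref_ct <- setNames(ref$ct, ref_key)
  tech$dct <- tech$ct - ref_ct[paste(tech$tissue, tech$bio_rep)]
  genes <- unique(tech$gene)
  rows <- list()
  for (g in genes) {
    gt <- tech[tech$gene == g, ]
    calib <- gt$dct[gt$tissue == calibrator_tissue]
    if (!length(calib)) {
      stop(sprintf("gene '%s' has no measurement in calibrator tissue '%s'",
                   g, calibrator_tissue))
    }
    baseline <- mean(calib)
    for (tis in unique(gt$tissue)) {
      folds <- 2^(-(gt$dct[gt$tissue == tis] - baseline))
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, tissue = tis, fold = mean(folds),
        sd = if (length(folds) > 1) stats::sd(folds) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
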