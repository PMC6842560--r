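# Exon-intron statistics from gene models and deterministic protein motif
# scanning: the LXXLL activation and LXLXLX inhibitory motifs, leucine
# heptad (zipper) runs with a basic flank, and K-domain presence via a
# second profile.

#' Number of introns of a gene
#'
#' Exon count minus one on the gene's (longest-transcript) exon structure.
#'
#' @param gm A \code{\link{gene_model}}.
#' @return Non-negative integer.
#' @export
count_introns <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  nrow(gm$exons) - 1L
}

#' Exon-intron coordinate table
#'
#' One row per gene with its chromosome, span, strand, exon count, summed
#' exonic length and intron count; the tabular counterpart of a gene
#' structure diagram.
#'
#' @param gene_models Named list of \code{\link{gene_model}} objects.
#' @return data.frame.
#' @export
exon_intron_table <- function(gene_models) {
  rows <- lapply(gene_models, function(gm) {
    data.frame(gene_id = gm$gene_id,
               chromosome = ifelse(is.na(gm$chromosome), NA_character_, gm$chromosome),
               start = gm$start, end = gm$end, strand = gm$strand,
               n_exons = nrow(gm$exons),
               exonic_bp = sum(gm$exons[, 2] - gm$exons[, 1] + 1),
               introns = count_introns(gm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

FIXED_MOTIFS <- list(
  LXXLL = "L..LL",    # transcriptional activation motif
  LXLXLX = "L.L.L."   # EAR-like inhibitory motif
)

#' Scan a protein for a fixed-pattern motif
#'
#' Reports all (possibly overlapping) occurrences of the named motif in
#' order of position. \code{LXXLL} is L, any, any, L, L; \code{LXLXLX} is
#' L, any, L, any, L, any.
#'
#' @param protein Length-1 character vector (optionally named).
#' @param motif_name One of \code{"LXXLL"}, \code{"LXLXLX"}.
#' @return data.frame with columns \code{protein_id}, \code{motif_name},
#'   \code{start}, \code{end}.
#' @export
scan_fixed_motif <- function(protein, motif_name) {
  if (!motif_name %in% names(FIXED_MOTIFS)) {
    stop("unknown motif name: ", motif_name, " (known: ",
         paste(names(FIXED_MOTIFS), collapse = ", "), ")")
  }
  pattern <- FIXED_MOTIFS[[motif_name]]
  id <- names(protein) %||% ""
  hits <- gregexpr(paste0("(?=", pattern, ")"), unname(protein), perl = TRUE)[[1]]
  if (hits[1] == -1) {
    return(data.frame(protein_id = character(0), motif_name = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  len <- nchar(pattern)  # patterns are literal residues and '.' only
  data.frame(protein_id = id, motif_name = motif_name,
             start = as.integer(hits), end = as.integer(hits + len - 1L),
             stringsAsFactors = FALSE)
}

#' Detect basic leucine-zipper heptad runs
#'
#' A zipper run is a maximal series of leucines at exact 7-residue
#' periodicity with at least \code{min_repeats} leucines. With
#' \code{basic_flank = TRUE} (the default) a run is only reported when the
#' 15 residues immediately N-terminal of the run contain at least three
#' basic residues (K/R), the "basic region" of a bZIP. This deterministic
#' rule stands in for coiled-coil prediction and is labeled as such in the
#' output.
#'
#' @param protein Length-1 character vector (optionally named).
#' @param min_repeats Minimum number of leucines in the run.
#' @param basic_flank Require the basic N-terminal flank.
#' @return data.frame with columns \code{protein_id}, \code{motif_name}
#'   (\code{"LEUCINE_ZIPPER"}), \code{start}, \code{end} (first and last
#'   leucine of the run).
#' @export
detect_leucine_zipper <- function(protein, min_repeats = 4, basic_flank = TRUE) {
  stopifnot(min_repeats >= 2)
  id <- names(protein) %||% ""
  seq <- unname(protein)
  chars <- strsplit(seq, "")[[1]]
  lpos <- which(chars == "L")
  empty <- data.frame(protein_id = character(0), motif_name = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(lpos)) return(empty)
  in_l <- logical(length(chars))
  in_l[lpos] <- TRUE
  rows <- list()
  for (p in lpos) {
    if (p > 7 && in_l[p - 7]) next  # not the start of a maximal run
    run <- p
    while (run[length(run)] + 7 <= length(chars) && in_l[run[length(run)] + 7]) {
      run <- c(run, run[length(run)] + 7)
    }
    if (length(run) < min_repeats) next
    if (basic_flank) {
      flank <- chars[max(1, p - 15):max(1, p - 1)]
      if (p == 1 || sum(flank %in% c("K", "R")) < 3) next
    }
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = id, motif_name = "LEUCINE_ZIPPER",
      start = run[1], end = run[length(run)], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Test for the presence of a K-like domain
#'
#' Scans the protein with a second profile built from a K-domain seed
#' alignment; structural confirmation of the two major family types rests
#' on the core domain hit with (MIKC-type) or without (M-type) a K-domain
#' hit.
#'
#' @param protein Length-1 character vector (optionally named).
#' @param k_pssm Profile built from the K-domain seed.
#' @param min_bits Threshold in bits; default half the maximal attainable
#'   score.
#' @return \code{TRUE}/\code{FALSE}.
#' @export
has_k_domain <- function(protein, k_pssm, min_bits = 0.5 * k_pssm$max_score) {
  nrow(scan_protein(protein, k_pssm, min_bits)) > 0
}
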