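# Summary statistics over a family table: census by class, chromosomal
# placement, orthologue row counts per species, intron structure, and
# physicochemical ranges.

#' Summarize a family table
#'
#' Computes the family-level statistics conventionally reported for a gene
#' family census. Orthologue counts are per row (gene): a row with two
#' entries for one species still counts once for that species. The two
#' major types aggregate the five classes: M-type = Malpha + Mbeta +
#' Mgamma, MIKC-type = MIKCc + MIKC*.
#'
#' @param rows A \code{family_table} (see \code{\link{read_family_table}}).
#' @return List of class \code{"family_summary"}: \code{n_total},
#'   \code{class_counts}, \code{type_counts}, \code{n_placed},
#'   \code{n_chromosomes}, \code{chromosome_counts},
#'   \code{orthologue_rows} (per species, overall and per major type),
#'   \code{intron} (see \code{\link{intron_stats}}), and min/max/mean of
#'   length, MW and pI.
#' @export
summarize_family <- function(rows) {
  stopifnot(inherits(rows, "family_table"))
  if (nrow(rows) == 0) stop("empty family table")
  cls <- factor(rows$class, levels = family_classes())
  class_counts <- table(cls)
  is_m <- rows$class %in% m_type_classes()
  species <- c("sp1", "sp2", "sp3")
  orth_cols <- paste0("orthologues_", species)
  row_has <- vapply(orth_cols, function(col) lengths(rows[[col]]) > 0,
                    logical(nrow(rows)))
  row_has <- matrix(row_has, nrow = nrow(rows), dimnames = list(NULL, species))
  orthologue_rows <- list(
    overall = colSums(row_has),
    m_type = colSums(row_has[is_m, , drop = FALSE]),
    mikc_type = colSums(row_has[!is_m, , drop = FALSE])
  )
  hist <- chromosome_histogram(rows)
  structure(list(
    n_total = nrow(rows),
    class_counts = setNames(as.integer(class_counts), names(class_counts)),
    type_counts = c(m_type = sum(is_m), mikc_type = sum(!is_m)),
    n_placed = sum(!is.na(rows$chromosome)),
    n_chromosomes = length(hist),
    chromosome_counts = hist,
    orthologue_rows = orthologue_rows,
    intron = intron_stats(rows),
    length_aa = c(min = min(rows$length_aa), max = max(rows$length_aa),
                  mean = round(mean(rows$length_aa), 2)),
    mw_kda = c(min = min(rows$mw_kda), max = max(rows$mw_kda),
               mean = round(mean(rows$mw_kda), 2)),
    pi = c(min = min(rows$pi), max = max(rows$pi),
           mean = round(mean(rows$pi), 2))
  ), class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat(sprintf("<family_summary> %d genes, %d placed on %d chromosomes\n",
              x$n_total, x$n_placed, x$n_chromosomes))
  cat("classes:", paste(names(x$class_counts), x$class_counts, collapse = ", "),
      "\n")
  cat(sprintf("introns: max %d; %d MIKC-type rows with >= 4; M-type zero-intron %d%%\n",
              x$intron$max_introns, x$intron$n_mikc_ge4,
              x$intron$zero_fraction_m_pct))
  invisible(x)
}

#' Intron statistics of a family table
#'
#' @param rows A \code{family_table}.
#' @param k Intron threshold for the MIKC-type count.
#' @return List with \code{max_introns}, \code{n_mikc_ge4} (MIKC-type rows
#'   with at least \code{k} introns), \code{n_mikc},
#'   \code{zero_fraction_m_pct} (percentage of M-type rows with zero
#'   introns, rounded half-up to an integer).
#' @export
intron_stats <- function(rows, k = 4) {
  stopifnot(inherits(rows, "family_table"), nrow(rows) > 0)
  is_m <- rows$class %in% m_type_classes()
  m_introns <- rows$introns[is_m]
  mikc_introns <- rows$introns[!is_m]
  list(
    max_introns = max(rows$introns),
    n_mikc_ge4 = sum(mikc_introns >= k),
    n_mikc = length(mikc_introns),
    zero_fraction_m_pct = if (length(m_introns)) {
      as.integer(round_half_up(100 * sum(m_introns == 0) / length(m_introns)))
    } else {
      NA_integer_
    }
  )
}

#' Per-chromosome gene counts
#'
#' Unplaced genes are excluded; chromosomes are returned in natural
#' (numeric-aware) order.
#'
#' @param rows A \code{family_table}.
#' @return Named integer vector.
#' @export
chromosome_histogram <- function(rows) {
  stopifnot(inherits(rows, "family_table"))
  placed <- rows$chromosome[!is.na(rows$chromosome)]
  if (!length(placed)) return(setNames(integer(0), character(0)))
  counts <- table(placed)
  out <- setNames(as.integer(counts), names(counts))
  out[natural_order(names(out))]
}
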