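# Readers and writers for the formats the pipeline touches (FASTA, GFF3,
# Stockholm, Newick, TSV) plus the family-table data model.

FAMILY_TABLE_COLUMNS <- c(
  "name", "sequence_id", "class", "chromosome",
  "orthologues_sp1", "orthologues_sp2", "orthologues_sp3",
  "length_aa", "mw_kda", "pi", "introns"
)

# cell values meaning "no orthologue detected" (en dash as printed, plus the
# plain ASCII fall-backs)
EMPTY_CELL <- c("\u2013", "-", "", "NA")

parse_orthologue_cell <- function(cell) {
  cell <- trimws(cell)
  if (cell %in% EMPTY_CELL) return(character(0))
  # split on commas, then on the division slash (either U+2215 or "/"),
  # flattening: "7/45, 8/24" -> c("7","45","8","24")
  parts <- unlist(strsplit(cell, ","))
  parts <- unlist(strsplit(parts, "[/\u2215]"))
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

format_orthologue_cell <- function(entries) {
  if (length(entries) == 0) "\u2013" else paste(entries, collapse = ",")
}

#' Read a family table (TSV)
#'
#' The family table mirrors the per-gene summary table of a gene-family
#' survey: one row per family member with its subfamily class, chromosome,
#' orthologues in up to three other species, physicochemical properties and
#' intron count. Empty orthologue cells are written as an en dash and parse
#' to an empty list; multi-entry cells like \code{"47,48"} parse to multiple
#' entries; the chromosome cell \code{"N/A"} parses to \code{NA} (unplaced).
#'
#' @param path Path to a tab-separated file with the 11 documented columns.
#' @return A \code{data.frame} of class \code{"family_table"} with
#'   list-columns for the orthologue cells.
#' @export
read_family_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = "character", fileEncoding = "UTF-8",
                           check.names = FALSE)
  if (!identical(names(tab), FAMILY_TABLE_COLUMNS)) {
    stop("family table header must be: ", paste(FAMILY_TABLE_COLUMNS, collapse = ", "))
  }
  if (nrow(tab) == 0) return(empty_family_table())
  bad_class <- setdiff(unique(tab$class), family_classes())
  if (length(bad_class)) {
    stop("unknown class label(s): ", paste(bad_class, collapse = ", "))
  }
  num_col <- function(col, integer = FALSE) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(vals) | (integer & vals != floor(vals)))
    if (length(bad)) {
      stop(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                   col, bad[1], tab[[col]][bad[1]]))
    }
    if (integer) as.integer(vals) else vals
  }
  out <- data.frame(
    name = tab$name, sequence_id = tab$sequence_id, class = tab$class,
    chromosome = ifelse(tab$chromosome %in% c("N/A", "NA", ""), NA_character_,
                        tab$chromosome),
    stringsAsFactors = FALSE
  )
  out$orthologues_sp1 <- I(lapply(tab$orthologues_sp1, parse_orthologue_cell))
  out$orthologues_sp2 <- I(lapply(tab$orthologues_sp2, parse_orthologue_cell))
  out$orthologues_sp3 <- I(lapply(tab$orthologues_sp3, parse_orthologue_cell))
  out$length_aa <- num_col("length_aa", integer = TRUE)
  out$mw_kda <- num_col("mw_kda")
  out$pi <- num_col("pi")
  out$introns <- num_col("introns", integer = TRUE)
  if (any(out$length_aa < 1)) stop("length_aa must be >= 1")
  if (any(out$introns < 0)) stop("introns must be >= 0")
  if (anyDuplicated(out$name)) stop("duplicate gene names in family table")
  out <- out[, FAMILY_TABLE_COLUMNS]
  class(out) <- c("family_table", "data.frame")
  out
}

empty_family_table <- function() {
  out <- data.frame(
    name = character(0), sequence_id = character(0), class = character(0),
    chromosome = character(0), stringsAsFactors = FALSE
  )
  out$orthologues_sp1 <- I(list())
  out$orthologues_sp2 <- I(list())
  out$orthologues_sp3 <- I(list())
  out$length_aa <- integer(0); out$mw_kda <- numeric(0)
  out$pi <- numeric(0); out$introns <- integer(0)
  class(out) <- c("family_table", "data.frame")
  out
}

#' Write a family table (TSV)
#'
#' Inverse of \code{\link{read_family_table}}: empty orthologue lists are
#' written as an en dash, unplaced chromosomes as \code{"N/A"}.
#'
#' @param tab A \code{family_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_family_table <- function(tab, path) {
  stopifnot(inherits(tab, "family_table"))
  out <- data.frame(
    name = tab$name, sequence_id = tab$sequence_id, class = tab$class,
    chromosome = ifelse(is.na(tab$chromosome), "N/A", tab$chromosome),
    orthologues_sp1 = vapply(tab$orthologues_sp1, format_orthologue_cell, ""),
    orthologues_sp2 = vapply(tab$orthologues_sp2, format_orthologue_cell, ""),
    orthologues_sp3 = vapply(tab$orthologues_sp3, format_orthologue_cell, ""),
    length_aa = tab$length_aa, mw_kda = tab$mw_kda, pi = tab$pi,
    introns = tab$introns, stringsAsFactors = FALSE, check.names = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene model
#'
#' A chromosome-placed gene with its exon intervals, all coordinates GFF3
#' native (1-based, inclusive). An unplaced gene has \code{chromosome = NA}.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name, or \code{NA} for an unplaced gene.
#' @param start,end 1-based inclusive gene span.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Two-column matrix of exon (start, end) intervals.
#' @return A list of class \code{"gene_model"}.
#' @export
gene_model <- function(gene_id, chromosome, start, end, strand = "+", exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1) stop("gene model needs at least one exon: ", gene_id)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) stop("exon end < start in ", gene_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stop("overlapping exons in ", gene_id)
  }
  if (start > end) stop("gene start > end: ", gene_id)
  if (exons[1, 1] < start || exons[nrow(exons), 2] > end) {
    stop("exons outside gene span in ", gene_id)
  }
  structure(list(gene_id = gene_id,
                 chromosome = if (is.na(chromosome)) NA_character_ else as.character(chromosome),
                 start = as.numeric(start), end = as.numeric(end),
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  chr <- if (is.na(x$chromosome)) "unplaced" else x$chromosome
  cat(sprintf("<gene_model> %s %s:%.0f-%.0f (%s), %d exon(s)\n", x$gene_id, chr,
              x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Builds one \code{\link{gene_model}} per gene feature. Exons are linked to
#' genes through their mRNA parents (\code{ID}/\code{Parent} attributes);
#' when a gene has several mRNAs, the mRNA with the greatest summed exonic
#' length is retained, so each gene carries a single transcript structure and
#' a single intron count. Exons whose parent cannot be resolved, and
#' overlapping exons within one mRNA, are errors.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of \code{gene_model} objects (names are gene IDs).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- meta$Parent  # CharacterList
  genes <- which(type == "gene")
  mrnas <- which(type %in% c("mRNA", "transcript"))
  exons <- which(type == "exon")
  if (!length(genes)) stop("no gene features in ", path)
  mrna_gene <- setNames(vapply(mrnas, function(i) {
    p <- as.character(parents[[i]])
    if (!length(p)) stop("mRNA without Parent: ", ids[i])
    p[1]
  }, character(1)), ids[mrnas])
  gene_ids <- ids[genes]
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in ", path)
  # exon -> mRNA (or directly to gene, for single-level files)
  exon_parent <- lapply(exons, function(i) as.character(parents[[i]]))
  models <- vector("list", length(genes))
  names(models) <- gene_ids
  exon_parent_flat <- rep(unlist(lapply(seq_along(exons), function(k) {
    p <- exon_parent[[k]]
    if (!length(p)) stop("exon without resolvable parent at row ", exons[k])
    p
  })), times = 1)
  exon_rows <- rep(exons, lengths(exon_parent))
  bad <- !(exon_parent_flat %in% c(names(mrna_gene), gene_ids))
  if (any(bad)) {
    stop("exon without resolvable parent: ", exon_parent_flat[which(bad)[1]])
  }
  starts <- BiocGenerics::start(gr); ends <- BiocGenerics::end(gr)
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  strands <- as.character(BiocGenerics::strand(gr))
  for (g in seq_along(genes)) {
    gi <- genes[g]
    gid <- gene_ids[g]
    tx <- names(mrna_gene)[mrna_gene == gid]
    tx_exons <- if (length(tx)) {
      lapply(tx, function(t) exon_rows[exon_parent_flat == t])
    } else {
      list(exon_rows[exon_parent_flat == gid])
    }
    lens <- vapply(tx_exons, function(rows) {
      if (!length(rows)) return(0)
      sum(ends[rows] - starts[rows] + 1)
    }, numeric(1))
    if (all(lens == 0)) stop("gene without exons: ", gid)
    rows <- tx_exons[[which.max(lens)]]
    models[[g]] <- gene_model(
      gene_id = gid, chromosome = chroms[gi],
      start = starts[gi], end = ends[gi], strand = strands[gi],
      exons = cbind(starts[rows], ends[rows])
    )
  }
  models
}

#' Read a protein FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of uppercase amino-acid sequences; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  validate_protein_set(seqs)
  seqs
}

validate_protein_set <- function(proteins) {
  if (length(proteins) == 0) return(invisible(proteins))
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("every protein needs an id")
  }
  if (anyDuplicated(names(proteins))) {
    stop("duplicate protein ids: ",
         paste(unique(names(proteins)[duplicated(names(proteins))]), collapse = ", "))
  }
  if (any(!nzchar(proteins))) {
    stop("empty sequence for: ", names(proteins)[!nzchar(proteins)][1])
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", proteins)
  if (any(bad)) {
    stop("non-amino-acid letters in: ", names(proteins)[bad][1])
  }
  invisible(proteins)
}

#' Write a protein FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70) {
  validate_protein_set(proteins)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(proteins)) {
    writeLines(paste0(">", names(proteins)[i]), con)
    seq <- proteins[[i]]
    starts <- seq.int(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))), con)
  }
  invisible(path)
}

#' Read a seed alignment in Stockholm format
#'
#' Returns the aligned rows plus the indices of the match columns, defined
#' as the columns with fewer than 50 percent gap characters; these are the
#' columns retained when building a profile with \code{\link{build_pssm}}.
#'
#' @param path Path to a Stockholm file.
#' @return List of class \code{"seed_alignment"} with elements \code{ids},
#'   \code{aligned} (equal-length aligned sequences) and
#'   \code{match_columns}.
#' @export
read_stockholm <- function(path) {
  aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
  rows <- as.character(Biostrings::unmasked(aln))
  if (!length(rows)) stop("empty alignment in ", path)
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  gaps <- mat %in% c("-", ".")
  dim(gaps) <- dim(mat)
  gap_frac <- colMeans(gaps)
  seed_alignment(ids = rownames(mat),
                 aligned = apply(mat, 1, paste, collapse = ""),
                 match_columns = which(gap_frac < 0.5))
}

#' @rdname read_stockholm
#' @param ids,aligned,match_columns Components of the alignment.
#' @export
seed_alignment <- function(ids, aligned, match_columns = NULL) {
  aligned <- toupper(aligned)
  if (length(aligned) < 1) stop("empty alignment")
  if (length(unique(nchar(aligned))) != 1) stop("ragged alignment rows")
  if (is.null(match_columns)) {
    mat <- do.call(rbind, strsplit(aligned, ""))
    match_columns <- which(colMeans(mat == "-" | mat == ".") < 0.5)
  }
  if (is.unsorted(match_columns, strictly = TRUE)) {
    stop("match_columns must be strictly increasing")
  }
  structure(list(ids = ids, aligned = unname(aligned),
                 match_columns = as.integer(match_columns)),
            class = "seed_alignment")
}

#' Write a seed alignment in Stockholm format
#' @param seed A \code{seed_alignment}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_stockholm <- function(seed, path) {
  stopifnot(inherits(seed, "seed_alignment"))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-20s %s", seed$ids, seed$aligned), con)
  writeLines("//", con)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape} that turn silent parse failures into errors
#' and write branch lengths with six-decimal precision, enough for a
#' round-trip to preserve the patristic distance matrix.
#'
#' @param path Path to a Newick file.
#' @return \code{read_newick}: an \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  tree
}

#' @rdname read_newick
#' @param tree A \code{phylo} object.
#' @param digits Decimal digits for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
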