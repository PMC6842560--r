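# Physicochemical properties of proteins: length, molecular weight from
# average residue masses, and isoelectric point by bisection over the
# Henderson-Hasselbalch net charge with the Bjellqvist pKa set.

# average (not monoisotopic) residue masses in daltons; a peptide's mass is
# the residue sum plus one water
AA_AVERAGE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

# Bjellqvist pKa values (the set behind the ExPASy-style pI): ionizable side
# chains plus the two termini
PKA_BJELLQVIST <- list(
  positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
)

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.01528 Da). Only the 20
#' standard residues are accepted; strip \code{'X'} before calling if the
#' sequence contains unknowns.
#'
#' @param protein Length-1 character vector.
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(protein) {
  chars <- strsplit(unname(protein), "")[[1]]
  if (!length(chars)) stop("empty sequence")
  masses <- AA_AVERAGE_MASS[chars]
  if (anyNA(masses)) {
    stop("non-standard residue(s): ",
         paste(unique(chars[is.na(masses)]), collapse = ", "))
  }
  sum(masses) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: each basic group (N-terminus, K, R, H)
#' contributes \eqn{1/(1+10^{pH-pKa})}, each acidic group (C-terminus, D, E,
#' C, Y) \eqn{-1/(1+10^{pKa-pH})}.
#'
#' @param protein Length-1 character vector.
#' @param ph pH value(s).
#' @param pka pKa table; defaults to the Bjellqvist set.
#' @return Net charge, vectorized over \code{ph}.
#' @export
protein_charge <- function(protein, ph, pka = PKA_BJELLQVIST) {
  chars <- strsplit(unname(protein), "")[[1]]
  if (!length(chars)) stop("empty sequence")
  counts <- table(chars)
  n_of <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
  pos_n <- c(Nterm = 1, K = n_of("K"), R = n_of("R"), H = n_of("H"))
  neg_n <- c(Cterm = 1, D = n_of("D"), E = n_of("E"), C = n_of("C"), Y = n_of("Y"))
  vapply(ph, function(p) {
    sum(pos_n / (1 + 10^(p - pka$positive[names(pos_n)]))) -
      sum(neg_n / (1 + 10^(pka$negative[names(neg_n)] - p)))
  }, numeric(1))
}

#' Isoelectric point of a protein
#'
#' pH at which the net charge vanishes, located by bisection on [0, 14]
#' until \eqn{|charge| < 10^{-4}}. The charge is strictly decreasing in pH,
#' so the root exists and is unique.
#'
#' @inheritParams protein_charge
#' @return The isoelectric point.
#' @export
isoelectric_point <- function(protein, pka = PKA_BJELLQVIST) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- protein_charge(protein, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physicochemical table for a protein set
#'
#' Length, molecular weight (kDa, 2 decimals as conventionally printed) and
#' isoelectric point for each protein. \code{'X'} residues are stripped
#' before computation.
#'
#' @param proteins Named character vector.
#' @return data.frame with columns \code{id}, \code{length_aa},
#'   \code{mw_kda}, \code{pi}.
#' @export
physchem_table <- function(proteins) {
  validate_protein_set(proteins)
  stripped <- gsub("X", "", proteins)
  data.frame(
    id = names(proteins),
    length_aa = nchar(unname(proteins)),
    mw_kda = round(vapply(stripped, molecular_weight, numeric(1)) / 1000, 2),
    pi = round(vapply(stripped, isoelectric_point, numeric(1)), 2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
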