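# Spectral-count abundance and N-terminal sequence features.

#' Kyte-Doolittle hydropathy scale
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Mean spectral count over identified timepoints
#'
#' Arithmetic mean of the spectral counts over the timepoints in which
#' the proteoform was actually identified; timepoints without an
#' identification are excluded, not zero-filled.
#'
#' @param counts Spectral counts at identified timepoints (`NA` entries
#'   are treated as not identified and dropped).
#' @return Mean spectral count.
#' @export
#' @examples
#' mean_spectral_counts(c(4, 6))   # 5
mean_spectral_counts <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) {
    stop("no identifications: cannot average spectral counts", call. = FALSE)
  }
  if (any(counts < 0)) stop("spectral counts must be >= 0", call. = FALSE)
  mean(counts)
}

#' Normalized spectral abundance factor
#'
#' NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j): each proteoform's
#' length-normalized spectral count as a fraction of the dataset total.
#' Lengths are mature proteoform lengths (database length minus start
#' position plus one), since proteoforms are start-specific.
#'
#' @param counts Mean spectral counts (>= 0, at least one positive).
#' @param lengths Proteoform lengths in residues (> 0).
#' @return Vector of NSAF values summing to 1.
#' @export
#' @examples
#' nsaf(c(10, 10), c(100, 50))   # 1/3, 2/3
nsaf <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("`counts` and `lengths` must have the same length", call. = FALSE)
  }
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  saf <- counts / lengths
  tot <- sum(saf)
  if (tot == 0) stop("all spectral counts are zero", call. = FALSE)
  saf / tot
}

#' Grand average of hydropathy of an N-terminal window
#'
#' Mean Kyte-Doolittle hydropathy over the first `n_residues` residues;
#' higher scores indicate greater hydrophobicity.  The study windows are
#' the 2 and 10 most N-terminal residues.
#'
#' @param sequence Amino-acid sequence (length >= `n_residues`).
#' @param n_residues Window size, typically 2 or 10.
#' @return GRAVY score.
#' @export
#' @examples
#' gravy("MVKLT", 2)    # (1.9 + 4.2)/2 = 3.05
gravy <- function(sequence, n_residues = 2) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < n_residues) {
    stop("sequence shorter than the ", n_residues, "-residue window",
         call. = FALSE)
  }
  aa <- strsplit(substr(sequence, 1, n_residues), "")[[1]]
  bad <- setdiff(aa, names(KYTE_DOOLITTLE))
  if (length(bad)) {
    stop("invalid residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  mean(KYTE_DOOLITTLE[aa])
}

#' Append abundance and sequence features to an annotated table
#'
#' Computes per-proteoform mean spectral counts from the quantification
#' table, NSAF over the dataset, and 2- and 10-residue GRAVY scores of
#' the proteoform N-terminus.  Disorder percentages and ubiquitination
#' evidence, when present as input columns, pass through untouched.
#'
#' @param records Annotated proteoform tibble (needs `accession`,
#'   `peptide`, `proteoform_length`).
#' @param quant Quantification tibble with `accession`, `timepoint_h`,
#'   `spectral_count`.
#' @return `records` with columns `mean_spc`, `nsaf`, `gravy2`,
#'   `gravy10` appended (`NA` where undefined, e.g. short peptides).
#' @export
compute_features <- function(records, quant) {
  spc <- vapply(records$accession, function(acc) {
    x <- quant$spectral_count[quant$accession == acc]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }, numeric(1))
  has <- !is.na(spc)
  ns <- rep(NA_real_, length(spc))
  if (any(has)) ns[has] <- nsaf(spc[has], records$proteoform_length[has])
  g <- function(n) vapply(records$peptide, function(p) {
    if (nchar(p) < n) NA_real_ else gravy(p, n)
  }, numeric(1))
  dplyr::mutate(records, mean_spc = unname(spc), nsaf = unname(ns),
                gravy2 = unname(g(2)), gravy10 = unname(g(10)))
}
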