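#' Standard terrestrial isotope abundances
#'
#' Natural isotopic abundances (mole fractions) used for all
#' natural-abundance mass-isotopomer calculations, indexed by element symbol.
#' For each element the vector entry at position \code{i} is the abundance of
#' the isotopologue with nominal mass shift \code{i - 1} relative to the
#' lightest isotope; impossible shifts carry abundance 0.  Values are the
#' IUPAC representative terrestrial abundances:
#' \itemize{
#'   \item H: 1H 0.999885, 2H 0.000115
#'   \item C: 12C 0.9893, 13C 0.0107
#'   \item N: 14N 0.99636, 15N 0.00364
#'   \item O: 16O 0.99757, 17O 0.00038, 18O 0.00205
#'   \item F: 19F 1 (monoisotopic)
#'   \item S: 32S 0.9499, 33S 0.0075, 34S 0.0425, 36S 0.0001
#'   \item P: 31P 1 (monoisotopic)
#' }
#'
#' @format A named list of numeric vectors; each vector sums to 1.
#' @export
isotopeAbundances <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  F = 1,
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  P = 1
)

# Default analyte: intact pentafluorobenzyl ester of alanine.  The exact
# GC/MS fragment monitored is configurable; only the relative M1 excess
# enters downstream ratios, so any fragment composition can be substituted.
.defaultFormulaCounts <- c(C = 10, H = 8, F = 5, N = 1, O = 2)

# Body-water amplification of alanine EM1 at low enrichment (the plateau
# EM1max / precursor p correlation used to overlay body water and protein
# label curves).
.defaultAmplification <- 2.7

# Default number of carbon-bound, exchange-labile hydrogen positions on
# alanine that can acquire deuterium from body water during synthesis.
.defaultNSites <- 4L
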