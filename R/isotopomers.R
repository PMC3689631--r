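## Mass-isotopomer arithmetic for the alanine analyte.
##
## All distributions are computed by per-element polynomial convolution: a
## single atom of element E contributes the polynomial whose coefficient at
## mass shift m is the abundance of its m-shifted isotope; a molecule is the
## product of one polynomial per atom, truncated at the requested order.

# truncated polynomial product: coefficients indexed by mass shift 0..K
.convTrunc <- function(a, b, K) {
  n <- K + 1L
  out <- numeric(n)
  la <- min(length(a), n)
  for (i in seq_len(la)) {
    if (a[i] == 0) next
    jmax <- min(length(b), n - i + 1L)
    idx <- seq_len(jmax)
    out[i + idx - 1L] <- out[i + idx - 1L] + a[i] * b[idx]
  }
  out
}

# p raised to the n-th convolution power, truncated at order K
# (binary exponentiation keeps rounding error ~ log2(n) convolutions deep)
.convPow <- function(p, n, K) {
  result <- c(1, numeric(K))
  base <- .convTrunc(p, c(1, numeric(K)), K)
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .convTrunc(result, base, K)
    base <- .convTrunc(base, base, K)
    n <- n %/% 2L
  }
  result
}

.naturalFractions <- function(counts, K) {
  out <- c(1, numeric(K))
  for (el in names(counts)) {
    if (counts[[el]] == 0L) next
    out <- .convTrunc(out, .convPow(isotopeAbundances[[el]], counts[[el]], K),
                      K)
  }
  out
}

#' Natural-abundance mass-isotopomer distribution
#'
#' Computes the isotopologue mass distribution of an analyte from standard
#' terrestrial isotope abundances (\code{\link{isotopeAbundances}}) by
#' per-element polynomial convolution, truncated at mass shift
#' \code{truncationOrder}.  Its M1 fraction is the baseline that measured M1
#' fractions are referenced against when forming EM1.
#'
#' @param formula An \code{\link{ElementalFormula}}.
#' @param truncationOrder Highest mass shift retained (default 4; EM1 only
#'   needs M0/M1 accurately and M4 keeps truncation error far below
#'   measurement noise).
#' @return An \code{\link{IsotopomerDistribution}}.
#' @examples
#' naturalAbundanceDistribution(elementalFormula(C = 3, H = 7, N = 1, O = 2))
#' @export
naturalAbundanceDistribution <- function(formula, truncationOrder = 4L) {
  stopifnot(is(formula, "ElementalFormula"))
  validObject(formula)
  if (truncationOrder < 1L)
    stop("truncationOrder must be >= 1")
  .newDistribution(.naturalFractions(formula@counts,
                                     as.integer(truncationOrder)))
}

.checkEnrichment <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 0.70)
    stop("precursor enrichment must lie in [0, 0.70] ",
         "(body water cannot exceed dose purity)")
  p
}

#' Mass-isotopomer distribution of fully newly synthesized analyte
#'
#' Distribution of a 100%-newly-synthesized analyte population at body-water
#' deuterium enrichment \code{p}: the \code{nSites} labelable hydrogens carry
#' deuterium with per-site probability (natural 2H abundance +
#' \code{siteExchangeFraction * p}) -- their natural 2H contribution is
#' replaced by the labeling term, not double-counted -- binomially convolved
#' with the natural-abundance distribution of the remaining atoms.  At
#' \code{p = 0} this reduces exactly to
#' \code{\link{naturalAbundanceDistribution}}.
#'
#' @param formula An \code{\link{ElementalFormula}}; must contain at least
#'   \code{nSites} hydrogens.
#' @param model A \code{\link{LabelingModel}}.
#' @param p Precursor (body-water) 2H mole-fraction excess, in [0, 0.70].
#' @param truncationOrder Highest mass shift retained.
#' @param naturalAbundance Set \code{FALSE} to disable natural isotope
#'   abundance entirely (pure binomial labeling; useful for analytic
#'   checks).
#' @return An \code{\link{IsotopomerDistribution}}.
#' @export
labeledDistribution <- function(formula, model, p, truncationOrder = 4L,
                                naturalAbundance = TRUE) {
  stopifnot(is(formula, "ElementalFormula"), is(model, "LabelingModel"))
  validObject(formula); validObject(model)
  .checkEnrichment(p)
  K <- as.integer(truncationOrder)
  if (K < 1L) stop("truncationOrder must be >= 1")
  n <- model@nSites
  nH <- if ("H" %in% names(formula@counts)) formula@counts[["H"]] else 0L
  if (nH < n)
    stop("formula has fewer hydrogens than the model's labeling sites")
  q <- model@siteExchangeFraction * p +
    if (naturalAbundance) isotopeAbundances$H[2] else 0
  site <- c(1 - q, q)
  labeled <- .convPow(site, n, K)
  if (naturalAbundance) {
    rest <- formula@counts
    rest[["H"]] <- nH - n
    labeled <- .convTrunc(labeled, .naturalFractions(rest, K), K)
  }
  .newDistribution(labeled)
}

#' Excess M1 fraction (EM1)
#'
#' The labeling readout: molar fraction of analyte molecules with one excess
#' mass unit above the natural-abundance M1 fraction, i.e. measured M1 minus
#' baseline M1.  Not clamped: a noisy measurement may come out slightly
#' negative, and clamping is deferred to the kinetics layer.
#'
#' @param measured,baseline \code{\link{IsotopomerDistribution}} objects
#'   sharing the same truncation order.
#' @return EM1 excess (dimensionless).
#' @export
em1Excess <- function(measured, baseline) {
  stopifnot(is(measured, "IsotopomerDistribution"),
            is(baseline, "IsotopomerDistribution"))
  if (measured@truncationOrder != baseline@truncationOrder)
    stop("measured and baseline distributions have mismatched ",
         "truncation orders")
  measured@fractions[2L] - baseline@fractions[2L]
}

#' Maximal EM1 at a given precursor enrichment
#'
#' EM1 of a hypothetical 100%-newly-synthesized analyte population at
#' time-averaged precursor enrichment \code{pBar}; the denominator of the
#' fractional-synthesis ratio.
#'
#' @param pBar Time-averaged body-water enrichment, in [0, 0.70].
#' @param model A \code{\link{LabelingModel}} (default: calibrated model,
#'   see \code{\link{defaultLabelingModel}}).
#' @param formula Analyte \code{\link{ElementalFormula}} (default:
#'   pentafluorobenzyl alanine).
#' @param truncationOrder Highest mass shift retained.
#' @return EM1max (dimensionless); 0 when \code{pBar = 0}.
#' @examples
#' em1Max(0.01)          # ~ 0.027: the 2.7x amplification at low enrichment
#' @export
em1Max <- function(pBar, model = defaultLabelingModel(formula),
                   formula = defaultAnalyteFormula(), truncationOrder = 4L) {
  em1Excess(labeledDistribution(formula, model, pBar, truncationOrder),
            naturalAbundanceDistribution(formula, truncationOrder))
}

#' Realized low-enrichment amplification of a labeling model
#'
#' The limiting ratio EM1max(p)/p as p -> 0, evaluated at \code{p = 1e-6}.
#' This is the factor by which body-water enrichment is amplified into
#' alanine EM1 at plateau (100% new protein) and the scale used to overlay
#' body-water and protein label curves.
#'
#' @param model A \code{\link{LabelingModel}}.
#' @param formula Analyte \code{\link{ElementalFormula}}.
#' @return Dimensionless amplification in (0, nSites].
#' @export
amplification <- function(model, formula = defaultAnalyteFormula()) {
  p0 <- 1e-6
  em1Max(p0, model, formula) / p0
}

.calibrationCache <- new.env(parent = emptyenv())

#' Calibrate the site exchange fraction to a target amplification
#'
#' The per-site exchange probability is chosen so that the realized
#' low-enrichment amplification (\code{\link{amplification}}) equals
#' \code{target} for the given analyte formula.  EM1max is linear in the
#' exchange fraction at low enrichment, so a single proportional solve
#' suffices.
#'
#' @param target Desired low-enrichment EM1max/p ratio (default 2.7, the
#'   empirical body-water to alanine correlation).
#' @param formula Analyte \code{\link{ElementalFormula}}.
#' @param nSites Number of labelable positions (default 4 for alanine).
#' @return Calibrated site exchange fraction in (0, 1].
#' @export
calibrateExchangeFraction <- function(target = .defaultAmplification,
                                      formula = defaultAnalyteFormula(),
                                      nSites = .defaultNSites) {
  unitModel <- labelingModel(nSites = nSites, siteExchangeFraction = 1)
  slope <- amplification(unitModel, formula)
  frac <- target / slope
  if (frac <= 0 || frac > 1)
    stop("target amplification ", target, " is not reachable with ",
         nSites, " sites (requires exchange fraction ", signif(frac, 4), ")")
  frac
}

#' Default calibrated labeling model
#'
#' Four alanine C-H labeling sites with the site exchange fraction
#' calibrated (once per formula, cached) so the low-enrichment limit of
#' EM1max(p)/p equals 2.7.
#'
#' @param formula Analyte \code{\link{ElementalFormula}} the calibration is
#'   performed against.
#' @return A \code{\link{LabelingModel}}.
#' @export
defaultLabelingModel <- function(formula = defaultAnalyteFormula()) {
  key <- paste0(paste0(names(formula@counts), formula@counts,
                       collapse = ""), "_", .defaultNSites, "_",
                .defaultAmplification)
  if (is.null(.calibrationCache[[key]]))
    .calibrationCache[[key]] <- labelingModel(
      nSites = .defaultNSites,
      siteExchangeFraction = calibrateExchangeFraction(formula = formula))
  .calibrationCache[[key]]
}
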