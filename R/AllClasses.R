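#' @import methods
NULL

## ---------------------------------------------------------------------------
## ElementalFormula
## ---------------------------------------------------------------------------

#' Elemental composition of an analyte
#'
#' Holds per-element atom counts for the molecule (or GC/MS fragment) whose
#' mass-isotopomer pattern is being modeled.  The default analyte throughout
#' the package is the pentafluorobenzyl derivative of alanine
#' (\code{C10 H8 F5 N O2}) measured by NCI-GC/MS.
#'
#' @slot counts Named integer vector of atom counts; names are element
#'   symbols with tabulated isotope abundances (see
#'   \code{\link{isotopeAbundances}}).
#' @export
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  if (length(cnt) == 0L || sum(cnt) == 0L)
    return("formula must contain at least one atom")
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    return("element counts must be named")
  if (any(cnt < 0L))
    return("element counts must be non-negative")
  unknown <- setdiff(names(cnt), names(isotopeAbundances))
  if (length(unknown))
    return(paste0("no isotope abundance table for element(s): ",
                  paste(unknown, collapse = ", ")))
  if (anyDuplicated(names(cnt)))
    return("duplicated element symbols")
  TRUE
})

#' Construct an ElementalFormula
#'
#' @param ... Either a single named numeric vector/list of atom counts
#'   (e.g. \code{c(C = 3, H = 7, N = 1, O = 2)}) or counts passed as named
#'   arguments (\code{elementalFormula(C = 3, H = 7, N = 1, O = 2)}).
#' @return An \code{ElementalFormula} object.
#' @examples
#' alanine <- elementalFormula(C = 3, H = 7, N = 1, O = 2)
#' pfbAlanine <- defaultAnalyteFormula()
#' @export
elementalFormula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ||
      (length(args) == 1L && (is.list(args[[1L]]) ||
                              (is.numeric(args[[1L]]) && length(args[[1L]]) > 1L) ||
                              !is.null(names(args[[1L]]))) && is.null(names(args))))
    args <- as.list(unlist(args[[1L]]))
  cnt <- unlist(args)
  if (length(cnt) == 0L)
    stop("empty formula: at least one atom is required")
  counts <- as.integer(round(cnt))
  names(counts) <- names(cnt)
  counts <- counts[counts > 0L]
  if (length(counts) == 0L)
    stop("empty formula: at least one atom is required")
  new("ElementalFormula", counts = counts)
}

#' Default analyte composition (pentafluorobenzyl alanine)
#'
#' @return \code{ElementalFormula} for C10H8F5NO2, the intact
#'   pentafluorobenzyl ester of alanine.
#' @export
defaultAnalyteFormula <- function() {
  elementalFormula(.defaultFormulaCounts)
}

#' @describeIn elementalFormula Total number of atoms in a formula.
#' @param formula An \code{ElementalFormula}.
#' @export
atomCount <- function(formula) sum(formula@counts)

setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula: ",
      paste0(names(object@counts), object@counts, collapse = " "), "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## IsotopomerDistribution
## ---------------------------------------------------------------------------

#' Mass-isotopomer distribution
#'
#' Ordered mole fractions of isotopologues with nominal masses M0..Mk (k =
#' truncation order).  The M1 fraction of protein-bound alanine, in excess
#' over natural abundance, is the EM1 labeling readout used throughout.
#'
#' @slot fractions Numeric vector of length \code{truncationOrder + 1};
#'   element \code{i} is the mole fraction of the M(i-1) isotopologue.
#' @slot truncationOrder Integer, highest mass shift retained.
#' @export
setClass("IsotopomerDistribution",
         representation(fractions = "numeric", truncationOrder = "integer"))

setValidity("IsotopomerDistribution", function(object) {
  fr <- object@fractions
  k <- object@truncationOrder
  if (length(k) != 1L || is.na(k) || k < 1L)
    return("truncationOrder must be a single integer >= 1")
  if (length(fr) != k + 1L)
    return("fractions must have length truncationOrder + 1")
  if (any(!is.finite(fr)) || any(fr < -1e-12) || any(fr > 1 + 1e-9))
    return("fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-9)
    return("fractions must sum to at most 1")
  TRUE
})

.newDistribution <- function(fractions) {
  new("IsotopomerDistribution",
      fractions = pmax(fractions, 0),
      truncationOrder = length(fractions) - 1L)
}

setMethod("show", "IsotopomerDistribution", function(object) {
  cat("IsotopomerDistribution (M0..M", object@truncationOrder, ")\n",
      sep = "")
  v <- signif(object@fractions, 6)
  names(v) <- paste0("M", seq_along(v) - 1L)
  print(v)
})

## ---------------------------------------------------------------------------
## LabelingModel
## ---------------------------------------------------------------------------

#' Deuterium labeling model for the analyte
#'
#' Describes how body-water deuterium enters newly synthesized protein-bound
#' alanine: \code{nSites} carbon-bound hydrogen positions each equilibrate
#' with body water with probability \code{siteExchangeFraction}, so a site's
#' deuterium probability in new protein is the natural abundance of 2H plus
#' \code{siteExchangeFraction * p} at precursor enrichment \code{p}.
#'
#' @slot nSites Integer count of labelable hydrogen positions (4 for
#'   alanine).
#' @slot siteExchangeFraction Probability in (0, 1] that a site equilibrates
#'   with body water.
#' @export
setClass("LabelingModel",
         representation(nSites = "integer", siteExchangeFraction = "numeric"))

setValidity("LabelingModel", function(object) {
  if (length(object@nSites) != 1L || object@nSites < 1L)
    return("nSites must be a single integer >= 1")
  c_ <- object@siteExchangeFraction
  if (length(c_) != 1L || !is.finite(c_) || c_ <= 0 || c_ > 1)
    return("siteExchangeFraction must lie in (0, 1]")
  TRUE
})

#' Construct a LabelingModel
#'
#' @param nSites Number of labelable hydrogen positions.
#' @param siteExchangeFraction Per-site probability of equilibrating with
#'   body water.
#' @return A \code{LabelingModel}.
#' @seealso \code{\link{defaultLabelingModel}} for the calibrated default.
#' @export
labelingModel <- function(nSites = .defaultNSites, siteExchangeFraction) {
  new("LabelingModel", nSites = as.integer(nSites),
      siteExchangeFraction = siteExchangeFraction)
}

setMethod("show", "LabelingModel", function(object) {
  cat("LabelingModel: nSites = ", object@nSites,
      ", siteExchangeFraction = ", signif(object@siteExchangeFraction, 6),
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## DosingSchedule
## ---------------------------------------------------------------------------

#' Heavy-water dosing schedule
#'
#' Explicit list of oral 2H2O dosing events.
#'
#' @slot events \code{data.frame} with columns \code{day} (days from study
#'   start, non-decreasing), \code{volumeML} (dose volume, mL, > 0) and
#'   \code{purity} (2H2O mole fraction of the dose, in (0, 1]).
#' @export
setClass("DosingSchedule", representation(events = "data.frame"))

setValidity("DosingSchedule", function(object) {
  ev <- object@events
  need <- c("day", "volumeML", "purity")
  if (!all(need %in% names(ev)))
    return("events must have columns day, volumeML, purity")
  if (nrow(ev)) {
    if (is.unsorted(ev$day))
      return("event days must be non-decreasing")
    if (any(ev$volumeML <= 0))
      return("dose volumes must be > 0")
    if (any(ev$purity <= 0 | ev$purity > 1))
      return("dose purity must lie in (0, 1]")
  }
  TRUE
})

#' @rdname DosingSchedule-class
#' @param x A \code{DosingSchedule}.
#' @export
dosingEvents <- function(x) x@events

setMethod("show", "DosingSchedule", function(object) {
  ev <- object@events
  cat("DosingSchedule: ", nrow(ev), " events",
      if (nrow(ev)) paste0(" over days [", min(ev$day), ", ",
                           round(max(ev$day), 3), "]"),
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EnrichmentCurve
## ---------------------------------------------------------------------------

#' Body-water deuterium enrichment versus time
#'
#' Body-water 2H enrichment (mole-fraction excess over natural abundance) on
#' a time grid, either simulated from a dosing schedule or interpolated from
#' measured saliva enrichments.  Simulated curves additionally carry their
#' impulse decomposition (per-dose enrichment increments and the first-order
#' water turnover rate) so time averages can be integrated in closed form.
#'
#' @slot days Strictly increasing numeric time grid (days).
#' @slot enrichment Enrichment values on the grid, in [0, 0.70].
#' @slot provenance \code{"simulated"} or \code{"measured-interpolated"}.
#' @slot impulses \code{data.frame(day, delta)} of per-dose enrichment steps
#'   (simulated curves only; zero rows otherwise).
#' @slot decayRate First-order water turnover rate (per day) used for the
#'   impulse decomposition; \code{NA} for measured curves.
#' @export
setClass("EnrichmentCurve",
         representation(days = "numeric", enrichment = "numeric",
                        provenance = "character", impulses = "data.frame",
                        decayRate = "numeric"))

setValidity("EnrichmentCurve", function(object) {
  d <- object@days
  e <- object@enrichment
  if (length(d) != length(e))
    return("days and enrichment must have equal length")
  if (length(d) < 1L)
    return("curve must contain at least one point")
  if (any(diff(d) <= 0))
    return("time grid must be strictly increasing")
  if (any(e < -1e-12) || any(e > 0.70 + 1e-12))
    return("enrichment values must lie in [0, 0.70]")
  if (!object@provenance %in% c("simulated", "measured-interpolated"))
    return("provenance must be 'simulated' or 'measured-interpolated'")
  TRUE
})

setMethod("show", "EnrichmentCurve", function(object) {
  cat("EnrichmentCurve (", object@provenance, "): ",
      length(object@days), " points over days [",
      round(min(object@days), 3), ", ", round(max(object@days), 3),
      "], peak enrichment ", signif(max(object@enrichment), 4), "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## TapeStripSeries
## ---------------------------------------------------------------------------

#' Tape-strip EM1 time series for one skin site
#'
#' Measured alanine EM1 excess values from serial tape strips at a single
#' anatomical site, together with the body-water enrichment curve of the
#' subject (the labeling precursor).
#'
#' @slot subjectId,siteId Character identifiers.
#' @slot lesional Logical; \code{TRUE} for psoriatic plaque sites.
#' @slot measurements \code{data.frame(day, em1)} with strictly increasing
#'   days (>= 0).
#' @slot curve The subject's \code{\link{EnrichmentCurve}}.
#' @export
setClass("TapeStripSeries",
         representation(subjectId = "character", siteId = "character",
                        lesional = "logical", measurements = "data.frame",
                        curve = "EnrichmentCurve"))

setValidity("TapeStripSeries", function(object) {
  m <- object@measurements
  if (!all(c("day", "em1") %in% names(m)))
    return("measurements must have columns day and em1")
  if (nrow(m)) {
    if (any(m$day < 0))
      return("measurement days must be >= 0")
    if (any(diff(m$day) <= 0))
      return("measurement days must be strictly increasing within a site")
  }
  if (length(object@lesional) != 1L || is.na(object@lesional))
    return("lesional must be TRUE or FALSE")
  TRUE
})

#' Construct a TapeStripSeries
#'
#' @param subjectId,siteId Identifiers.
#' @param lesional Logical lesional flag.
#' @param day,em1 Numeric vectors of sampling days and measured EM1 excess.
#' @param curve The subject's \code{\link{EnrichmentCurve}}.
#' @return A \code{TapeStripSeries}.
#' @export
tapeStripSeries <- function(subjectId, siteId, lesional, day, em1, curve) {
  o <- order(day)
  new("TapeStripSeries", subjectId = as.character(subjectId),
      siteId = as.character(siteId), lesional = as.logical(lesional),
      measurements = data.frame(day = day[o], em1 = em1[o]),
      curve = curve)
}

setMethod("show", "TapeStripSeries", function(object) {
  cat("TapeStripSeries: subject ", object@subjectId, ", site ",
      object@siteId, if (object@lesional) " (lesional)" else " (uninvolved)",
      ", ", nrow(object@measurements), " tape strips\n", sep = "")
})

## ---------------------------------------------------------------------------
## ConveyorFit
## ---------------------------------------------------------------------------

#' Fitted conveyor-belt kinetics for one site
#'
#' Result of fitting the delayed mono-exponential rise
#' \code{f(t) = 1 - exp(-k (t - tau))} (0 for \code{t <= tau}) to fractional
#' synthesis values: \code{tau} is the transit lag from basal synthesis to
#' surface appearance and \code{k} the stratum-corneum replacement rate.
#'
#' @slot subjectId,siteId Character identifiers (may be empty).
#' @slot lesional Logical lesional flag.
#' @slot tau Lag estimate, days.
#' @slot k Replacement rate estimate, per day.
#' @slot rss Residual sum of squares at the optimum.
#' @slot tauCI,kCI Numeric length-2 bootstrap percentile confidence bounds
#'   (\code{NA} if the bootstrap was not run).
#' @slot nPoints Number of fitted points.
#' @slot flags Character vector of fit diagnostics: may contain
#'   \code{"nonIdentifiableK"} (no rise observed; \code{tau} is a lower
#'   bound), \code{"kLowerBound"} (all post-lag observations saturated
#'   near 1, so \code{k} is only bounded from below) and/or
#'   \code{"sparseRise"} (a single point on the rise; \code{tau} and
#'   \code{k} are jointly unidentifiable and \code{tau} is reported at its
#'   lower bound).
#' @export
setClass("ConveyorFit",
         representation(subjectId = "character", siteId = "character",
                        lesional = "logical", tau = "numeric", k = "numeric",
                        rss = "numeric", tauCI = "numeric", kCI = "numeric",
                        nPoints = "integer", flags = "character"))

setValidity("ConveyorFit", function(object) {
  if (object@tau < 0) return("tau must be >= 0")
  if (object@k <= 0) return("k must be > 0")
  if (length(object@tauCI) != 2L || length(object@kCI) != 2L)
    return("CI slots must have length 2")
  ok <- function(ci, est) any(is.na(ci)) ||
    (ci[1] <= est + 1e-9 && est <= ci[2] + 1e-9)
  if (!ok(object@tauCI, object@tau))
    return("tau estimate must lie within its CI")
  if (!ok(object@kCI, object@k))
    return("k estimate must lie within its CI")
  TRUE
})

setMethod("show", "ConveyorFit", function(object) {
  cat("ConveyorFit", if (nzchar(object@subjectId))
        paste0(" [", object@subjectId, "/", object@siteId,
               if (object@lesional) ", lesional" else ", uninvolved", "]"),
      ": tau = ", signif(object@tau, 4), " d",
      if (!any(is.na(object@tauCI)))
        paste0(" (", signif(object@tauCI[1], 3), "-",
               signif(object@tauCI[2], 3), ")"),
      ", k = ", signif(object@k, 4), " /d",
      ", n = ", object@nPoints,
      if (length(object@flags)) paste0(" [", paste(object@flags,
                                                   collapse = ", "), "]"),
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## SpectralCountTable
## ---------------------------------------------------------------------------

#' Spectral-count proteomics table
#'
#' Per-protein spectral counting results for one skin condition, in the
#' layout of a label-free LC-MS/MS summary: protein name, number of unique
#' peptides, total peptide count (spectral count) and molecular weight.
#'
#' @slot condition Condition label, e.g. \code{"uninvolved"} or
#'   \code{"psoriatic"}.
#' @slot records \code{data.frame} with columns \code{proteinName},
#'   \code{uniquePeptides}, \code{totalPeptideCount}, \code{molWt} (Da).
#' @export
setClass("SpectralCountTable",
         representation(condition = "character", records = "data.frame"))

setValidity("SpectralCountTable", function(object) {
  r <- object@records
  need <- c("proteinName", "uniquePeptides", "totalPeptideCount", "molWt")
  if (!all(need %in% names(r)))
    return(paste("records must have columns",
                 paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$proteinName))
      return("protein names must be unique within a table")
    if (any(r$uniquePeptides < 1))
      return("uniquePeptides must be >= 1")
    if (any(r$totalPeptideCount < r$uniquePeptides))
      return("totalPeptideCount must be >= uniquePeptides")
    if (any(r$molWt <= 0))
      return("molecular weights must be > 0")
  }
  TRUE
})

#' Construct a SpectralCountTable
#'
#' @param condition Condition label.
#' @param records Data frame with columns \code{proteinName},
#'   \code{uniquePeptides}, \code{totalPeptideCount}, \code{molWt}.
#' @return A \code{SpectralCountTable}.
#' @export
spectralCountTable <- function(condition, records) {
  new("SpectralCountTable", condition = as.character(condition),
      records = as.data.frame(records))
}

setMethod("show", "SpectralCountTable", function(object) {
  cat("SpectralCountTable (", object@condition, "): ",
      nrow(object@records), " proteins, ",
      sum(object@records$totalPeptideCount), " total spectral counts\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## CohortBundle
## ---------------------------------------------------------------------------

#' Synthetic study cohort
#'
#' Everything a heavy-water tape-strip study produces, generated by
#' \code{\link{simulateCohort}}: per-subject dosing schedules and body-water
#' curves, saliva enrichment measurements, per-site tape-strip EM1 tables,
#' TEWL duplicate readings, spectral-count tables and the generating truth.
#'
#' @slot schedules Named list of \code{\link{DosingSchedule}} per subject.
#' @slot curves Named list of \code{\link{EnrichmentCurve}} per subject.
#' @slot saliva \code{data.frame(subject_id, day, enrichment_fraction)}.
#' @slot tapeStrips \code{data.frame(subject_id, site_id, lesional, day,
#'   em1)}.
#' @slot tewl \code{data.frame(subject_id, site_id, lesional, day,
#'   reading_1, reading_2)}.
#' @slot spectralCounts Named list of \code{\link{SpectralCountTable}}.
#' @slot truth \code{data.frame} of generating parameters, one row per site.
#' @slot seed Integer seed the cohort was generated from.
#' @slot config List of generator settings.
#' @export
setClass("CohortBundle",
         representation(schedules = "list", curves = "list",
                        saliva = "data.frame", tapeStrips = "data.frame",
                        tewl = "data.frame", spectralCounts = "list",
                        truth = "data.frame", seed = "integer",
                        config = "list"))

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle: ", length(object@schedules), " subjects, ",
      nrow(object@truth), " sites, seed ", object@seed, "\n", sep = "")
})
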