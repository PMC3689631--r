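## Body-water deuterium enrichment: dosing protocol expansion, a
## one-compartment impulse-dose forward model, interpolation of measured
## saliva enrichments, and the time-averaged precursor enrichment.

#' One-compartment body-water parameters
#'
#' @param bodyWaterVolume Total body water, liters (default 42, textbook
#'   adult value).
#' @param waterTurnoverRate First-order water elimination rate, per day
#'   (default 0.10, i.e. ~7-day water half-life).
#' @return A validated list with components \code{bodyWaterVolume} and
#'   \code{waterTurnoverRate}.
#' @export
bodyWaterParams <- function(bodyWaterVolume = 42, waterTurnoverRate = 0.10) {
  if (bodyWaterVolume <= 0) stop("bodyWaterVolume must be > 0")
  if (waterTurnoverRate < 0) stop("waterTurnoverRate must be >= 0")
  list(bodyWaterVolume = bodyWaterVolume,
       waterTurnoverRate = waterTurnoverRate)
}

# intra-day dose times for "twice daily" (08:00 and 20:00) and generalized
# even spacing for other dose counts
.doseTimesOfDay <- function(dosesPerDay) {
  if (dosesPerDay == 1L) return(1 / 3)
  if (dosesPerDay == 2L) return(c(1 / 3, 5 / 6))
  seq(1 / 3, 5 / 6, length.out = dosesPerDay)
}

#' Expand a weekly dosing protocol into explicit dosing events
#'
#' Expands a protocol such as "50 mL of 70% 2H2O twice daily Monday through
#' Friday for 16 to 38 days" into an explicit \code{\link{DosingSchedule}}.
#' Day 0 is the first study day; \code{weekdayPattern} gives the dosing days
#' of the week with 1 = Monday ... 7 = Sunday, and the study is assumed to
#' start on a Monday.
#'
#' @param startDay First dosing day (default 0).
#' @param durationDays Length of the dosing period in days, in [1, 365].
#' @param doseVolume Volume per dose, mL (default 50).
#' @param purity 2H2O mole fraction of the dose, in (0, 1] (default 0.70).
#' @param dosesPerDay Number of doses per dosing day (default 2).
#' @param weekdayPattern Integer vector of dosing weekdays (default Monday
#'   through Friday, \code{1:5}).
#' @return A \code{\link{DosingSchedule}}.
#' @examples
#' # 16-day study, twice daily Mon-Fri: 12 dosing days, 24 events
#' nrow(dosingEvents(buildProtocolSchedule(durationDays = 16)))
#' @export
buildProtocolSchedule <- function(startDay = 0, durationDays,
                                  doseVolume = 50, purity = 0.70,
                                  dosesPerDay = 2L,
                                  weekdayPattern = 1:5) {
  if (durationDays < 1 || durationDays > 365)
    stop("durationDays must lie in [1, 365]")
  if (doseVolume <= 0) stop("doseVolume must be > 0")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (length(weekdayPattern) == 0L)
    stop("weekdayPattern must contain at least one weekday")
  if (any(!weekdayPattern %in% 1:7))
    stop("weekdayPattern entries must lie in 1..7")
  days <- seq.int(0L, as.integer(ceiling(durationDays)) - 1L)
  weekday <- (days %% 7L) + 1L
  doseDays <- days[weekday %in% weekdayPattern]
  tod <- .doseTimesOfDay(as.integer(dosesPerDay))
  eventDay <- startDay + rep(doseDays, each = length(tod)) +
    rep(tod, times = length(doseDays))
  new("DosingSchedule",
      events = data.frame(day = sort(eventDay),
                          volumeML = doseVolume,
                          purity = purity))
}

#' Simulate body-water enrichment from a dosing schedule
#'
#' One-compartment impulse-dose model: each dose instantaneously raises
#' body-water enrichment by \code{volumeML * purity / (bodyWaterVolume in
#' mL)} and enrichment decays first-order at \code{waterTurnoverRate}
#' between doses.  The curve is the closed-form superposition of
#' exponentially decaying impulses, emitted on \code{grid} (default: 0.05-day
#' spacing over the schedule span plus a 10-day tail).  The impulse
#' decomposition is retained on the returned object so downstream time
#' averages are exact.
#'
#' @param schedule A \code{\link{DosingSchedule}}.
#' @param params \code{\link{bodyWaterParams}}.
#' @param grid Optional increasing numeric time grid (days).
#' @return An \code{\link{EnrichmentCurve}} with provenance
#'   \code{"simulated"}.
#' @export
simulateBodyWater <- function(schedule, params = bodyWaterParams(),
                              grid = NULL) {
  stopifnot(is(schedule, "DosingSchedule"))
  validObject(schedule)
  ev <- schedule@events
  if (is.null(grid)) {
    end <- if (nrow(ev)) max(ev$day) + 10 else 10
    grid <- seq(0, ceiling(end / 0.05) * 0.05, by = 0.05)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  delta <- if (nrow(ev)) ev$volumeML * ev$purity /
    (params$bodyWaterVolume * 1000) else numeric(0)
  kw <- params$waterTurnoverRate
  impulses <- data.frame(day = ev$day, delta = delta)
  enr <- .impulseEnrichment(grid, impulses, kw)
  new("EnrichmentCurve", days = grid, enrichment = enr,
      provenance = "simulated", impulses = impulses, decayRate = kw)
}

# superposition of decaying impulses evaluated at times t (vectorized)
.impulseEnrichment <- function(t, impulses, kw) {
  if (nrow(impulses) == 0L) return(numeric(length(t)))
  vapply(t, function(ti) {
    active <- impulses$day <= ti
    sum(impulses$delta[active] * exp(-kw * (ti - impulses$day[active])))
  }, numeric(1))
}

#' Interpolate measured saliva enrichments into a curve
#'
#' Piecewise-linear interpolation through measured (day, enrichment) saliva
#' points, held flat before the first and after the last point.  If no
#' measurement exists at or before day 0, enrichment 0 at day 0 is assumed
#' (labeling starts at study start) and the point (0, 0) is prepended.
#'
#' @param salivaPoints \code{data.frame} (or 2-column matrix) with columns
#'   \code{day} and \code{enrichment}; at least 2 points with distinct days.
#' @return An \code{\link{EnrichmentCurve}} with provenance
#'   \code{"measured-interpolated"}.
#' @export
interpolateMeasured <- function(salivaPoints) {
  sp <- as.data.frame(salivaPoints)
  if (ncol(sp) >= 2L && !all(c("day", "enrichment") %in% names(sp)))
    names(sp)[1:2] <- c("day", "enrichment")
  if (nrow(sp) < 2L)
    stop("insufficient data: at least 2 saliva points are required")
  if (anyDuplicated(sp$day))
    stop("saliva measurement days must be distinct")
  sp <- sp[order(sp$day), , drop = FALSE]
  if (min(sp$day) > 0)
    sp <- rbind(data.frame(day = 0, enrichment = 0), sp)
  new("EnrichmentCurve", days = sp$day, enrichment = sp$enrichment,
      provenance = "measured-interpolated",
      impulses = data.frame(day = numeric(0), delta = numeric(0)),
      decayRate = NA_real_)
}

#' Evaluate an enrichment curve at arbitrary times
#'
#' Simulated curves are evaluated from their closed-form impulse
#' superposition (exact); measured curves by linear interpolation, held flat
#' outside the measured span.
#'
#' @param curve An \code{\link{EnrichmentCurve}}.
#' @param t Numeric vector of times (days).
#' @return Enrichment values at \code{t}.
#' @export
enrichmentAt <- function(curve, t) {
  stopifnot(is(curve, "EnrichmentCurve"))
  if (curve@provenance == "simulated")
    .impulseEnrichment(t, curve@impulses, curve@decayRate)
  else
    stats::approx(curve@days, curve@enrichment, xout = t, rule = 2)$y
}

#' Time-averaged precursor enrichment
#'
#' The time-averaged body-water enrichment from labeling start (day 0) to
#' the tape-strip day \code{t}: \code{(1/t) * integral of the curve over [0,
#' t]}.  Measured (piecewise-linear) curves are integrated by the trapezoid
#' rule on their native grid, which is exact for them; simulated curves are
#' integrated in closed form from their impulse decomposition (each impulse
#' contributes \code{delta * (1 - exp(-kw (t - t_dose))) / kw}).  Times
#' beyond the curve span extrapolate by the held last value, with a warning.
#'
#' @param curve An \code{\link{EnrichmentCurve}}.
#' @param t Tape-strip day, > 0.
#' @return Mean enrichment over [0, t] (dimensionless).
#' @export
timeAveragedEnrichment <- function(curve, t) {
  stopifnot(is(curve, "EnrichmentCurve"))
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("t must be a single day > 0 (the precursor average is undefined ",
         "at or before labeling start)")
  if (t > max(curve@days) + 1e-9 && curve@provenance != "simulated")
    warning("t is beyond the measured span; extrapolating by last value")
  if (curve@provenance == "simulated") {
    imp <- curve@impulses
    active <- imp$day <= t
    if (!any(active)) return(0)
    kw <- curve@decayRate
    dt <- t - imp$day[active]
    area <- if (kw > 0)
      sum(imp$delta[active] * (1 - exp(-kw * dt)) / kw)
    else
      sum(imp$delta[active] * dt)
    return(area / t)
  }
  # piecewise-linear measured curve: trapezoid on native knots, exact
  d <- curve@days
  e <- curve@enrichment
  knots <- sort(unique(c(0, d[d > 0 & d < t], t)))
  vals <- stats::approx(d, e, xout = knots, rule = 2)$y
  area <- sum(diff(knots) * (head(vals, -1) + vals[-1]) / 2)
  area / t
}

#' @importFrom utils head
NULL
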