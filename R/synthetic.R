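## Seeded synthetic cohort generator.  Produces a study-shaped bundle --
## dosing schedules, body-water curves, saliva points, tape-strip EM1
## tables, TEWL duplicates and spectral-count tables -- by running the
## package's own forward models, so every analysis stage can be validated
## closed-loop against known truth.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions being emulated: twice-daily 50 mL x
#' 70% doses Monday-Friday for 16-38 days; lesional transit lags of 3-8
#' days with replacement fast enough that the stratum corneum turns over in
#' under 5 days (1 - exp(-5 k) > 0.99); uninvolved lags of 10-20 days with
#' slow replacement (plateau over ~2-3 weeks); tape strips every 2-5 days;
#' multiplicative GC/MS noise on EM1; lesional TEWL well above non-lesional.
#'
#' @param sitesPerGroup Lesional and uninvolved sites per subject
#'   (default 2).
#' @param durationRange Dosing duration range in days (default c(16, 38);
#'   drawn per subject as an integer).
#' @param doseVolume,dosePurity,dosesPerDay,weekdayPattern Dosing protocol
#'   (defaults: 50 mL, 0.70, twice daily, Monday-Friday).
#' @param bodyWater \code{\link{bodyWaterParams}}.
#' @param lesionalTauRange Lesional transit lag window, days (default
#'   c(3, 8)).
#' @param uninvolvedTauRange Uninvolved transit lag window, days (default
#'   c(10, 20)).
#' @param lesionalK,uninvolvedK Replacement rates, per day (defaults 1.0
#'   and 0.15).
#' @param samplingDays Tape-strip days (default c(3, 6, 10, 13, 17, 21, 24,
#'   28), intersected with each subject's duration).
#' @param em1NoiseSD Relative SD of multiplicative Gaussian EM1 noise
#'   (default 0.05; negative draws clamp to 0).
#' @param tewlLesionalMean,tewlNonLesionalMean TEWL site means,
#'   g m^-2 h^-1 (defaults 25 and 8; chosen to enforce the lesional >
#'   non-lesional ordering, not to match any published value).
#' @param tewlReadingSD Relative SD of a single TEWL reading (default
#'   0.15).
#' @param spectralTotals Total spectral counts drawn for the uninvolved and
#'   psoriatic tables (defaults 349 and 856, the packaged table totals).
#' @param model,formula Labeling model and analyte formula used in the
#'   forward EM1 model.
#' @return A list of settings for \code{\link{simulateCohort}}.
#' @export
cohortConfig <- function(sitesPerGroup = 2L,
                         durationRange = c(16, 38),
                         doseVolume = 50, dosePurity = 0.70,
                         dosesPerDay = 2L, weekdayPattern = 1:5,
                         bodyWater = bodyWaterParams(),
                         lesionalTauRange = c(3, 8),
                         uninvolvedTauRange = c(10, 20),
                         lesionalK = 1.0, uninvolvedK = 0.15,
                         samplingDays = c(3, 6, 10, 13, 17, 21, 24, 28),
                         em1NoiseSD = 0.05,
                         tewlLesionalMean = 25, tewlNonLesionalMean = 8,
                         tewlReadingSD = 0.15,
                         spectralTotals = c(uninvolved = 349L,
                                            psoriatic = 856L),
                         model = defaultLabelingModel(formula),
                         formula = defaultAnalyteFormula()) {
  if (lesionalTauRange[1] >= uninvolvedTauRange[1] ||
      lesionalTauRange[2] >= uninvolvedTauRange[2])
    stop("invalid config: lesional tau window must precede uninvolved")
  if (lesionalK <= 0 || uninvolvedK <= 0)
    stop("invalid config: replacement rates must be > 0")
  if (1 - exp(-lesionalK * 5) <= 0.99)
    warning("lesionalK implies stratum corneum replacement slower than ",
            "5 days; lesional sites are meant to turn over in < 5 days")
  if (em1NoiseSD < 0 || tewlReadingSD < 0)
    stop("invalid config: noise SDs must be >= 0")
  if (diff(durationRange) < 0 || durationRange[1] < 1)
    stop("invalid config: bad duration range")
  as.list(environment())
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# multinomial resampling of a spectral-count profile
.sampleSpectralTable <- function(profile, total, condition) {
  counts <- as.vector(stats::rmultinom(1, total,
                                       profile$totalPeptideCount))
  keep <- counts > 0
  uniq <- pmax(1L, pmin(counts,
                        round(counts * profile$uniquePeptides /
                                profile$totalPeptideCount)))
  spectralCountTable(condition, data.frame(
    proteinName = profile$proteinName[keep],
    uniquePeptides = as.integer(uniq[keep]),
    totalPeptideCount = as.integer(counts[keep]),
    molWt = profile$molWt[keep]))
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-site truth (lesional transit lag ~ Uniform over
#' \code{lesionalTauRange}, uninvolved ~ Uniform over
#' \code{uninvolvedTauRange}, replacement rates from the config), simulates
#' each subject's body-water enrichment from the dosing protocol, computes
#' true fractional synthesis on the sampling days, maps it to EM1 via
#' EM1max(p-bar) x f, adds multiplicative Gaussian noise, and emits saliva
#' points on tape-strip days, TEWL duplicates with lesional > non-lesional
#' means, and spectral-count tables by multinomial resampling of the
#' packaged single-patient profiles.
#'
#' @param nSubjects Number of subjects (>= 1; default 4).
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param config \code{\link{cohortConfig}} settings.
#' @return A \code{\link{CohortBundle}}.
#' @examples
#' bundle <- simulateCohort(nSubjects = 2, seed = 7)
#' cohortTruth(bundle)
#' @export
simulateCohort <- function(nSubjects = 4L, seed, config = cohortConfig()) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (missing(seed)) stop("a seed is required")
  .withSeed(seed, {
    schedules <- list(); curves <- list()
    saliva <- list(); strips <- list(); tewl <- list(); truth <- list()
    for (i in seq_len(nSubjects)) {
      sid <- sprintf("S%02d", i)
      duration <- sample(seq(config$durationRange[1],
                             config$durationRange[2]), 1L)
      sched <- buildProtocolSchedule(
        durationDays = duration, doseVolume = config$doseVolume,
        purity = config$dosePurity, dosesPerDay = config$dosesPerDay,
        weekdayPattern = config$weekdayPattern)
      curve <- simulateBodyWater(sched, config$bodyWater)
      schedules[[sid]] <- sched
      curves[[sid]] <- curve
      days <- config$samplingDays[config$samplingDays <= duration]
      pBar <- vapply(days, function(d) timeAveragedEnrichment(curve, d),
                     numeric(1))
      em1max <- vapply(pBar, function(p)
        em1Max(p, config$model, config$formula), numeric(1))
      saliva[[sid]] <- data.frame(subject_id = sid, day = days,
                                  enrichment_fraction =
                                    enrichmentAt(curve, days))
      for (grp in c(TRUE, FALSE)) {
        for (j in seq_len(config$sitesPerGroup)) {
          siteId <- sprintf("%s_%s%d", sid,
                            if (grp) "les" else "uninv", j)
          tauRange <- if (grp) config$lesionalTauRange
            else config$uninvolvedTauRange
          tau <- stats::runif(1, tauRange[1], tauRange[2])
          k <- if (grp) config$lesionalK else config$uninvolvedK
          fTrue <- predictF(days, tau, k)
          em1 <- em1max * fTrue
          if (config$em1NoiseSD > 0)
            em1 <- pmax(0, em1 * (1 + stats::rnorm(length(em1), 0,
                                                   config$em1NoiseSD)))
          strips[[siteId]] <- data.frame(
            subject_id = sid, site_id = siteId, lesional = as.integer(grp),
            day = days, em1 = em1)
          tewlMean <- if (grp) config$tewlLesionalMean
            else config$tewlNonLesionalMean
          readings <- matrix(stats::rnorm(2 * length(days), tewlMean,
                                          config$tewlReadingSD * tewlMean),
                             ncol = 2)
          readings <- pmax(readings, 0.1 * tewlMean)
          tewl[[siteId]] <- data.frame(
            subject_id = sid, site_id = siteId, lesional = as.integer(grp),
            day = days, reading_1 = readings[, 1],
            reading_2 = readings[, 2])
          truth[[siteId]] <- data.frame(
            subject_id = sid, site_id = siteId, lesional = grp,
            tau = tau, k = k, em1NoiseSD = config$em1NoiseSD,
            durationDays = duration)
        }
      }
    }
    profiles <- list(
      uninvolved = scRecords(readSpectralCounts(
        system.file("extdata", "tapestrip_uninvolved_counts.tsv",
                    package = "epiTurnover"), "uninvolved")),
      psoriatic = scRecords(readSpectralCounts(
        system.file("extdata", "tapestrip_psoriatic_counts.tsv",
                    package = "epiTurnover"), "psoriatic")))
    spectral <- list(
      uninvolved = .sampleSpectralTable(profiles$uninvolved,
                                        config$spectralTotals[["uninvolved"]],
                                        "uninvolved"),
      psoriatic = .sampleSpectralTable(profiles$psoriatic,
                                       config$spectralTotals[["psoriatic"]],
                                       "psoriatic"))
    cfg <- config
    cfg$model <- NULL; cfg$formula <- NULL  # S4 objects; recorded via defaults
    new("CohortBundle", schedules = schedules, curves = curves,
        saliva = do.call(rbind, c(saliva, list(make.row.names = FALSE))),
        tapeStrips = do.call(rbind, c(strips, list(make.row.names = FALSE))),
        tewl = do.call(rbind, c(tewl, list(make.row.names = FALSE))),
        spectralCounts = spectral,
        truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
        seed = as.integer(seed), config = cfg)
  })
}

#' Generating-parameter report for a synthetic cohort
#'
#' Machine-readable truth for closed-loop recovery tests: one row per site
#' with the generating lag, replacement rate, noise SD and dosing duration.
#'
#' @param bundle A \code{\link{CohortBundle}}.
#' @return \code{data.frame} (zero rows for an empty bundle).
#' @export
truthReport <- function(bundle) {
  stopifnot(is(bundle, "CohortBundle"))
  bundle@truth
}
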