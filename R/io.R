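## Readers, writers and pipeline orchestration.  File dialects:
##   saliva.csv        subject_id, day, enrichment_fraction
##   dosing.csv        subject_id, day, volume_ml, purity
##   tape_strips.csv   subject_id, site_id, lesional (0/1), day, em1
##   tewl.csv          subject_id, site_id, lesional, day, reading_1,
##                     reading_2
##   spectral_counts_<condition>.tsv   protein_name, unique_peptides,
##                     total_peptide_count, mol_wt_da
##   truth.json        generating parameters (synthetic cohorts only)
## Every run emits a manifest recording the seed and a config hash so
## outputs are reproducible from (inputs, config, seed).

.requireColumns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read saliva enrichment measurements
#'
#' @param path CSV with columns \code{subject_id}, \code{day},
#'   \code{enrichment_fraction}.
#' @return \code{data.frame}.
#' @export
readSaliva <- function(path) {
  .requireColumns(utils::read.csv(path, stringsAsFactors = FALSE),
                  c("subject_id", "day", "enrichment_fraction"), path)
}

#' Read tape-strip EM1 measurements
#'
#' @param path CSV with columns \code{subject_id}, \code{site_id},
#'   \code{lesional} (0/1), \code{day}, \code{em1}.
#' @return \code{data.frame}.
#' @export
readTapeStrips <- function(path) {
  df <- .requireColumns(utils::read.csv(path, stringsAsFactors = FALSE),
                        c("subject_id", "site_id", "lesional", "day",
                          "em1"), path)
  bad <- which(!is.finite(df$day) | df$day < 0 | !is.finite(df$em1))
  if (length(bad))
    stop("malformed tape-strip row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  df
}

#' Read explicit dosing events
#'
#' @param path CSV with columns \code{subject_id}, \code{day},
#'   \code{volume_ml}, \code{purity}.
#' @return Named list of \code{\link{DosingSchedule}} objects, one per
#'   subject.
#' @export
readDosing <- function(path) {
  df <- .requireColumns(utils::read.csv(path, stringsAsFactors = FALSE),
                        c("subject_id", "day", "volume_ml", "purity"),
                        path)
  lapply(split(df, df$subject_id), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    new("DosingSchedule",
        events = data.frame(day = g$day, volumeML = g$volume_ml,
                            purity = g$purity))
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the exact CSV/TSV dialects the pipeline readers consume, plus the
#' generating truth (\code{truth.json}) and a run manifest.
#'
#' @param bundle A \code{\link{CohortBundle}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeCohort <- function(bundle, dir) {
  stopifnot(is(bundle, "CohortBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  wcsv(bundle@saliva, "saliva.csv")
  wcsv(bundle@tapeStrips, "tape_strips.csv")
  wcsv(bundle@tewl, "tewl.csv")
  dosing <- do.call(rbind, lapply(names(bundle@schedules), function(sid) {
    ev <- dosingEvents(bundle@schedules[[sid]])
    data.frame(subject_id = sid, day = ev$day, volume_ml = ev$volumeML,
               purity = ev$purity)
  }))
  wcsv(dosing, "dosing.csv")
  for (cond in names(bundle@spectralCounts)) {
    r <- scRecords(bundle@spectralCounts[[cond]])
    utils::write.table(
      data.frame(protein_name = r$proteinName,
                 unique_peptides = r$uniquePeptides,
                 total_peptide_count = r$totalPeptideCount,
                 mol_wt_da = r$molWt),
      file.path(dir, paste0("spectral_counts_", cond, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle@truth, file.path(dir, "truth.json"),
                       digits = NA)
  writeManifest(dir, seed = bundle@seed, config = bundle@config)
  invisible(dir)
}

#' Read a cohort directory back into tables
#'
#' @param dir Directory written by \code{\link{writeCohort}} (or assembled
#'   by hand in the same dialects).
#' @return List with components \code{saliva}, \code{tapeStrips},
#'   \code{tewl}, \code{schedules}, \code{spectralCounts} (named list of
#'   \code{\link{SpectralCountTable}}) and \code{truth} (\code{NULL} when
#'   absent).
#' @export
readCohort <- function(dir) {
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  p <- function(name) file.path(dir, name)
  if (!file.exists(p("tape_strips.csv")))
    stop("input directory lacks tape_strips.csv: ", dir)
  scFiles <- list.files(dir, "^spectral_counts_.*\\.tsv$")
  spectral <- list()
  for (f in scFiles) {
    cond <- sub("^spectral_counts_(.*)\\.tsv$", "\\1", f)
    spectral[[cond]] <- readSpectralCounts(p(f), cond)
  }
  list(
    saliva = if (file.exists(p("saliva.csv"))) readSaliva(p("saliva.csv")),
    tapeStrips = readTapeStrips(p("tape_strips.csv")),
    tewl = if (file.exists(p("tewl.csv"))) readTewl(p("tewl.csv")),
    schedules = if (file.exists(p("dosing.csv"))) readDosing(p("dosing.csv")),
    spectralCounts = spectral,
    truth = if (file.exists(p("truth.json")))
      jsonlite::fromJSON(p("truth.json")))
}

#' Write a run manifest
#'
#' Records the seed and an MD5 hash of the serialized configuration so any
#' output directory can be traced to (inputs, config, seed).
#'
#' @param dir Output directory.
#' @param seed Integer seed used for the run (\code{NA} for deterministic
#'   runs).
#' @param config Configuration list.
#' @return Invisibly, the manifest list.
#' @export
writeManifest <- function(dir, seed = NA_integer_, config = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  manifest <- list(package = "epiTurnover",
                   version = as.character(utils::packageVersion("epiTurnover")),
                   seed = seed,
                   configHash = unname(tools::md5sum(tmp)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

# per-subject enrichment curves: measured saliva takes precedence over
# dosing simulation (mirrors the study, which measured rather than modeled)
.cohortCurves <- function(inputs, bodyWater = bodyWaterParams()) {
  subjects <- unique(inputs$tapeStrips$subject_id)
  curves <- list()
  for (sid in subjects) {
    sal <- if (!is.null(inputs$saliva))
      inputs$saliva[inputs$saliva$subject_id == sid, , drop = FALSE]
    if (!is.null(sal) && nrow(sal) >= 2L) {
      curves[[sid]] <- interpolateMeasured(
        data.frame(day = sal$day, enrichment = sal$enrichment_fraction))
    } else if (!is.null(inputs$schedules) &&
               sid %in% names(inputs$schedules)) {
      curves[[sid]] <- simulateBodyWater(inputs$schedules[[sid]],
                                         bodyWater)
    } else {
      stop("subject ", sid, " has neither >= 2 saliva points nor a dosing ",
           "schedule; cannot build an enrichment curve")
    }
  }
  curves
}

#' Analyze a cohort end to end
#'
#' Runs the full pipeline on a cohort: builds each subject's body-water
#' enrichment curve (measured saliva takes precedence over dosing
#' simulation; a \code{\link{CohortBundle}}'s attached simulated curves are
#' used directly), converts each site's EM1 series to fractional synthesis,
#' fits the conveyor-belt model per site, and summarizes lesional vs
#' uninvolved kinetics, spectral counts and TEWL.
#'
#' @param x A \code{\link{CohortBundle}} or a directory path in the
#'   \code{\link{writeCohort}} layout.
#' @param config \code{\link{fitConfig}} for the kinetic fits.
#' @param model,formula Labeling model and analyte formula.
#' @param outputDir Optional directory; when given, per-site fits
#'   (\code{fits.csv}), the cohort summary (\code{summary.json}) and a
#'   manifest are written there.
#' @param minPoints Sites with fewer usable points are skipped with a
#'   warning (default 3).
#' @return List with components \code{fits} (named list of
#'   \code{\link{ConveyorFit}}), \code{fitTable} (\code{data.frame}),
#'   \code{comparison} (\code{\link{compareSites}} output or \code{NULL}),
#'   \code{appearance} (\code{data.frame} of threshold appearance times),
#'   \code{proteomics} (per-condition \code{\link{keratinFraction}}
#'   summaries) and \code{tewl} (\code{\link{lesionalContrast}} output or
#'   \code{NULL}).
#' @export
analyzeCohort <- function(x, config = fitConfig(),
                          model = defaultLabelingModel(formula),
                          formula = defaultAnalyteFormula(),
                          outputDir = NULL, minPoints = 3L) {
  if (is(x, "CohortBundle")) {
    inputs <- list(saliva = x@saliva, tapeStrips = x@tapeStrips,
                   tewl = x@tewl, schedules = x@schedules,
                   spectralCounts = x@spectralCounts, truth = x@truth)
    curves <- x@curves
  } else {
    inputs <- readCohort(x)
    curves <- .cohortCurves(inputs)
  }
  ts <- inputs$tapeStrips
  if (is.null(ts) || nrow(ts) == 0L)
    stop("no tape-strip measurements to analyze")
  fits <- list(); appearance <- list()
  for (siteId in unique(ts$site_id)) {
    sub <- ts[ts$site_id == siteId, , drop = FALSE]
    sid <- sub$subject_id[1]
    series <- tapeStripSeries(sid, siteId, sub$lesional[1] != 0,
                              sub$day, sub$em1, curves[[sid]])
    pts <- suppressWarnings(seriesToF(series, model, formula))
    if (nrow(pts) < minPoints) {
      warning("site ", siteId, " has fewer than ", minPoints,
              " usable points; skipped")
      next
    }
    fits[[siteId]] <- fitConveyor(pts, config, subjectId = sid,
                                  siteId = siteId,
                                  lesional = sub$lesional[1] != 0)
    at <- appearanceTime(pts)
    appearance[[siteId]] <- data.frame(
      subject_id = sid, site_id = siteId,
      lesional = sub$lesional[1] != 0,
      appearanceDay = as.numeric(at),
      censored = is.na(at))
  }
  fitTable <- do.call(rbind, lapply(fits, function(f) data.frame(
    subject_id = f@subjectId, site_id = f@siteId, lesional = f@lesional,
    tau = f@tau, tauLo = f@tauCI[1], tauHi = f@tauCI[2], k = f@k,
    kLo = f@kCI[1], kHi = f@kCI[2], rss = f@rss, nPoints = f@nPoints,
    flags = paste(f@flags, collapse = ";"))))
  rownames(fitTable) <- NULL
  appearance <- do.call(rbind, c(appearance,
                                 list(make.row.names = FALSE)))
  comparison <- if (length(unique(fitTable$lesional)) == 2L)
    compareSites(fits) else NULL
  proteomics <- lapply(inputs$spectralCounts, function(tab)
    suppressWarnings(keratinFraction(
      tab, subset = skinCondition(tab) == "psoriatic")))
  tewlOut <- if (!is.null(inputs$tewl) && nrow(inputs$tewl))
    suppressWarnings(lesionalContrast(inputs$tewl)) else NULL
  result <- list(fits = fits, fitTable = fitTable,
                 comparison = comparison, appearance = appearance,
                 proteomics = proteomics, tewl = tewlOut)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fitTable, file.path(outputDir, "fits.csv"),
                     row.names = FALSE)
    summary <- list(
      nSites = nrow(fitTable),
      groups = if (!is.null(comparison)) comparison$groups,
      proteomics = lapply(names(proteomics), function(cond)
        list(condition = cond,
             keratin_percent = proteomics[[cond]]$percentRounded,
             n_proteins = proteomics[[cond]]$nProteins)),
      tewlSignCount = if (!is.null(tewlOut)) as.list(tewlOut$signCount))
    jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeManifest(outputDir, seed = if (!is.null(config$seed))
      config$seed else NA_integer_,
      config = config[setdiff(names(config), "tauGrid")])
  }
  result
}
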