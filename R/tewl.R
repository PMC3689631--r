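## Transepidermal water loss (TEWL): duplicate-reading summaries and
## descriptive lesional vs non-lesional contrasts.  No hypothesis test is
## computed; TEWL is reported descriptively (means, SDs, paired differences
## and day-to-day CV).

#' Summarize duplicate TEWL readings
#'
#' Arithmetic mean and sample standard deviation of the evaporimeter
#' readings taken at one site on one day (typically duplicates).  A single
#' reading yields SD 0 with a flag.
#'
#' @param readings Numeric vector of evaporimeter values
#'   (g m^-2 h^-1), all > 0.
#' @return List with components \code{mean}, \code{sd}, \code{n} and
#'   \code{singleReading} (logical flag).
#' @examples
#' summarizeTewl(c(10, 14))   # mean 12, sd ~2.83
#' @export
summarizeTewl <- function(readings) {
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0L)
    stop("invalid input: at least one TEWL reading is required")
  if (any(readings <= 0))
    stop("TEWL readings must be > 0")
  n <- length(readings)
  list(mean = mean(readings),
       sd = if (n > 1L) stats::sd(readings) else 0,
       n = n, singleReading = n == 1L)
}

#' Read a TEWL table from CSV
#'
#' Expects columns \code{subject_id}, \code{site_id}, \code{lesional}
#' (0/1), \code{day}, \code{reading_1} and optionally \code{reading_2}.
#'
#' @param path Path to the CSV file.
#' @return \code{data.frame} in the same layout.
#' @export
readTewl <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "site_id", "lesional", "day", "reading_1")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("TEWL file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!"reading_2" %in% names(df)) df$reading_2 <- NA_real_
  df
}

# long per-site-day summaries from the wide reading_1/reading_2 layout
.tewlSummaries <- function(records) {
  do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    s <- summarizeTewl(unlist(records[i, c("reading_1", "reading_2")]))
    data.frame(subject_id = records$subject_id[i],
               site_id = records$site_id[i],
               lesional = as.logical(records$lesional[i]),
               day = records$day[i], mean = s$mean, sd = s$sd,
               singleReading = s$singleReading)
  }))
}

#' Lesional vs non-lesional TEWL contrast
#'
#' Per-subject paired comparison of lesional and non-lesional TEWL: for each
#' subject, site-day readings are summarized, averaged within group on days
#' both groups were measured (exact day match by default; nearest-day
#' matching within \code{dayTolerance} by config), and the difference of
#' group means across those shared days is reported, together with the
#' cohort sign count and the day-to-day coefficient of variation per site
#' (the noise that limits TEWL's longitudinal use).  Subjects lacking a
#' measured day in either group are excluded with a warning.
#'
#' @param records TEWL \code{data.frame} as read by \code{\link{readTewl}}.
#' @param dayTolerance Maximum |day difference| for pairing lesional and
#'   non-lesional days (default 0: exact match).
#' @return List with components \code{perSubject} (\code{data.frame}:
#'   \code{subject_id}, \code{lesionalMean}, \code{nonLesionalMean},
#'   \code{difference}, \code{nSharedDays}), \code{signCount} (subjects with
#'   positive difference / subjects compared) and \code{siteCV}
#'   (\code{data.frame} of day-to-day CV of the site mean per site).
#' @export
lesionalContrast <- function(records, dayTolerance = 0) {
  s <- .tewlSummaries(records)
  perSubject <- list(); dropped <- character(0)
  for (sid in unique(s$subject_id)) {
    sub <- s[s$subject_id == sid, , drop = FALSE]
    les <- sub[sub$lesional, , drop = FALSE]
    non <- sub[!sub$lesional, , drop = FALSE]
    if (nrow(les) == 0L || nrow(non) == 0L) {
      dropped <- c(dropped, sid); next
    }
    lesDays <- unique(les$day)
    shared <- lesDays[vapply(lesDays, function(d)
      any(abs(non$day - d) <= dayTolerance), logical(1))]
    if (length(shared) == 0L) { dropped <- c(dropped, sid); next }
    lesMean <- mean(les$mean[les$day %in% shared])
    nonIdx <- vapply(shared, function(d)
      which.min(abs(non$day - d)), integer(1))
    nonDays <- unique(non$day[nonIdx])
    nonMean <- mean(non$mean[non$day %in% nonDays])
    perSubject[[sid]] <- data.frame(
      subject_id = sid, lesionalMean = lesMean, nonLesionalMean = nonMean,
      difference = lesMean - nonMean, nSharedDays = length(shared))
  }
  if (length(dropped))
    warning("subject(s) without paired lesional/non-lesional days ",
            "excluded: ", paste(dropped, collapse = ", "))
  perSubject <- if (length(perSubject)) do.call(rbind, perSubject)
    else data.frame(subject_id = character(0), lesionalMean = numeric(0),
                    nonLesionalMean = numeric(0), difference = numeric(0),
                    nSharedDays = integer(0))
  rownames(perSubject) <- NULL
  siteCV <- do.call(rbind, lapply(
    split(s, interaction(s$subject_id, s$site_id, drop = TRUE)),
    function(g) data.frame(subject_id = g$subject_id[1],
                           site_id = g$site_id[1],
                           lesional = g$lesional[1], nDays = nrow(g),
                           cv = if (nrow(g) > 1 && mean(g$mean) > 0)
                             stats::sd(g$mean) / mean(g$mean) else NA_real_)))
  rownames(siteCV) <- NULL
  list(perSubject = perSubject,
       signCount = c(positive = sum(perSubject$difference > 0),
                     total = nrow(perSubject)),
       siteCV = siteCV)
}
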