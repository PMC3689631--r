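## Spectral-count proteomics summaries: molecular-weight-normalized
## abundance index, abundance ranking, and the keratin-derived fraction of
## all spectral counts.

#' Molecular-weight-normalized abundance index
#'
#' Crude relative-abundance measure for spectral counting: the total peptide
#' count (number of MS/MS spectra matched to a protein's peptides) divided
#' by the protein's molecular weight, times 10^3.  Reported raw and rounded
#' to 2 decimals, the convention of published count/MW tables.
#'
#' @param totalPeptideCount Total spectral count (>= 1).
#' @param molWt Molecular weight in Da (> 0).
#' @return List with components \code{raw} and \code{rounded}.
#' @examples
#' abundanceIndex(91, 58827)$rounded   # 1.55 (Keratin 10, uninvolved skin)
#' @export
abundanceIndex <- function(totalPeptideCount, molWt) {
  if (any(molWt <= 0)) stop("molecular weight must be > 0")
  raw <- totalPeptideCount / molWt * 1e3
  list(raw = raw, rounded = round(raw, 2))
}

#' Rank a spectral-count table by abundance
#'
#' Orders records by descending abundance index
#' (\code{\link{abundanceIndex}}); ties are broken by descending total
#' peptide count, then alphabetically by protein name.  The returned table
#' gains an \code{abundanceIndex} column (rounded to 2 decimals).
#'
#' @param table A \code{\link{SpectralCountTable}}.
#' @return The same \code{SpectralCountTable} with reordered records and an
#'   \code{abundanceIndex} column.
#' @export
rankByAbundance <- function(table) {
  stopifnot(is(table, "SpectralCountTable"))
  validObject(table)
  r <- table@records
  if (nrow(r) == 0L)
    stop("insufficient data: empty spectral-count table")
  idx <- abundanceIndex(r$totalPeptideCount, r$molWt)
  r$abundanceIndex <- idx$rounded
  ord <- order(-idx$raw, -r$totalPeptideCount, r$proteinName)
  r <- r[ord, , drop = FALSE]
  rownames(r) <- NULL
  new("SpectralCountTable", condition = table@condition, records = r)
}

#' Default keratin classifier
#'
#' Classifies a protein as keratin when its name begins with "Keratin"
#' (case-insensitive), optionally extended by an override list of exact
#' names.
#'
#' @param overrides Character vector of additional protein names to count
#'   as keratin.
#' @return A function mapping a character vector of protein names to a
#'   logical vector.
#' @export
keratinClassifier <- function(overrides = character(0)) {
  force(overrides)
  function(proteinName)
    grepl("^keratin", proteinName, ignore.case = TRUE) |
      proteinName %in% overrides
}

#' Keratin-derived fraction of spectral counts
#'
#' Percentage of all spectral counts in a table that derive from keratins:
#' \code{100 * sum(counts over keratin records) / sum(counts over all
#' records)}.  When the table is a prominent-protein subset rather than a
#' complete inventory (e.g. only the most abundant proteins were listed),
#' set \code{subset = TRUE} to attach a warning that the fraction describes
#' the listed subset only.
#'
#' @param table A \code{\link{SpectralCountTable}}.
#' @param classifier Function from protein names to logical
#'   (default \code{\link{keratinClassifier}()}).
#' @param subset Logical; is the table a known subset of detected proteins?
#' @return List with components \code{percent} (raw), \code{percentRounded}
#'   (whole percent), \code{keratinCounts}, \code{totalCounts} and
#'   \code{nProteins}.
#' @examples
#' tab <- readSpectralCounts(system.file("extdata",
#'   "tapestrip_uninvolved_counts.tsv", package = "epiTurnover"), "uninvolved")
#' keratinFraction(tab)$percentRounded   # 98
#' @export
keratinFraction <- function(table, classifier = keratinClassifier(),
                            subset = FALSE) {
  stopifnot(is(table, "SpectralCountTable"))
  validObject(table)
  r <- table@records
  if (nrow(r) == 0L)
    stop("insufficient data: empty spectral-count table")
  total <- sum(r$totalPeptideCount)
  if (total <= 0)
    stop("degenerate input: zero total spectral counts")
  isKer <- classifier(r$proteinName)
  pct <- 100 * sum(r$totalPeptideCount[isKer]) / total
  if (subset)
    warning("table is a prominent-protein subset; the keratin fraction ",
            "describes the listed records only, not the full proteome")
  list(percent = pct, percentRounded = round(pct),
       keratinCounts = sum(r$totalPeptideCount[isKer]),
       totalCounts = total, nProteins = nrow(r))
}

#' Read a spectral-count table from TSV
#'
#' Expects tab-separated columns \code{protein_name},
#' \code{unique_peptides}, \code{total_peptide_count}, \code{mol_wt_da}.
#' The published single-patient tables ship with the package as
#' \code{extdata/tapestrip_uninvolved_counts.tsv} and
#' \code{extdata/tapestrip_psoriatic_counts.tsv}.
#'
#' @param path Path to the TSV file.
#' @param condition Condition label for the table.
#' @return A \code{\link{SpectralCountTable}}.
#' @export
readSpectralCounts <- function(path, condition) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_name", "unique_peptides", "total_peptide_count",
            "mol_wt_da")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("spectral-count file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$total_peptide_count) |
                 !is.finite(df$mol_wt_da) | df$mol_wt_da <= 0 |
                 df$unique_peptides < 1 |
                 df$total_peptide_count < df$unique_peptides)
  if (length(bad))
    stop("malformed spectral-count row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  if (anyDuplicated(df$protein_name))
    stop("duplicate protein name(s) in ", path, ": ",
         paste(unique(df$protein_name[duplicated(df$protein_name)]),
               collapse = ", "))
  spectralCountTable(condition,
                     data.frame(proteinName = df$protein_name,
                                uniquePeptides = df$unique_peptides,
                                totalPeptideCount = df$total_peptide_count,
                                molWt = df$mol_wt_da))
}

#' Write a ranked spectral-count table and summary
#'
#' Writes the ranked table as TSV and a JSON summary \code{{condition,
#' keratin_percent, n_proteins}} alongside it.
#'
#' @param table A \code{\link{SpectralCountTable}}.
#' @param path Output TSV path; the JSON summary goes to the same path with
#'   extension \code{.json}.
#' @param subset Passed to \code{\link{keratinFraction}}.
#' @return Invisibly, the summary list.
#' @export
writeSpectralSummary <- function(table, path, subset = FALSE) {
  ranked <- rankByAbundance(table)
  r <- ranked@records
  out <- data.frame(protein_name = r$proteinName,
                    unique_peptides = r$uniquePeptides,
                    total_peptide_count = r$totalPeptideCount,
                    mol_wt_da = r$molWt,
                    abundance_index = r$abundanceIndex)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kf <- suppressWarnings(keratinFraction(table, subset = subset))
  summary <- list(condition = skinCondition(table),
                  keratin_percent = kf$percentRounded,
                  n_proteins = kf$nProteins)
  jsonlite::write_json(summary, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE)
  invisible(summary)
}
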