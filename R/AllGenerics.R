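#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{fractions} and \code{truncationOrder} on an
#' \code{\link{IsotopomerDistribution}}; \code{lagDays},
#' \code{replacementRate} and \code{fitFlags} on a \code{\link{ConveyorFit}};
#' \code{isLesional} on site-level objects; \code{measurements} on a
#' \code{\link{TapeStripSeries}}; \code{scRecords} and \code{skinCondition}
#' on a \code{\link{SpectralCountTable}}; \code{cohortTruth} on a
#' \code{\link{CohortBundle}}.
#'
#' @param x Object to access.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setMethod("fractions", "IsotopomerDistribution", function(x) x@fractions)

#' @rdname accessors
#' @export
setGeneric("truncationOrder", function(x) standardGeneric("truncationOrder"))
#' @rdname accessors
#' @export
setMethod("truncationOrder", "IsotopomerDistribution",
          function(x) x@truncationOrder)

#' @rdname accessors
#' @export
setGeneric("lagDays", function(x) standardGeneric("lagDays"))
#' @rdname accessors
#' @export
setMethod("lagDays", "ConveyorFit", function(x) x@tau)

#' @rdname accessors
#' @export
setGeneric("replacementRate", function(x) standardGeneric("replacementRate"))
#' @rdname accessors
#' @export
setMethod("replacementRate", "ConveyorFit", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))
#' @rdname accessors
#' @export
setMethod("fitFlags", "ConveyorFit", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("isLesional", function(x) standardGeneric("isLesional"))
#' @rdname accessors
#' @export
setMethod("isLesional", "TapeStripSeries", function(x) x@lesional)
#' @rdname accessors
#' @export
setMethod("isLesional", "ConveyorFit", function(x) x@lesional)

#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setMethod("measurements", "TapeStripSeries", function(x) x@measurements)

#' @rdname accessors
#' @export
setGeneric("scRecords", function(x) standardGeneric("scRecords"))
#' @rdname accessors
#' @export
setMethod("scRecords", "SpectralCountTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("skinCondition", function(x) standardGeneric("skinCondition"))
#' @rdname accessors
#' @export
setMethod("skinCondition", "SpectralCountTable", function(x) x@condition)

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setMethod("cohortTruth", "CohortBundle", function(x) x@truth)
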