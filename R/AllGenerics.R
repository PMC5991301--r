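#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the container classes of the package:
#' `records()` returns the long-format sample table of a
#' [CommunityDataset-class]; `taxa()`, `habitats()` and `surveyMonths()`
#' return its ordered label sets; `interactionValues()`, `rowTotals()`,
#' `colTotals()`, `grandTotal()` and `valueMode()` expose the weighted
#' matrix and margins of an [InteractionMatrix-class]; `nullDraws()` and
#' `pValue()` expose the randomization context of a [NullEnsemble-class].
#'
#' @param x an object of the appropriate class.
#' @return The slot content documented for each class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("habitats", function(x) standardGeneric("habitats"))

#' @rdname accessors
#' @export
setGeneric("surveyMonths", function(x) standardGeneric("surveyMonths"))

#' @rdname accessors
#' @export
setGeneric("interactionValues", function(x) standardGeneric("interactionValues"))

#' @rdname accessors
#' @export
setGeneric("rowTotals", function(x) standardGeneric("rowTotals"))

#' @rdname accessors
#' @export
setGeneric("colTotals", function(x) standardGeneric("colTotals"))

#' @rdname accessors
#' @export
setGeneric("grandTotal", function(x) standardGeneric("grandTotal"))

#' @rdname accessors
#' @export
setGeneric("valueMode", function(x) standardGeneric("valueMode"))

#' @rdname accessors
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("specializationIndex", function(x) standardGeneric("specializationIndex"))
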