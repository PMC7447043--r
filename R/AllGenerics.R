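#' @rdname SyntheticCohort-class
#' @param x a `SyntheticCohort`
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("labs", function(x) standardGeneric("labs"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("meds", function(x) standardGeneric("meds"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("participants", "SyntheticCohort", function(x) x@participants)

#' @rdname SyntheticCohort-class
#' @export
setMethod("labs", "SyntheticCohort", function(x) x@labs)

#' @rdname SyntheticCohort-class
#' @export
setMethod("codes", "SyntheticCohort", function(x) x@codes)

#' @rdname SyntheticCohort-class
#' @export
setMethod("meds", "SyntheticCohort", function(x) x@meds)

#' @rdname SyntheticCohort-class
#' @export
setMethod("genotypes", "SyntheticCohort", function(x) x@genotypes)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
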