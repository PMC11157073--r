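#' Accessors for mrscreen classes
#'
#' Small accessor generics for the package's S4 containers. Slot access by
#' \code{@} is discouraged outside the package.
#'
#' @param x an mrscreen object.
#' @name mrscreen-accessors
NULL

#' @rdname mrscreen-accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("thetaHat", function(x) standardGeneric("thetaHat"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("mrExtra", function(x) standardGeneric("mrExtra"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("indirectEffect", function(x) standardGeneric("indirectEffect"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("proportionMediated",
           function(x) standardGeneric("proportionMediated"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("gatePassed", function(x) standardGeneric("gatePassed"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("sensitivityTable", function(x) standardGeneric("sensitivityTable"))
#' @rdname mrscreen-accessors
#' @export
setGeneric("looTable", function(x) standardGeneric("looTable"))
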