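#' @title Generics for trichrom data containers
#' @description Accessor generics for the S4 containers used throughout the
#'   package. See the class pages for the semantics of each accessor.
#' @param x a trichrom S4 object.
#' @param ... passed to methods.
#' @name trichrom-generics
NULL

#' @rdname trichrom-generics
#' @export
setGeneric("fragments", function(x, ...) standardGeneric("fragments"))

#' @rdname trichrom-generics
#' @export
setGeneric("cutSites", function(x, ...) standardGeneric("cutSites"))

#' @rdname trichrom-generics
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname trichrom-generics
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname trichrom-generics
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))

#' @rdname trichrom-generics
#' @export
setGeneric("contactMetadata", function(x) standardGeneric("contactMetadata"))

#' @rdname trichrom-generics
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' @rdname trichrom-generics
#' @export
setGeneric("viewpoint", function(x) standardGeneric("viewpoint"))

#' @rdname trichrom-generics
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))

#' @rdname trichrom-generics
#' @export
setGeneric("matrixEntries", function(x) standardGeneric("matrixEntries"))

#' @rdname trichrom-generics
#' @export
setGeneric("matrixResolution", function(x) standardGeneric("matrixResolution"))

#' @rdname trichrom-generics
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname trichrom-generics
#' @export
setGeneric("matrixTotal", function(x) standardGeneric("matrixTotal"))
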