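#' @rdname ItemBank-class
#' @param object,x an object.
#' @export
setGeneric("bankName", function(x) standardGeneric("bankName"))

#' @rdname ItemBank-class
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname ItemBank-class
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname ItemBank-class
#' @export
setGeneric("itemParameters", function(x) standardGeneric("itemParameters"))

#' @rdname ItemBank-class
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("trueThetas", function(x) standardGeneric("trueThetas"))

#' @rdname PersonEstimate-class
#' @export
setGeneric("thetaEst", function(x) standardGeneric("thetaEst"))

#' @rdname PersonEstimate-class
#' @export
setGeneric("semEst", function(x) standardGeneric("semEst"))

#' @rdname CatSession-class
#' @export
setGeneric("administered", function(x) standardGeneric("administered"))

#' @rdname CatSession-class
#' @export
setGeneric("thetaTrace", function(x) standardGeneric("thetaTrace"))

#' @rdname CatSession-class
#' @export
setGeneric("semTrace", function(x) standardGeneric("semTrace"))

#' @rdname CatSession-class
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @rdname CatSession-class
#' @export
setGeneric("finalEstimate", function(x) standardGeneric("finalEstimate"))
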