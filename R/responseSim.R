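# Seeded simulation of person measures and complete response matrices: the
# study's synthetic data. Persons are drawn from N(0, 1); each response cell
# is drawn by inverse CDF from the item's category probabilities at that
# person's true theta. The uniform draws are consumed persons-major (person 1
# items 1..k, then person 2, ...), so matrices are bit-reproducible per seed.

#' Draw true person measures from the standard-normal population
#'
#' @param n number of persons (>= 1).
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG stream is left untouched.
#' @return numeric vector of length `n`.
#' @examples
#' identical(sampleThetas(5, seed = 1), sampleThetas(5, seed = 1))
#' @export
sampleThetas <- function(n, seed = NULL) {
  if (!.isCount(n)) stop("n must be a positive integer")
  .withSeed(seed, stats::rnorm(n))
}

#' Simulate a complete response matrix from an item bank
#'
#' Generates integer category responses for every person x item cell from the
#' model probabilities [categoryProbs()] at the person's true measure, by
#' inverse CDF on a single uniform draw per cell.
#'
#' @param thetas numeric vector of true person measures.
#' @param bank an [ItemBank-class].
#' @param seed optional integer seed (see [sampleThetas()]).
#' @return a [ResponseMatrix-class] with `trueThetas` retained and no missing
#'   cells.
#' @examples
#' rm <- simulateMatrix(sampleThetas(10, seed = 1), fixtureBank("CADL"), seed = 2)
#' dim(responses(rm))
#' @export
simulateMatrix <- function(thetas, bank, seed = NULL) {
  stopifnot(is(bank, "ItemBank"))
  thetas <- as.numeric(thetas)
  if (length(thetas) == 0L || any(!is.finite(thetas)))
    stop("thetas must be a nonempty vector of finite numbers")
  n <- length(thetas)
  comp <- .compileBank(bank)
  k <- length(comp)
  u <- .withSeed(seed, matrix(stats::runif(n * k), nrow = n, byrow = TRUE))
  resp <- matrix(0L, n, k, dimnames = list(NULL, itemIds(bank)))
  for (i in seq_len(k)) {
    ci <- comp[[i]]
    z <- ci$a * (outer(thetas, ci$x) - matrix(ci$s, n, ci$m + 1L, byrow = TRUE))
    z <- z - apply(z, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    cum <- t(apply(p, 1L, cumsum))
    # response = number of category boundaries below the uniform draw
    resp[, i] <- as.integer(rowSums(u[, i] > cum[, seq_len(ci$m), drop = FALSE]))
  }
  new("ResponseMatrix", bankName = bankName(bank), responses = resp,
      trueThetas = thetas)
}

#' @rdname ResponseMatrix-class
#' @param x a `ResponseMatrix`.
#' @export
setMethod("responses", "ResponseMatrix", function(x) x@responses)

#' @rdname ResponseMatrix-class
#' @export
setMethod("trueThetas", "ResponseMatrix", function(x) x@trueThetas)

#' @rdname ResponseMatrix-class
#' @export
setMethod("bankName", "ResponseMatrix", function(x) x@bankName)

setMethod("show", "ResponseMatrix", function(object) {
  r <- object@responses
  cat(sprintf("ResponseMatrix \"%s\": %d persons x %d items (%d missing)%s\n",
              object@bankName, nrow(r), ncol(r), sum(is.na(r)),
              if (length(object@trueThetas)) ", true thetas known" else ""))
  invisible(object)
})

setMethod("dim", "ResponseMatrix", function(x) dim(x@responses))

#' Read and write response matrices as delimited text
#'
#' External format: a CSV whose header is the item ids (plus an optional
#' leading `true_theta` column); one row per person; `-1` marks an
#' unadministered (missing) cell, which becomes `NA` in memory.
#'
#' @param path file to read/write.
#' @param bankName scale name to attach on read.
#' @return `readResponseMatrix()` a [ResponseMatrix-class];
#'   `writeResponseMatrix()` the path, invisibly.
#' @export
readResponseMatrix <- function(path, bankName = "user") {
  if (!file.exists(path)) stop("response-matrix file does not exist: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (nrow(d) == 0L || ncol(d) == 0L) stop("response-matrix file is empty")
  tt <- numeric(0)
  if (names(d)[1L] == "true_theta") {
    tt <- as.numeric(d[[1L]])
    d <- d[, -1L, drop = FALSE]
  }
  m <- as.matrix(d)
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m[m == -1L] <- NA_integer_
  new("ResponseMatrix", bankName = bankName, responses = m, trueThetas = tt)
}

#' @rdname readResponseMatrix
#' @param rm a [ResponseMatrix-class].
#' @export
writeResponseMatrix <- function(rm, path) {
  stopifnot(is(rm, "ResponseMatrix"))
  m <- rm@responses
  m[is.na(m)] <- -1L
  d <- as.data.frame(m, check.names = FALSE)
  if (length(rm@trueThetas))
    d <- cbind(true_theta = rm@trueThetas, d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
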