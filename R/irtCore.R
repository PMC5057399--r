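# Numerical kernels for the two model families.
#
# GPCM:  P(X = x | theta) = exp(a*(x*theta - s_x)) / sum_c exp(a*(c*theta - s_c)),
# where s_x = sum of the first x step difficulties (s_0 = 0, the empty sum).
# The dichotomous Rasch model is the a = 1, m = 1 special case
# P(1) = exp(theta - delta) / (1 + exp(theta - delta)).
# All accumulation is done in log space with max-subtraction so that user
# banks with extreme parameters (the CADL deltas reach -8.41) stay finite.

# internal: log category probabilities for one compiled item
.logProbs <- function(theta, ci) {
  z <- ci$a * (ci$x * theta - ci$s)
  z - .logSumExp(z)
}

.logSumExp <- function(z) {
  m <- max(z)
  m + log(sum(exp(z - m)))
}

.probs <- function(theta, ci) exp(.logProbs(theta, ci))

# internal: expected score and score variance of one compiled item
.scoreMoments <- function(theta, ci) {
  p <- .probs(theta, ci)
  e <- sum(ci$x * p)
  list(p = p, e = e, w = sum(ci$x^2 * p) - e^2)
}

.info <- function(theta, ci) {
  mo <- .scoreMoments(theta, ci)
  ci$a^2 * mo$w
}

.asCompiledItem <- function(item, bank = NULL) {
  if (is.list(item) && !is.null(item$s)) return(item)
  stop("internal: expected a compiled item")
}

# pick one row of an ItemBank as a compiled item
.bankItem <- function(bank, i) .compileBank(bank)[[i]]

#' Category response probabilities
#'
#' Probability of each score category `0..m` under the item's model at person
#' measure `theta`. For a dichotomous Rasch item this is the logistic
#' \eqn{P(1) = e^{\theta-\delta} / (1 + e^{\theta-\delta})}; for a GPCM item
#' the partial-credit form
#' \eqn{P(x) \propto \exp\{\sum_{v \le x} a(\theta - b_v)\}} with the empty
#' sum equal to 0. Evaluated in log space.
#'
#' @param theta person measure on the logit scale (finite).
#' @param bank an [ItemBank-class].
#' @param item item index or item id within `bank`.
#' @return numeric vector of length `m + 1` summing to 1.
#' @examples
#' b <- fixtureBank("CADL")
#' categoryProbs(0.55, b, "BI 2: bathing")  # theta at delta: c(0.5, 0.5)
#' @export
categoryProbs <- function(theta, bank, item) {
  ci <- .resolveItem(bank, item)
  if (length(theta) != 1L || !is.finite(theta))
    stop("theta must be a single finite number")
  p <- .probs(theta, ci)
  names(p) <- as.character(ci$x)
  p
}

#' Fisher item information
#'
#' \eqn{I(\theta) = a^2 \{\sum_x x^2 P_x - (\sum_x x P_x)^2\}}, i.e. the
#' discrimination-scaled score variance; for a dichotomous Rasch item this
#' reduces to \eqn{P(1-P)}. This is the "maximal variance" currency used for
#' adaptive item selection and the SEM.
#'
#' @inheritParams categoryProbs
#' @return nonnegative scalar.
#' @export
itemInformation <- function(theta, bank, item) {
  ci <- .resolveItem(bank, item)
  if (length(theta) != 1L || !is.finite(theta))
    stop("theta must be a single finite number")
  .info(theta, ci)
}

#' Response-pattern log-likelihood
#'
#' Sum of log category probabilities over the answered items; the objective
#' maximized by the MLE person estimator and, with a standard-normal log-prior
#' added, by MAP.
#'
#' @inheritParams categoryProbs
#' @param items item indices or ids within `bank`.
#' @param x observed integer categories aligned with `items` (each in
#'   `0..m_i`).
#' @return a single finite number (0 for an empty pattern).
#' @export
logLikelihood <- function(theta, bank, items, x) {
  if (length(theta) != 1L || !is.finite(theta))
    stop("theta must be a single finite number")
  if (length(items) != length(x))
    stop("items and x must have equal length")
  if (length(items) == 0L) return(0)
  comp <- .resolveItems(bank, items)
  .patternLogLik(theta, comp, as.integer(x))
}

.patternLogLik <- function(theta, comp, x) {
  ll <- 0
  for (j in seq_along(comp)) {
    ci <- comp[[j]]
    if (x[j] < 0L || x[j] > ci$m)
      stop(sprintf("response %d out of range 0..%d for item \"%s\"",
                   x[j], ci$m, ci$id))
    ll <- ll + .logProbs(theta, ci)[x[j] + 1L]
  }
  ll
}

# gradient and curvature of the pattern log-likelihood:
# d logP(x)/d theta = a*(x - E), d2 = -a^2 * W
.patternScore <- function(theta, comp, x) {
  g <- 0; i <- 0
  for (j in seq_along(comp)) {
    ci <- comp[[j]]
    mo <- .scoreMoments(theta, ci)
    g <- g + ci$a * (x[j] - mo$e)
    i <- i + ci$a^2 * mo$w
  }
  list(grad = g, info = i)
}

.patternInfo <- function(theta, comp) {
  s <- 0
  for (ci in comp) s <- s + .info(theta, ci)
  s
}

.resolveItem <- function(bank, item) {
  if (is.list(item) && !is.null(item$s)) return(item)
  stopifnot(is(bank, "ItemBank"))
  if (is.character(item)) {
    i <- match(item, bank@items$item_id)
    if (is.na(i)) stop("unknown item id: ", item)
  } else i <- as.integer(item)
  if (i < 1L || i > nrow(bank@items)) stop("item index out of range")
  .bankItem(bank, i)
}

.resolveItems <- function(bank, items) {
  comp <- .compileBank(bank)
  if (is.character(items)) {
    idx <- match(items, bank@items$item_id)
    if (anyNA(idx)) stop("unknown item id: ", items[which(is.na(idx))[1L]])
  } else idx <- as.integer(items)
  comp[idx]
}
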