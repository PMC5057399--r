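# Person-measure estimation shared by CAT and full-bank (NAT) scoring.
#
# MLE  : Newton-Raphson on the pattern log-likelihood (safeguarded by
#        bisection on the gradient bracket), solution clamped to [-4, 4];
#        patterns without an interior maximum are pinned at the boundary.
# MAP  : the same search on log-likelihood + log N(0,1); the unit-variance
#        prior adds 1 to the curvature, so the posterior mode always exists.
# EAP  : posterior mean over 61 equally spaced quadrature nodes on [-4, 4]
#        with standard-normal weights; SEM is the posterior SD.

.MAX_NEWTON <- 50L
.NEWTON_TOL <- 1e-6

.EAP_NODES <- seq(-.THETA_BOUND, .THETA_BOUND, length.out = 61L)
.EAP_LOGW <- stats::dnorm(.EAP_NODES, log = TRUE)

# log-prob table of one compiled item at the EAP nodes: 61 x (m + 1)
.itemNodeLogProbs <- function(ci) {
  z <- ci$a * (outer(.EAP_NODES, ci$x) -
                 matrix(ci$s, length(.EAP_NODES), ci$m + 1L, byrow = TRUE))
  z - apply(z, 1L, .logSumExp)
}

.eapFromLogLik <- function(ll) {
  w <- exp(ll + .EAP_LOGW - max(ll + .EAP_LOGW))
  w <- w / sum(w)
  theta <- sum(w * .EAP_NODES)
  v <- sum(w * (.EAP_NODES - theta)^2)
  list(theta = theta, sem = sqrt(max(v, 1e-12)), converged = TRUE,
       atBoundary = FALSE)
}

# safeguarded Newton on a score function g with curvature (negative of the
# objective's second derivative) cv; assumes g is decreasing in theta.
.newtonRoot <- function(scoreFun, lo = -.THETA_BOUND, hi = .THETA_BOUND) {
  glo <- scoreFun(lo)$grad
  if (glo <= 0) return(list(theta = lo, converged = TRUE, atBoundary = TRUE))
  ghi <- scoreFun(hi)$grad
  if (ghi >= 0) return(list(theta = hi, converged = TRUE, atBoundary = TRUE))
  theta <- 0
  converged <- FALSE
  for (iter in seq_len(.MAX_NEWTON)) {
    s <- scoreFun(theta)
    if (s$grad > 0) lo <- theta else hi <- theta
    step <- if (s$curv > 1e-10) s$grad / s$curv else NA_real_
    if (!is.na(step) && abs(step) < .NEWTON_TOL) { converged <- TRUE; break }
    cand <- theta + step
    if (is.na(cand) || cand <= lo || cand >= hi) cand <- (lo + hi) / 2
    if (abs(cand - theta) < .NEWTON_TOL) {
      theta <- cand; converged <- TRUE; break
    }
    theta <- cand
  }
  list(theta = theta, converged = converged, atBoundary = FALSE)
}

.estMLE <- function(comp, x) {
  if (length(comp) == 0L) stop("MLE is undefined for an empty response pattern")
  mtop <- vapply(comp, `[[`, 0, "m")
  if (all(x == 0L) || all(x == mtop)) {
    theta <- if (all(x == 0L)) -.THETA_BOUND else .THETA_BOUND
    return(list(theta = theta, sem = 1 / sqrt(max(.patternInfo(theta, comp), 1e-12)),
                converged = TRUE, atBoundary = TRUE))
  }
  sf <- function(th) {
    s <- .patternScore(th, comp, x)
    list(grad = s$grad, curv = s$info)
  }
  r <- .newtonRoot(sf)
  r$sem <- 1 / sqrt(max(.patternInfo(r$theta, comp), 1e-12))
  r
}

.estMAP <- function(comp, x) {
  sf <- function(th) {
    s <- if (length(comp)) .patternScore(th, comp, x) else list(grad = 0, info = 0)
    list(grad = s$grad - th, curv = s$info + 1)
  }
  r <- .newtonRoot(sf)
  r$sem <- 1 / sqrt(.patternInfo(r$theta, comp) + 1)
  r
}

.estEAP <- function(comp, x, nodeTabs = NULL) {
  ll <- numeric(length(.EAP_NODES))
  for (j in seq_along(comp)) {
    tab <- if (is.null(nodeTabs)) .itemNodeLogProbs(comp[[j]]) else nodeTabs[[j]]
    ll <- ll + tab[, x[j] + 1L]
  }
  .eapFromLogLik(ll)
}

.estimate <- function(comp, x, method) {
  x <- as.integer(x)
  for (j in seq_along(comp))
    if (x[j] < 0L || x[j] > comp[[j]]$m)
      stop(sprintf("response %d out of range 0..%d for item \"%s\"",
                   x[j], comp[[j]]$m, comp[[j]]$id))
  switch(method,
         MLE = .estMLE(comp, x),
         MAP = .estMAP(comp, x),
         EAP = .estEAP(comp, x),
         stop("unknown estimation method: ", method))
}

.asPersonEstimate <- function(r, method, n) {
  new("PersonEstimate", theta = r$theta, sem = r$sem, method = method,
      nItems = as.integer(n), converged = isTRUE(r$converged),
      atBoundary = isTRUE(r$atBoundary))
}

#' Estimate a person measure from a response pattern
#'
#' Scores one response pattern against (a subset of) an item bank with one of
#' the three estimators: maximum likelihood (`"MLE"`), posterior mode under a
#' standard-normal prior (`"MAP"`), or posterior mean (`"EAP"`, 61-node
#' quadrature on \eqn{[-4, 4]}). Estimates are reported on the bank's logit
#' scale, clamped to \eqn{[-4, 4]}; response patterns with every item at its
#' minimum (or maximum) category have no interior likelihood maximum, so MLE
#' returns the boundary value with `atBoundary = TRUE`.
#'
#' The standard error of measurement is \eqn{1/\sqrt{\sum_i I_i(\hat\theta)}}
#' for MLE, \eqn{1/\sqrt{\sum_i I_i(\hat\theta) + 1}} for MAP (the prior
#' contributes unit curvature), and the posterior SD for EAP.
#'
#' @param bank an [ItemBank-class].
#' @param x integer response categories, aligned with `items`.
#' @param items item ids or indices answered; defaults to the whole bank.
#' @param method `"MLE"`, `"MAP"` or `"EAP"`.
#' @return a [PersonEstimate-class].
#' @examples
#' b <- fixtureBank("ADL-male")
#' estimateAbility(b, rep(1L, 34), method = "MAP")
#' @export
estimateAbility <- function(bank, x, items = NULL,
                            method = c("MLE", "MAP", "EAP")) {
  method <- match.arg(method)
  stopifnot(is(bank, "ItemBank"))
  if (is.null(items)) items <- seq_len(nItems(bank))
  if (length(x) != length(items))
    stop("x and items must have equal length")
  if (method == "MLE" && length(x) == 0L)
    stop("MLE is undefined for an empty response pattern")
  comp <- .resolveItems(bank, items)
  .asPersonEstimate(.estimate(comp, x, method), method, length(x))
}

#' @rdname PersonEstimate-class
#' @export
setMethod("thetaEst", "PersonEstimate", function(x) x@theta)

#' @rdname PersonEstimate-class
#' @export
setMethod("semEst", "PersonEstimate", function(x) x@sem)

setMethod("show", "PersonEstimate", function(object) {
  cat(sprintf("PersonEstimate (%s, %d items): theta = %.3f, SEM = %.3f%s%s\n",
              object@method, object@nItems, object@theta, object@sem,
              if (object@atBoundary) " [boundary]" else "",
              if (!object@converged) " [not converged]" else ""))
  invisible(object)
})

#' Person reliability implied by a standard error of measurement
#'
#' On a unit-variance trait, reliability is `1 - sem^2`. The adaptive test's
#' precision stop rule fires when this reaches 0.90, i.e. when the SEM drops
#' below \eqn{\sqrt{0.1} \approx 0.316}.
#'
#' @param sem positive standard error of measurement.
#' @return reliability in \eqn{(-\infty, 1]}; negative when `sem > 1`.
#' @examples
#' reliabilityFromSem(sqrt(0.1))  # 0.9, the CAT precision threshold
#' @export
reliabilityFromSem <- function(sem) {
  if (any(!is.finite(sem)) || any(sem <= 0)) stop("sem must be positive")
  1 - sem^2
}
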