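# CAT-vs-NAT comparison. NAT ("non-adaptive testing") scores every item of
# the bank; the comparison statistics mirror the study design: Pearson
# correlation of paired measures, the percentage of persons whose CAT and NAT
# measures differ significantly (per-person Wald z on the paired difference),
# the item-length efficiency, and Cronbach's alpha of the raw matrix.

#' Full-bank (NAT) scoring of a complete response matrix
#'
#' @param rm a complete [ResponseMatrix-class].
#' @param bank the matching [ItemBank-class].
#' @param method `"MLE"`, `"MAP"` or `"EAP"`.
#' @return `data.frame` with one row per person: `theta`, `sem`, `converged`,
#'   `at_boundary`.
#' @examples
#' rm <- simulateMatrix(sampleThetas(20, seed = 1), fixtureBank("CADL"), seed = 2)
#' head(natEstimate(rm, fixtureBank("CADL"), "MAP"))
#' @export
natEstimate <- function(rm, bank, method = c("MAP", "EAP", "MLE")) {
  method <- match.arg(method)
  stopifnot(is(rm, "ResponseMatrix"), is(bank, "ItemBank"))
  r <- responses(rm)
  if (!identical(colnames(r), itemIds(bank)))
    stop("response matrix columns do not match the bank's items")
  if (anyNA(r)) stop("NAT scoring requires a complete response matrix")
  comp <- .compileBank(bank)
  n <- nrow(r)
  if (method == "EAP") {
    # accumulate the node-wise log-likelihood over items for all persons
    ll <- matrix(0, length(.EAP_NODES), n)
    for (i in seq_along(comp)) {
      tab <- .itemNodeLogProbs(comp[[i]])
      ll <- ll + tab[, r[, i] + 1L, drop = FALSE]
    }
    lp <- ll + .EAP_LOGW
    w <- exp(sweep(lp, 2L, apply(lp, 2L, max)))
    w <- sweep(w, 2L, colSums(w), "/")
    theta <- colSums(w * .EAP_NODES)
    sem <- sqrt(pmax(colSums(w * .EAP_NODES^2) - theta^2, 1e-12))
    return(data.frame(theta = theta, sem = sem, converged = TRUE,
                      at_boundary = FALSE))
  }
  out <- lapply(seq_len(n), function(p) .estimate(comp, r[p, ], method))
  data.frame(theta = vapply(out, `[[`, 0, "theta"),
             sem = vapply(out, `[[`, 0, "sem"),
             converged = vapply(out, `[[`, TRUE, "converged"),
             at_boundary = vapply(out, `[[`, TRUE, "atBoundary"))
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric measures (length >= 3, nonzero variance).
#' @return the correlation coefficient.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must be paired with length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(x, y)
}

#' Percentage of persons whose CAT and NAT measures differ significantly
#'
#' For each person computes the Wald statistic
#' \eqn{z = (\theta_{CAT} - \theta_{NAT}) / \sqrt{SEM_{CAT}^2 + SEM_{NAT}^2}}
#' and counts \eqn{|z| > 1.96} (two-sided 5\% level). A ratio below 5\%
#' declares the adaptive and full-length measures equivalent.
#'
#' @param thetaCat,semCat CAT measures and their SEMs.
#' @param thetaNat,semNat paired full-bank measures and SEMs.
#' @param alphaLevel two-sided significance level (default 0.05).
#' @return percentage in `[0, 100]`.
#' @export
diffRatio <- function(thetaCat, semCat, thetaNat, semNat, alphaLevel = 0.05) {
  n <- length(thetaCat)
  if (length(semCat) != n || length(thetaNat) != n || length(semNat) != n)
    stop("all four vectors must be paired")
  if (anyNA(semCat) || anyNA(semNat)) stop("SEMs must not be missing")
  crit <- stats::qnorm(1 - alphaLevel / 2)
  z <- (thetaCat - thetaNat) / sqrt(semCat^2 + semNat^2)
  100 * mean(abs(z) > crit)
}

#' CAT item-length efficiency relative to the full bank
#'
#' `100 * (full_len - mean items administered) / full_len`: the percentage of
#' item administrations saved by stopping adaptively.
#'
#' @param sessions list of [CatSession-class], or an integer vector of
#'   administered item counts.
#' @param fullLen the full bank length.
#' @return percentage in `[0, 100)`.
#' @export
efficiency <- function(sessions, fullLen) {
  if (!.isCount(fullLen)) stop("fullLen must be a positive item count")
  nIt <- if (is.numeric(sessions)) sessions
  else vapply(sessions, function(s) length(administered(s)), 0L)
  if (length(nIt) == 0L) stop("no sessions")
  100 * (fullLen - mean(nIt)) / fullLen
}

#' Cronbach's alpha of a response matrix
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_{total}^2)} with sample
#' variances (`n - 1` denominator) of the raw item scores and of the person
#' total scores.
#'
#' @param rm a complete [ResponseMatrix-class] or a numeric persons-by-items
#'   matrix.
#' @return the alpha coefficient (at most 1).
#' @export
cronbachAlpha <- function(rm) {
  m <- if (is(rm, "ResponseMatrix")) responses(rm) else as.matrix(rm)
  if (anyNA(m)) stop("Cronbach's alpha requires a complete matrix")
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need at least 2 items and 2 persons")
  vt <- stats::var(rowSums(m))
  if (vt <= 0) stop("total-score variance is zero; alpha undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / vt)
}

#' Compare CAT against full-bank scoring on one simulated scale
#'
#' Runs full-bank (NAT) scoring of the complete response matrix and an
#' adaptive session per person for each requested estimator, and tabulates
#' the comparison: Pearson r between paired CAT/NAT measures, the significant
#' difference ratio, mean administered items, efficiency, and the scale's
#' Cronbach's alpha.
#'
#' By default (`responseSource = "fresh"`) the adaptive sessions draw their
#' responses from the model at each person's true theta, i.e. CAT and NAT are
#' two independent administrations of the same persons — the design under
#' which the comparison statistics are meaningful measurement replications.
#' `"matrix"` reuses the NAT matrix's realized responses instead, which
#' removes response-sampling noise but makes the paired errors strongly
#' dependent (correlations then approach 1 mechanically).
#'
#' @param rm a complete [ResponseMatrix-class] with `trueThetas` (unless
#'   `responseSource = "matrix"`).
#' @param bank the matching [ItemBank-class].
#' @param methods estimators to compare (default all three).
#' @param seed integer seed driving the random first items and fresh draws.
#' @param responseSource see [runCatCohort()].
#' @param ... stop-rule parameters passed to [runCat()].
#' @return `data.frame` with one row per method: `scale`, `method`,
#'   `pearson_r`, `diff_ratio_pct`, `mean_items_cat`, `efficiency_pct`,
#'   `cronbach_alpha`; CAT and NAT per-person estimates are attached as the
#'   `"estimates"` attribute.
#' @export
compareCatNat <- function(rm, bank, methods = c("MAP", "EAP", "MLE"),
                          seed = NULL, responseSource = c("fresh", "matrix"),
                          ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  responseSource <- match.arg(responseSource)
  alpha <- cronbachAlpha(rm)
  fullLen <- nItems(bank)
  rows <- list(); est <- list()
  for (mth in methods) {
    nat <- natEstimate(rm, bank, mth)
    sess <- runCatCohort(rm, bank, mth, seed = seed,
                         responseSource = responseSource, ...)
    cs <- cohortSummary(sess)
    rows[[mth]] <- data.frame(
      scale = bankName(bank), method = mth,
      pearson_r = pearsonR(cs$theta, nat$theta),
      diff_ratio_pct = diffRatio(cs$theta, cs$sem, nat$theta, nat$sem),
      mean_items_cat = mean(cs$n_items),
      efficiency_pct = efficiency(cs$n_items, fullLen),
      cronbach_alpha = alpha)
    est[[mth]] <- list(cat = cs, nat = nat)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "estimates") <- est
  out
}
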