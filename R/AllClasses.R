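#' @import methods
NULL

.MODELS <- c("rasch_dichotomous", "gpcm")
.METHODS <- c("MLE", "MAP", "EAP")
.THETA_BOUND <- 4.0
.STOP_REASONS <- c("reliability", "convergence", "bank_exhausted")

#' ItemBank: a named, ordered collection of IRT item parameters
#'
#' An `ItemBank` holds one calibrated scale: for every item its model family
#' (dichotomous Rasch or generalized partial credit model), discrimination on
#' the logit metric, and ordered step difficulties. All items of a bank live on
#' a common logit scale, so person measures estimated from any subset of items
#' are comparable.
#'
#' @slot name scale name (e.g. `"CADL"`, `"ADL-male"`, `"ADL-female"`).
#' @slot items `data.frame` with columns `item_id`, `model`, `discrimination`,
#'   `step_1`, `step_2`, `step_3`; unused trailing steps are `NA`.
#'
#' @seealso [itemBank()], [fixtureBank()], [loadBank()]
#' @export
setClass("ItemBank", slots = c(name = "character", items = "data.frame"))

setValidity("ItemBank", function(object) {
  it <- object@items
  req <- c("item_id", "model", "discrimination", "step_1", "step_2", "step_3")
  if (!all(req %in% names(it)))
    return(sprintf("items must have columns %s", paste(req, collapse = ", ")))
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (nrow(it) == 0L) return("bank must contain at least one item")
  if (anyDuplicated(it$item_id)) return("duplicate item_id")
  if (!all(it$model %in% .MODELS))
    return(sprintf("model must be one of: %s", paste(.MODELS, collapse = ", ")))
  if (any(!is.finite(it$discrimination)) || any(it$discrimination <= 0))
    return("discrimination must be a positive finite number")
  steps <- as.matrix(it[, c("step_1", "step_2", "step_3")])
  m <- rowSums(!is.na(steps))
  # steps must be contiguous from step_1
  gap <- apply(steps, 1L, function(s) {
    k <- sum(!is.na(s))
    k > 0L && any(is.na(s[seq_len(k)]))
  })
  if (any(gap)) return("step difficulties must fill step_1..step_m without gaps")
  if (any(m < 1L)) return("every item needs at least one step difficulty")
  ra <- it$model == "rasch_dichotomous"
  if (any(m[ra] != 1L)) return("rasch_dichotomous items must have exactly one step")
  if (any(abs(it$discrimination[ra] - 1) > 1e-12))
    return("rasch_dichotomous items must have discrimination 1.0")
  if (any(m[!ra] > 3L)) return("gpcm items support at most 3 steps")
  TRUE
})

#' PersonEstimate: one person measure with its standard error
#'
#' @slot theta estimated person measure (logit scale, clamped to \eqn{\pm 4}).
#' @slot sem standard error of measurement, \eqn{1/\sqrt{\sum I_i(\hat\theta)}}
#'   (MLE), with `+1` inside the root for the MAP posterior curvature, or the
#'   posterior SD for EAP.
#' @slot method `"MLE"`, `"MAP"` or `"EAP"`.
#' @slot nItems number of responses the estimate is based on.
#' @slot converged did the iterative search converge.
#' @slot atBoundary `TRUE` when the pattern had no interior optimum and the
#'   estimate was pinned at \eqn{\pm 4}.
#' @export
setClass("PersonEstimate", slots = c(
  theta = "numeric", sem = "numeric", method = "character",
  nItems = "integer", converged = "logical", atBoundary = "logical"
))

setValidity("PersonEstimate", function(object) {
  if (length(object@theta) != 1L || !is.finite(object@theta))
    return("theta must be a single finite number")
  if (abs(object@theta) > .THETA_BOUND + 1e-9)
    return(sprintf("|theta| must be <= %.1f", .THETA_BOUND))
  if (length(object@sem) != 1L || is.na(object@sem) || object@sem <= 0)
    return("sem must be a single positive number")
  if (!object@method %in% .METHODS)
    return(sprintf("method must be one of %s", paste(.METHODS, collapse = ", ")))
  if (object@nItems < 0L) return("nItems must be >= 0")
  TRUE
})

#' ResponseMatrix: persons-by-items integer category responses
#'
#' Rows are persons, columns the items of one [ItemBank] (column names are the
#' item ids). Entries are integer score categories `0..m_i`; `NA` marks an
#' unadministered item (written as `-1` in the delimited external format).
#' When the matrix comes from simulation the generating person measures are
#' kept in `trueThetas`.
#'
#' @slot bankName name of the bank the columns refer to.
#' @slot responses integer matrix, persons x items.
#' @slot trueThetas numeric vector of generating thetas (length 0 when unknown).
#' @seealso [simulateMatrix()], [readResponseMatrix()]
#' @export
setClass("ResponseMatrix", slots = c(
  bankName = "character", responses = "matrix", trueThetas = "numeric"
))

setValidity("ResponseMatrix", function(object) {
  r <- object@responses
  if (!is.numeric(r)) return("responses must be a numeric/integer matrix")
  v <- r[!is.na(r)]
  if (any(v < 0) || any(v != round(v)))
    return("responses must be nonnegative integer categories (NA = missing)")
  if (is.null(colnames(r))) return("responses must carry item ids as colnames")
  n <- length(object@trueThetas)
  if (n > 0L && n != nrow(r))
    return("trueThetas length must equal the number of persons")
  TRUE
})

#' CatSession: one person's adaptive-testing trajectory
#'
#' Records the administered item sequence, the responses, the provisional
#' person measure and its standard error after every step, the convergence
#' diagnostics used by the stop rule, and the final estimate.
#'
#' `resi` is the mean of the last three absolute changes in the provisional
#' theta (defined once four estimates exist); `corr` is the Pearson
#' correlation between the last five provisional thetas and their step index —
#' the flatter the theta trend, the more likely the measure has converged.
#'
#' @slot bankName,method bank and estimator used.
#' @slot administered ordered item ids.
#' @slot responses observed categories, aligned with `administered`.
#' @slot thetaTrace,semTrace provisional estimate and SEM after each item.
#' @slot resi,corr convergence diagnostics (NA while undefined).
#' @slot stopReason `"reliability"`, `"convergence"` or `"bank_exhausted"`.
#' @slot final the final [PersonEstimate].
#' @seealso [runCat()]
#' @export
setClass("CatSession", slots = c(
  bankName = "character", method = "character",
  administered = "character", responses = "integer",
  thetaTrace = "numeric", semTrace = "numeric",
  resi = "numeric", corr = "numeric",
  stopReason = "character", final = "PersonEstimate"
))

setValidity("CatSession", function(object) {
  n <- length(object@administered)
  if (length(object@responses) != n || length(object@thetaTrace) != n ||
      length(object@semTrace) != n)
    return("responses and traces must match the administered length")
  if (anyDuplicated(object@administered)) return("administered ids must be unique")
  if (!object@stopReason %in% .STOP_REASONS)
    return(sprintf("stopReason must be one of %s",
                   paste(.STOP_REASONS, collapse = ", ")))
  TRUE
})

#' PersonFit: response-pattern diagnostics for one person
#'
#' Standardized residuals \eqn{z_i = (x_i - E_i)/\sqrt{W_i}} for each answered
#' item, the unweighted (outfit) and information-weighted (infit) mean-square
#' statistics, and the ids of items whose \eqn{|z| \ge 2} flag an unexpected
#' response.
#'
#' @slot infitMnsq,outfitMnsq mean-square fit statistics (about 1 under the model).
#' @slot zScores per-item standardized residuals, named by item id.
#' @slot flagged item ids with \eqn{|z| \ge 2.0}.
#' @seealso [personFit()]
#' @export
setClass("PersonFit", slots = c(
  infitMnsq = "numeric", outfitMnsq = "numeric",
  zScores = "numeric", flagged = "character"
))

setValidity("PersonFit", function(object) {
  if (object@infitMnsq < 0 || object@outfitMnsq < 0)
    return("mean-square statistics must be nonnegative")
  if (!all(object@flagged %in% names(object@zScores)))
    return("flagged ids must be a subset of the scored items")
  TRUE
})

#' StratumResult: norm-referenced person strata and their cutpoints
#'
#' The output of the cutpoint procedure: `k` ascending ability strata with
#' their cluster sizes, and for each of the `k - 1` boundaries the theta-scale
#' cutpoint, its T-score transform (\eqn{T = 50 + 10\theta}), and the
#' specificity/sensitivity of the cut under the two adjacent normal clusters.
#'
#' @slot labels ordered stratum names, lowest ability first.
#' @slot sizes persons per stratum.
#' @slot clusterMeans,clusterSds per-stratum normal parameters.
#' @slot cutTheta,cutT strictly increasing cutpoints (logit and T scale).
#' @slot specificity,sensitivity per cut, in `[0, 1]`.
#' @seealso [deriveCutpoints()]
#' @export
setClass("StratumResult", slots = c(
  labels = "character", sizes = "integer",
  clusterMeans = "numeric", clusterSds = "numeric",
  cutTheta = "numeric", cutT = "numeric",
  specificity = "numeric", sensitivity = "numeric"
))

setValidity("StratumResult", function(object) {
  k <- length(object@labels)
  if (length(object@sizes) != k || length(object@clusterMeans) != k ||
      length(object@clusterSds) != k)
    return("labels, sizes, clusterMeans, clusterSds must share length k")
  nc <- k - 1L
  if (length(object@cutTheta) != nc || length(object@cutT) != nc ||
      length(object@specificity) != nc || length(object@sensitivity) != nc)
    return("cut vectors must have length k - 1")
  if (nc > 1L && any(diff(object@cutTheta) <= 0))
    return("cutTheta must be strictly increasing")
  if (any(object@specificity < 0 | object@specificity > 1) ||
      any(object@sensitivity < 0 | object@sensitivity > 1))
    return("specificity and sensitivity must lie in [0, 1]")
  TRUE
})
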