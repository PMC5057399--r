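# Norm-referenced person-strata cutpoints. Lacking a gold standard, the
# procedure replaces an empirical ROC with: (1) a reliability-based count of
# statistically distinguishable strata, (2) one-dimensional k-means clusters
# of the person measures, and (3) for each adjacent cluster pair, a brute
# force search for the score maximizing specificity + sensitivity under the
# two fitted normal distributions. Cuts are finally mapped to the T metric,
# T = 50 + 10 * theta.

#' Number of distinguishable person strata implied by reliability
#'
#' Uses the separation index \eqn{G = \sqrt{rel/(1-rel)}} and
#' \eqn{H = \lfloor (4G + 1)/3 \rfloor} (minimum 1): the number of person
#' levels a scale of that reliability can separate with 95\% confidence.
#' Reproduces the conventional lookup 0.67 to 2 groups, 0.80 to 3, 0.90 to 4,
#' 0.94 to 5, 0.96 to 6, 0.97 to 7.
#'
#' @param reliability scale reliability in `[0, 1)`.
#' @return integer number of strata (>= 1).
#' @examples
#' strataCount(0.90)  # 4
#' @export
strataCount <- function(reliability) {
  if (length(reliability) != 1L || !is.finite(reliability) ||
      reliability < 0 || reliability >= 1)
    stop("reliability must lie in [0, 1)")
  G <- sqrt(reliability / (1 - reliability))
  max(1L, as.integer(floor((4 * G + 1) / 3)))
}

#' One-dimensional k-means clustering of person measures
#'
#' Exact 1-D k-means: in one dimension the optimal clusters are contiguous in
#' sorted order, so the globally optimal partition (minimal within-cluster sum
#' of squares) is found by dynamic programming over the sorted values — no
#' random restarts, no Lloyd local optima, fully deterministic. (Lloyd
#' iterations from quantile starts can collapse adjacent clusters on the
#' strongly discretized measure distributions short scales produce.)
#' Clusters are returned in ascending order; each cluster's SD is taken from
#' its own members (singletons and zero-variance clusters fall back to the
#' pooled within-cluster SD).
#'
#' @param x numeric person measures (length >= k).
#' @param k number of clusters.
#' @return list with `means`, `sds`, `sizes` (ascending by mean), `cluster`
#'   (1-based ascending assignment per observation) and `wcss` (the optimal
#'   within-cluster sum of squares).
#' @export
kmeans1d <- function(x, k) {
  x <- as.numeric(x)
  if (!.isCount(k)) stop("k must be a positive integer")
  n <- length(x)
  if (n < k) stop("need at least k observations")
  k <- as.integer(k)
  ord <- order(x)
  xs <- x[ord]
  cs <- c(0, cumsum(xs)); css <- c(0, cumsum(xs^2))
  # cost(j, i): WCSS of one cluster spanning sorted positions j..i
  costTo <- function(i, j) {
    nseg <- i - j + 1
    css[i + 1L] - css[j] - (cs[i + 1L] - cs[j])^2 / nseg
  }
  D <- matrix(Inf, n, k)  # D[i, kk]: best WCSS of xs[1..i] in kk clusters
  B <- matrix(1L, n, k)   # start index of the last cluster
  D[, 1L] <- costTo(seq_len(n), 1L)
  if (k > 1L) for (kk in 2:k) for (i in kk:n) {
    j <- kk:i
    vals <- D[j - 1L, kk - 1L] + costTo(i, j)
    best <- which.min(vals)   # first minimum: deterministic tie-break
    D[i, kk] <- vals[best]
    B[i, kk] <- j[best]
  }
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  i <- n
  for (kk in k:1) { bounds[kk] <- B[i, kk] - 1L; i <- B[i, kk] - 1L }
  clSorted <- rep(seq_len(k), diff(bounds))
  cl <- integer(n); cl[ord] <- clSorted
  means <- vapply(seq_len(k), function(j) mean(xs[clSorted == j]), 0)
  sizes <- vapply(seq_len(k), function(j) sum(clSorted == j), 0L)
  sds <- vapply(seq_len(k), function(j) {
    seg <- xs[clSorted == j]
    if (length(seg) > 1L) stats::sd(seg) else NA_real_
  }, 0)
  if (anyNA(sds) || any(sds == 0, na.rm = TRUE)) {
    pooled <- sqrt(D[n, k] / max(n - k, 1L))
    sds[is.na(sds) | sds == 0] <- max(pooled, 1e-6)
  }
  list(means = means, sds = sds, sizes = sizes, cluster = cl, wcss = D[n, k])
}

#' Best cutpoint between two adjacent normal clusters
#'
#' Grid search over `[muLo, muHi]` for the score `c` maximizing
#' `Sp(c) + Se(c)`, where specificity \eqn{Sp = \Phi((c - \mu_{lo})/\sigma_{lo})}
#' is the probability that a lower-cluster member falls below the cut and
#' sensitivity \eqn{Se = 1 - \Phi((c - \mu_{hi})/\sigma_{hi})} the probability
#' that an upper-cluster member falls above it. With equal SDs the optimum is
#' the midpoint of the means; in general it is the point where the two normal
#' densities are equal.
#'
#' @param muLo,sdLo mean and SD of the lower cluster.
#' @param muHi,sdHi mean and SD of the upper cluster (`muHi > muLo`).
#' @param gridStep search resolution on the theta scale (default 0.01, i.e.
#'   0.1 T-score units).
#' @return list with `cut`, `specificity`, `sensitivity`.
#' @examples
#' bestCut(-1, 1, 1, 1)  # cut 0, Se = Sp = pnorm(1)
#' @export
bestCut <- function(muLo, sdLo, muHi, sdHi, gridStep = 0.01) {
  if (!is.finite(muLo) || !is.finite(muHi) || muLo >= muHi)
    stop("muLo must be strictly below muHi")
  if (sdLo <= 0 || sdHi <= 0) stop("cluster SDs must be positive")
  grid <- seq(muLo, muHi, by = gridStep)
  if (grid[length(grid)] < muHi) grid <- c(grid, muHi)
  sp <- stats::pnorm((grid - muLo) / sdLo)
  se <- stats::pnorm((grid - muHi) / sdHi, lower.tail = FALSE)
  i <- which.max(sp + se)
  list(cut = grid[i], specificity = sp[i], sensitivity = se[i])
}

#' T-score transform of a person measure
#'
#' `T = 50 + 10 * theta`: the logit measure re-expressed on a mean-50, SD-10
#' reporting scale.
#'
#' @param theta person measure(s) on the logit scale.
#' @return T score(s).
#' @examples
#' tScore(c(-0.66, 0.46, 1.51))
#' @export
tScore <- function(theta) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  50 + 10 * theta
}

.DEFAULT_STRATA <- c("Not Active", "Fairly Active", "Active", "Very Active")

#' Derive norm-referenced strata cutpoints from person measures
#'
#' The full staged procedure: scale reliability determines the number of
#' strata ([strataCount()], capped at `cap`); [kmeans1d()] groups the person
#' measures; [bestCut()] places a cut between every adjacent cluster pair at
#' maximal specificity + sensitivity; [tScore()] maps the cuts to the T
#' metric. Stratum labels run from lowest to highest functioning.
#'
#' @param measures estimated person measures (typically full-bank estimates).
#' @param alpha scale reliability feeding [strataCount()]; ignored when `k`
#'   is given directly.
#' @param k optional explicit number of strata.
#' @param cap maximum strata (default 4, the conventional reporting choice
#'   even for scales whose reliability would support 5).
#' @param gridStep resolution of the cut search, see [bestCut()].
#' @param labels stratum names, lowest first; used when `k` matches their
#'   length, otherwise generic names are generated.
#' @return a [StratumResult-class].
#' @examples
#' x <- c(rnorm(50, -2, .3), rnorm(50, 0, .3), rnorm(50, 2, .3))
#' deriveCutpoints(x, k = 3)
#' @export
deriveCutpoints <- function(measures, alpha = NULL, k = NULL, cap = 4L,
                            gridStep = 0.01, labels = .DEFAULT_STRATA) {
  measures <- as.numeric(measures)
  if (any(!is.finite(measures))) stop("measures must be finite")
  if (is.null(k)) {
    if (is.null(alpha)) stop("give either alpha (reliability) or k")
    k <- min(strataCount(alpha), as.integer(cap))
  }
  k <- as.integer(k)
  if (length(measures) < 2L * k)
    stop("need at least 2*k person measures")
  cl <- kmeans1d(measures, k)
  labs <- if (length(labels) == k) labels else paste("Stratum", seq_len(k))
  if (k == 1L)
    return(new("StratumResult", labels = labs, sizes = as.integer(cl$sizes),
               clusterMeans = cl$means, clusterSds = cl$sds,
               cutTheta = numeric(0), cutT = numeric(0),
               specificity = numeric(0), sensitivity = numeric(0)))
  cuts <- lapply(seq_len(k - 1L), function(j)
    bestCut(cl$means[j], cl$sds[j], cl$means[j + 1L], cl$sds[j + 1L],
            gridStep = gridStep))
  new("StratumResult", labels = labs, sizes = as.integer(cl$sizes),
      clusterMeans = cl$means, clusterSds = cl$sds,
      cutTheta = vapply(cuts, `[[`, 0, "cut"),
      cutT = tScore(vapply(cuts, `[[`, 0, "cut")),
      specificity = vapply(cuts, `[[`, 0, "specificity"),
      sensitivity = vapply(cuts, `[[`, 0, "sensitivity"))
}

setMethod("show", "StratumResult", function(object) {
  k <- length(object@labels)
  cat(sprintf("StratumResult: %d strata, %d persons\n", k, sum(object@sizes)))
  for (j in seq_len(k)) {
    if (j > 1L)
      cat(sprintf("  -- cut theta %.2f (T %.1f), Sp %.2f / Se %.2f --\n",
                  object@cutTheta[j - 1L], object@cutT[j - 1L],
                  object@specificity[j - 1L], object@sensitivity[j - 1L]))
    cat(sprintf("  %-14s n = %d (mean %.2f, SD %.2f)\n", object@labels[j],
                object@sizes[j], object@clusterMeans[j], object@clusterSds[j]))
  }
  invisible(object)
})

#' Tabulate a StratumResult
#'
#' One row per stratum, mirroring the cutpoint report layout: stratum label,
#' cluster size, the IRT-scale and T-scale cutpoint that separates the
#' stratum from the one below it (blank for the lowest), and the cut's
#' specificity and sensitivity.
#'
#' @param x a [StratumResult-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a `data.frame`.
#' @export
as.data.frame.StratumResult <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  k <- length(x@labels)
  pad <- function(v) c(NA_real_, v)
  data.frame(stratum = x@labels, n = x@sizes,
             irt_score = pad(x@cutTheta), t_score = pad(x@cutT),
             specificity = pad(x@specificity), sensitivity = pad(x@sensitivity))
}
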