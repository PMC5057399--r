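# Small banks and brute-force oracles shared across the test files.
# All fixtures are built in code; the only packaged data are the item banks.

dichBank <- function(deltas, name = "dich") {
  itemBank(name, data.frame(
    item_id = sprintf("d%02d", seq_along(deltas)),
    model = "rasch_dichotomous", discrimination = 1,
    step_1 = deltas, step_2 = NA_real_, step_3 = NA_real_))
}

# mixed-format polytomous bank exercising 2-, 3- and 4-category items
toyGpcmBank <- function() {
  itemBank("toy-gpcm", data.frame(
    item_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    model = "gpcm",
    discrimination = c(2.18, 0.8, 1.06, 3.02, 2.07, 0.55),
    step_1 = c(-1.36, -0.84, -1.95, -1.12, -0.83, -2.48),
    step_2 = c(NA, NA, -0.78, -0.24, -0.03, -1.35),
    step_3 = c(NA, NA, NA, NA, 0.16, NA)))
}

# direct GPCM category probabilities, written independently of the package
# kernels (plain exponential form, no log-space tricks)
oracleProbs <- function(theta, a, steps) {
  num <- vapply(0:length(steps), function(x)
    exp(sum(a * (theta - steps[seq_len(x)]))), 0)
  num / sum(num)
}

# vectorized pattern log-likelihood over a theta grid
gridLogLik <- function(grid, bank, items, x) {
  pars <- itemParameters(bank)[items, ]
  ll <- numeric(length(grid))
  for (j in seq_len(nrow(pars))) {
    steps <- unlist(pars[j, c("step_1", "step_2", "step_3")])
    steps <- steps[!is.na(steps)]
    a <- pars$discrimination[j]
    s <- c(0, cumsum(steps))
    z <- a * (outer(grid, 0:length(steps)) -
                matrix(s, length(grid), length(s), byrow = TRUE))
    z <- z - apply(z, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    ll <- ll + log(p[, x[j] + 1L])
  }
  ll
}

# grid-search oracles for the three estimators
oracleMLE <- function(bank, items, x, step = 5e-4) {
  grid <- seq(-4, 4, by = step)
  grid[which.max(gridLogLik(grid, bank, items, x))]
}
oracleMAP <- function(bank, items, x, step = 5e-4) {
  grid <- seq(-4, 4, by = step)
  grid[which.max(gridLogLik(grid, bank, items, x) + dnorm(grid, log = TRUE))]
}
oracleEAP <- function(bank, items, x, nNodes = 1e5) {
  grid <- seq(-4, 4, length.out = nNodes)
  lp <- gridLogLik(grid, bank, items, x) + dnorm(grid, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  sum(w * grid)
}

# random response pattern on a bank (any category equally likely; stresses
# the estimators with patterns the model itself would rarely produce)
randomPattern <- function(bank, nItems) {
  nItems <- min(nItems, adlcat::nItems(bank))
  idx <- sort(sample.int(adlcat::nItems(bank), nItems))
  m <- maxScore(bank)[idx]
  list(items = idx, x = vapply(m, function(mm) sample(0:mm, 1L), 0L))
}

# exhaustive optimal contiguous 1-D partition (dynamic-programming-free
# enumeration over boundary placements; tractable for n <= 12, k <= 3)
oracleWcss <- function(x, k) {
  xs <- sort(x); n <- length(xs)
  segCost <- function(i, j) sum((xs[i:j] - mean(xs[i:j]))^2)
  if (k == 1L) return(segCost(1, n))
  bounds <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (col in seq_len(ncol(bounds))) {
    b <- c(0L, bounds[, col], n)
    cost <- sum(vapply(seq_len(k), function(j) segCost(b[j] + 1L, b[j + 1L]), 0))
    best <- min(best, cost)
  }
  best
}
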