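test_that("full-bank scoring matches the single-pattern estimators", {
  bank <- toyGpcmBank()
  rm <- simulateMatrix(sampleThetas(25, seed = 21), bank, seed = 22)
  r <- responses(rm)
  for (m in c("MAP", "EAP", "MLE")) {
    nat <- natEstimate(rm, bank, m)
    expect_equal(nrow(nat), 25L)
    # the vectorized cohort path must agree with per-person estimation
    for (p in c(1, 13, 25)) {
      one <- estimateAbility(bank, r[p, ], method = m)
      expect_equal(nat$theta[p], thetaEst(one), tolerance = 1e-9)
      expect_equal(nat$sem[p], semEst(one), tolerance = 1e-9)
    }
  }
  # all-minimum row under MAP: negative but finite (prior regularizes)
  rm0 <- new("ResponseMatrix", bankName = "toy-gpcm",
             responses = matrix(0L, 1, 6, dimnames = list(NULL, itemIds(bank))),
             trueThetas = numeric(0))
  est0 <- natEstimate(rm0, bank, "MAP")
  expect_lt(est0$theta, 0)
  expect_true(is.finite(est0$theta))
  # missing cells are refused
  rNA <- responses(rm); rNA[2, 3] <- NA
  rmNA <- new("ResponseMatrix", bankName = "toy-gpcm", responses = rNA,
              trueThetas = numeric(0))
  expect_error(natEstimate(rmNA, bank, "MAP"), "complete")
})

test_that("pearsonR reproduces the product-moment formula", {
  expect_equal(pearsonR(1:5, 1:5), 1)
  expect_equal(pearsonR(1:5, 5:1), -1)
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1); y <- c(0.8, 2.9, 2.5, 4.2, 4.4)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), byHand, tolerance = 1e-12)
  expect_error(pearsonR(1:2, 1:2), "length")
  expect_error(pearsonR(rep(1, 5), 1:5), "variance")
})

test_that("diffRatio counts per-person Wald-significant pairs", {
  th <- rnorm(50)
  expect_equal(diffRatio(th, rep(0.3, 50), th, rep(0.3, 50)), 0)
  expect_equal(diffRatio(th + 10, rep(0.1, 50), th, rep(0.1, 50)), 100)
  # one pair exactly at 3 SE, others identical
  cat <- c(0, 3 * sqrt(2) * 0.5); nat <- c(0, 0)
  expect_equal(diffRatio(cat, c(0.5, 0.5), nat, c(0.5, 0.5)), 50)
  expect_error(diffRatio(1:3, 1:3, 1:3, 1:2), "paired")
  expect_error(diffRatio(1, NA, 1, 1), "missing")
})

test_that("efficiency is the mean item-length saving", {
  expect_equal(efficiency(rep(13L, 10), 34), 100 * 21 / 34, tolerance = 1e-12)
  expect_equal(efficiency(rep(17L, 3), 34), 50)
  expect_equal(efficiency(rep(23L, 5), 23), 0)
  expect_error(efficiency(integer(0), 34), "no sessions")
  expect_error(efficiency(1:3, 0), "positive")
})

test_that("cronbachAlpha matches the hand formula", {
  m <- cbind(a = c(1, 0, 1, 1, 0), b = c(1, 0, 1, 1, 0))
  expect_equal(cronbachAlpha(m), 1)
  m2 <- cbind(x = c(2, 1, 0, 2, 1, 0), y = c(2, 0, 1, 2, 2, 0))
  k <- 2
  byHand <- k / (k - 1) * (1 - (var(m2[, 1]) + var(m2[, 2])) / var(rowSums(m2)))
  expect_equal(cronbachAlpha(m2), byHand, tolerance = 1e-12)
  expect_error(cronbachAlpha(matrix(1, 4, 3)), "variance")
  expect_error(cronbachAlpha(m2[1, , drop = FALSE]), "at least 2")
})

test_that("compareCatNat assembles a coherent per-method report", {
  bank <- fixtureBank("ADL-female")
  rm <- simulateMatrix(sampleThetas(120, seed = 23), bank, seed = 24)
  rep1 <- compareCatNat(rm, bank, methods = "MAP", seed = 25)
  expect_equal(names(rep1), c("scale", "method", "pearson_r", "diff_ratio_pct",
                              "mean_items_cat", "efficiency_pct",
                              "cronbach_alpha"))
  expect_equal(rep1$scale, "ADL-female")
  expect_gt(rep1$pearson_r, 0.8)
  expect_gte(rep1$mean_items_cat, 7)
  expect_true(rep1$efficiency_pct >= 0 && rep1$efficiency_pct < 100)
  expect_true(rep1$diff_ratio_pct >= 0 && rep1$diff_ratio_pct <= 100)
  # identical seed, identical report
  rep2 <- compareCatNat(rm, bank, methods = "MAP", seed = 25)
  expect_identical(rep1, rep2)
  # nested (matrix) responses tie CAT to NAT more tightly than fresh draws
  repM <- compareCatNat(rm, bank, methods = "MAP", seed = 25,
                        responseSource = "matrix")
  expect_gt(repM$pearson_r, rep1$pearson_r)
  # fresh draws need the generating thetas
  rmNoTT <- new("ResponseMatrix", bankName = bankName(rm),
                responses = responses(rm), trueThetas = numeric(0))
  expect_error(compareCatNat(rmNoTT, bank, methods = "MAP"), "trueThetas")
})
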