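test_that("item selection maximizes information at the provisional theta", {
  b <- fixtureBank("CADL")
  # Rasch information peaks where delta is nearest theta: at 0.5 that is
  # bathing (delta 0.55), once another item has been administered first
  expect_equal(selectNextItem(b, 0.5, administered = "FAI 6: local shopping"),
               "BI 2: bathing")
  # one remaining item: that item
  expect_equal(selectNextItem(b, 0, administered = itemIds(b)[-7]),
               itemIds(b)[7])
  expect_error(selectNextItem(b, 0, administered = itemIds(b)), "exhausted")
  expect_error(selectNextItem(b, 0, administered = "nope"), "unknown")
  # random first pick is seed-reproducible
  expect_identical(selectNextItem(b, 0, seed = 5), selectNextItem(b, 0, seed = 5))
})

mkSession <- function(n, sem, thetaTr, method = "MAP") {
  new("CatSession", bankName = "toy", method = method,
      administered = sprintf("i%02d", seq_len(n)), responses = rep(0L, n),
      thetaTrace = thetaTr, semTrace = c(rep(1, n - 1), sem),
      resi = NA_real_, corr = NA_real_, stopReason = "bank_exhausted",
      final = new("PersonEstimate", theta = thetaTr[n], sem = sem,
                  method = method, nItems = as.integer(n), converged = TRUE,
                  atBoundary = FALSE))
}

test_that("the compound stop rule needs 7 items plus its criteria", {
  flat <- function(n) rep(0.5, n)  # resi 0 once defined
  # below the minimum item count nothing stops, however precise
  expect_false(shouldStop(mkSession(6, 0.1, flat(6)))$stop)
  expect_false(shouldStop(mkSession(6, 0.1, flat(6)), stopRule = "any")$stop)
  # n = 7, sem 0.30: reliability 0.91 >= 0.90; flat trace satisfies resi too
  s <- shouldStop(mkSession(7, 0.30, flat(7)))
  expect_true(s$stop); expect_equal(s$reason, "reliability")
  # conjunctive rule: precise but still-moving trace must not stop
  moving <- c(rep(0.5, 6), 1.0, 1.5, 2.0, 2.5)
  expect_false(shouldStop(mkSession(10, 0.30, moving))$stop)
  expect_true(shouldStop(mkSession(10, 0.30, moving), stopRule = "any")$stop)
  # disjunctive rule stops on convergence alone: last 3 changes average 0.02
  tr <- c(rep(0, 7), 0.01, 0.03, 0.06)
  s2 <- shouldStop(mkSession(10, 0.5, tr), stopRule = "any")
  expect_true(s2$stop); expect_equal(s2$reason, "convergence")
  expect_false(shouldStop(mkSession(10, 0.5, tr))$stop)  # reliability unmet
})

test_that("runCat produces a coherent, reproducible session", {
  bank <- fixtureBank("ADL-male")
  s1 <- runCat(bank, "MAP", trueTheta = 0.3, seed = 71)
  s2 <- runCat(bank, "MAP", trueTheta = 0.3, seed = 71)
  expect_identical(thetaTrace(s1), thetaTrace(s2))
  expect_identical(administered(s1), administered(s2))
  n <- length(administered(s1))
  expect_gte(n, 7L)
  expect_equal(length(responses(s1)), n)
  expect_equal(length(semTrace(s1)), n)
  expect_false(anyDuplicated(administered(s1)) > 0)
  expect_true(stopReason(s1) %in% c("reliability", "convergence",
                                    "bank_exhausted"))
  expect_equal(thetaEst(finalEstimate(s1)), thetaTrace(s1)[n])
  # pinned first item overrides the random pick
  s3 <- runCat(bank, "MAP", trueTheta = 0.3, seed = 71,
               firstItem = "5. Taking public transportation")
  expect_equal(administered(s3)[1], "5. Taking public transportation")
})

test_that("simulated cohort sessions satisfy the engine invariants", {
  bank <- fixtureBank("ADL-male")
  tt <- sampleThetas(40, seed = 72)
  rm <- simulateMatrix(tt, bank, seed = 73)
  sess <- runCatCohort(rm, bank, "MAP", seed = 74, responseSource = "fresh")
  cs <- cohortSummary(sess)
  for (s in sess) {
    n <- length(administered(s))
    expect_true(stopReason(s) %in% c("reliability", "convergence",
                                     "bank_exhausted"))
    if (stopReason(s) != "bank_exhausted") expect_gte(n, 7L)
    if (stopReason(s) == "reliability")
      expect_gte(reliabilityFromSem(semTrace(s)[n]), 0.90)
    # under the conjunctive rule a regular stop also satisfied resi
    if (stopReason(s) %in% c("reliability", "convergence"))
      expect_lt(s@resi, 0.05)
  }
  # matrix mode reuses the realized responses: administered cells must agree
  sessM <- runCatCohort(rm, bank, "MAP", seed = 74, responseSource = "matrix")
  r <- responses(rm)
  for (p in seq_along(sessM)) {
    idx <- match(administered(sessM[[p]]), itemIds(bank))
    expect_identical(responses(sessM[[p]]), unname(r[p, idx]))
  }
  expect_identical(cohortSummary(runCatCohort(rm, bank, "MAP", seed = 74,
                                              responseSource = "fresh")), cs)
})

test_that("responder callbacks are validated and drive the session", {
  bank <- dichBank(seq(-2, 2, by = 0.5), name = "toy9")
  alwaysTop <- function(id, i) 1L
  s <- runCat(bank, "MAP", responder = alwaysTop, seed = 75)
  expect_true(all(responses(s) == 1L))
  expect_gt(thetaEst(finalEstimate(s)), 0)
  expect_error(runCat(bank, "MAP", responder = function(id, i) 7L, seed = 75),
               "invalid category")
  expect_error(runCat(bank, "MAP", trueTheta = 0, responses = rep(0L, 9)),
               "exactly one")
})

test_that("person-fit statistics follow their definitions", {
  b <- dichBank(0)
  fit <- personFit(b, 1L, theta = 0)   # P = 0.5: z = (1 - .5)/sqrt(.25) = 1
  expect_equal(unname(fit@zScores), 1, tolerance = 1e-12)
  expect_equal(fit@outfitMnsq, 1, tolerance = 1e-12)
  expect_equal(fit@infitMnsq, 1, tolerance = 1e-12)
  expect_length(fit@flagged, 0L)

  # under the model, outfit is about 1 on average
  bank <- fixtureBank("ADL-male")
  tt <- sampleThetas(200, seed = 76)
  r <- responses(simulateMatrix(tt, bank, seed = 77))
  outfits <- vapply(seq_len(200), function(p)
    personFit(bank, r[p, ], theta = tt[p])@outfitMnsq, 0)
  expect_lt(abs(mean(outfits) - 1), 0.1)

  # all-correct answers on very easy items: residuals near 0, nothing flagged
  easy <- dichBank(rep(-6, 8), name = "easy")
  fitE <- personFit(easy, rep(1L, 8), theta = 2)
  expect_true(all(abs(fitE@zScores) < 0.2))
  expect_length(fitE@flagged, 0L)

  # degenerate items (zero score variance at theta) are excluded with warning
  deg <- dichBank(c(-30, 0), name = "deg")
  expect_warning(fitD <- personFit(deg, c(1L, 1L), theta = 4), "degenerate")
  expect_length(fitD@zScores, 1L)
})

test_that("session logs tabulate every step", {
  bank <- fixtureBank("ADL-male")
  s <- runCat(bank, "MAP", trueTheta = -0.5, seed = 78)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSessionLog(s, bank, f)
  log <- read.csv(f)
  expect_equal(nrow(log), length(administered(s)))
  expect_equal(names(log), c("step", "item_id", "response", "theta", "sem",
                             "resi", "corr", "z"))
  expect_equal(log$theta, thetaTrace(s), tolerance = 1e-9)
})
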