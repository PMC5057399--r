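test_that("studyConfig validates its inputs", {
  cfg <- studyConfig(nPersons = 10, seed = 9)
  expect_s3_class(cfg, "StudyConfig")
  expect_equal(cfg$stopRule, "all")
  expect_error(studyConfig(scales = "ADL"), "unknown scale")
  expect_error(studyConfig(methods = "WLE"), "unknown method")
  expect_error(studyConfig(nPersons = 0), "positive")
  expect_error(studyConfig(reliabilityStop = 1.2), "0, 1")
  expect_error(studyConfig(scaleAlpha = c(CADL = 0.9)), "every requested")
})

test_that("simulateStudyData shares one cohort across the scales", {
  cfg <- studyConfig(nPersons = 20, seed = 9)
  data <- simulateStudyData(cfg)
  expect_named(data, c("CADL", "ADL-male", "ADL-female"))
  expect_equal(dim(data$CADL), c(20L, 23L))
  expect_equal(dim(data$`ADL-male`), c(20L, 34L))
  expect_equal(dim(data$`ADL-female`), c(20L, 34L))
  expect_identical(trueThetas(data$CADL), trueThetas(data$`ADL-male`))
  # same config, same data
  expect_identical(responses(simulateStudyData(cfg)$CADL),
                   responses(data$CADL))
})

test_that("writeStudyMatrices writes reproducible CSVs plus a manifest", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg1 <- studyConfig(nPersons = 15, seed = 10, outDir = d1)
  cfg2 <- studyConfig(nPersons = 15, seed = 10, outDir = d2)
  f1 <- writeStudyMatrices(cfg1)
  f2 <- writeStudyMatrices(cfg2)
  expect_length(f1, 3L)
  expect_true(all(file.exists(f1)))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  man <- jsonlite::read_json(file.path(d1, "run_manifest.json"))
  expect_equal(man$seed, 10L)
  expect_equal(man$n_persons, 15L)
  expect_equal(man$stop_rule, "all")
  # written matrices load back as valid response data
  back <- readResponseMatrix(f1[1], bankName = "CADL")
  expect_equal(dim(back), c(15L, 23L))
})

test_that("runComparison populates the requested grid deterministically", {
  cfg <- studyConfig(scales = "ADL-male", methods = c("MAP", "EAP"),
                     nPersons = 60, seed = 12)
  rep1 <- runComparison(cfg)
  expect_equal(nrow(rep1), 2L)
  expect_equal(rep1$method, c("MAP", "EAP"))
  expect_true(all(rep1$pearson_r > 0.7))
  expect_identical(runComparison(cfg), rep1)
  # single cell
  cfg1 <- studyConfig(scales = "CADL", methods = "MAP", nPersons = 40,
                      seed = 13)
  expect_equal(nrow(runComparison(cfg1)), 1L)
})

test_that("runCutpointStudy reports one block per scale and method", {
  cfg <- studyConfig(scales = "ADL-female", methods = "MAP", nPersons = 150,
                     seed = 14)
  cp <- runCutpointStudy(cfg)
  expect_equal(nrow(cp), 4L)  # four strata per block
  expect_equal(cp$stratum, c("Not Active", "Fairly Active", "Active",
                             "Very Active"))
  expect_equal(sum(cp$n), 150L)
  expect_true(all(diff(na.omit(cp$t_score)) > 0))
  expect_true(all(na.omit(c(cp$specificity, cp$sensitivity)) <= 1))
  # a strata cap of 2 gives a single cut
  cfg2 <- studyConfig(scales = "ADL-female", methods = "MAP", nPersons = 150,
                      seed = 14, strataCap = 2L)
  cp2 <- runCutpointStudy(cfg2)
  expect_equal(nrow(cp2), 2L)
  expect_equal(sum(!is.na(cp2$t_score)), 1L)
})

test_that("interactiveCat runs a scripted session to the stop rule", {
  bank <- dichBank(seq(-2.4, 2.4, by = 0.3), name = "toy17")
  answers <- textConnection(paste(rep(c("1", "0"), 20), collapse = "\n"))
  out <- textConnection("sink", "w", local = TRUE)
  s <- interactiveCat(bank, "MAP", input = answers, output = out, seed = 15)
  close(answers)
  printed <- textConnectionValue(out); close(out)
  expect_s4_class(s, "CatSession")
  expect_gte(length(administered(s)), 7L)
  expect_true(any(grepl("^Done", printed)))
  expect_equal(sum(grepl("^  step", printed)), length(administered(s)))

  # out-of-range input is re-prompted, not accepted
  answers2 <- textConnection(paste(c("9", "x", rep(c("1", "0"), 20)),
                                   collapse = "\n"))
  out2 <- textConnection("sink2", "w", local = TRUE)
  s2 <- interactiveCat(bank, "MAP", input = answers2, output = out2, seed = 15)
  close(answers2)
  printed2 <- textConnectionValue(out2); close(out2)
  expect_equal(sum(grepl("please answer", printed2)), 2L)
  expect_identical(responses(s2), responses(s))

  # exhausted input before the stop rule is an error
  answers3 <- textConnection("1\n0")
  expect_error(interactiveCat(bank, "MAP", input = answers3, seed = 15,
                              output = textConnection("s3", "w", local = TRUE)),
               "exhausted")
  close(answers3)
})

test_that("the command-line front end drives the study functions", {
  cli <- system.file("exec", "adlcat", package = "adlcat")
  expect_true(nzchar(cli))
  rbin <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run <- function(...) {
    suppressWarnings(system2(rbin, c(cli, ...), stdout = TRUE, stderr = TRUE,
                             env = paste0("R_LIBS=", shQuote(libs))))
  }
  d <- withr::local_tempdir()
  out <- run("simulate", "--n-persons", "8", "--seed", "3",
             "--scales", "CADL", "--out-dir", d)
  expect_true(file.exists(file.path(d, "responses_CADL.csv")))
  expect_true(file.exists(file.path(d, "run_manifest.json")))
  bad <- run("simulate", "--scales", "NOPE", "--out-dir", d)
  expect_equal(attr(bad, "status"), 1L)
  expect_true(any(grepl("unknown scale", bad)))
})
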