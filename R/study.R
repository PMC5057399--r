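# End-to-end study reproduction: one config object drives simulation of the
# three scales' response matrices, the CAT-vs-NAT comparison grid, and the
# cutpoint reports. Every source of randomness is derived from the single
# config seed, so identical configs give byte-identical outputs.

.SCALES <- c("CADL", "ADL-male", "ADL-female")
# published reliabilities of the source instruments, which drive the strata
# count of the cutpoint procedure (both imply >= 4 strata; capped at 4)
.SCALE_ALPHA <- c("CADL" = 0.94, "ADL-male" = 0.93, "ADL-female" = 0.93)

#' Configure a simulation study
#'
#' Bundles and validates everything a full study run needs: which scales and
#' estimators, the cohort size, the master seed, the CAT stop-rule
#' parameters, the strata cap and the reliabilities feeding the strata count,
#' and where reports are written.
#'
#' @param scales subset of `"CADL"`, `"ADL-male"`, `"ADL-female"`.
#' @param methods subset of `"MAP"`, `"EAP"`, `"MLE"`.
#' @param nPersons cohort size (default 1000).
#' @param seed master integer seed; all simulation, first-item and sub-stream
#'   seeds derive from it.
#' @param minItems,reliabilityStop,resiStop,stopRule CAT stop rule, see
#'   [shouldStop()].
#' @param strataCap maximum number of strata (default 4).
#' @param scaleAlpha named reliabilities per scale for [deriveCutpoints()];
#'   defaults to the instruments' published values (0.94 CADL, 0.93 ADL).
#' @param gridStep cut-search resolution, see [bestCut()].
#' @param outDir directory for CSV reports (`NULL` = do not write).
#' @return a validated `StudyConfig` list.
#' @export
studyConfig <- function(scales = .SCALES, methods = c("MAP", "EAP", "MLE"),
                        nPersons = 1000L, seed = 1L, minItems = 7L,
                        reliabilityStop = 0.90, resiStop = 0.05,
                        stopRule = c("all", "any"), strataCap = 4L,
                        scaleAlpha = .SCALE_ALPHA, gridStep = 0.01,
                        outDir = NULL) {
  stopRule <- match.arg(stopRule)
  bad <- setdiff(scales, .SCALES)
  if (length(bad)) stop("unknown scale: ", paste(bad, collapse = ", "))
  bad <- setdiff(methods, .METHODS)
  if (length(bad)) stop("unknown method: ", paste(bad, collapse = ", "))
  if (length(scales) == 0L || length(methods) == 0L)
    stop("need at least one scale and one method")
  if (!.isCount(nPersons)) stop("nPersons must be a positive integer")
  if (!.isCount(minItems)) stop("minItems must be a positive integer")
  if (reliabilityStop <= 0 || reliabilityStop > 1) stop("reliabilityStop in (0, 1]")
  if (resiStop <= 0) stop("resiStop must be positive")
  if (!.isCount(strataCap)) stop("strataCap must be a positive integer")
  if (!all(scales %in% names(scaleAlpha)))
    stop("scaleAlpha must name every requested scale")
  structure(list(scales = scales, methods = methods,
                 nPersons = as.integer(nPersons), seed = as.integer(seed),
                 minItems = as.integer(minItems),
                 reliabilityStop = reliabilityStop, resiStop = resiStop,
                 stopRule = stopRule,
                 strataCap = as.integer(strataCap), scaleAlpha = scaleAlpha,
                 gridStep = gridStep, outDir = outDir),
            class = "StudyConfig")
}

# deterministic sub-seeds per purpose and scale, all derived from the master
.studySeeds <- function(config) {
  s <- .withSeed(config$seed, sample.int(2147483646L, 1L + 2L * length(.SCALES)))
  list(theta = s[1L],
       sim = stats::setNames(s[2:4], .SCALES),
       cat = stats::setNames(s[5:7], .SCALES))
}

#' Simulate the study's response matrices
#'
#' Draws one shared cohort of true person measures from N(0, 1) and generates
#' a complete response matrix per requested scale (the same persons answer
#' every scale, as in a multi-scale administration).
#'
#' @param config a [studyConfig()].
#' @return named list of [ResponseMatrix-class], one per scale.
#' @export
simulateStudyData <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  sub <- .studySeeds(config)
  thetas <- sampleThetas(config$nPersons, seed = sub$theta)
  out <- lapply(config$scales, function(sc)
    simulateMatrix(thetas, fixtureBank(sc), seed = sub$sim[[sc]]))
  stats::setNames(out, config$scales)
}

.writeManifest <- function(config, dir, extra = list()) {
  man <- c(list(package = "adlcat",
                version = as.character(utils::packageVersion("adlcat")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                scales = config$scales, methods = config$methods,
                n_persons = config$nPersons, seed = config$seed,
                min_items = config$minItems,
                reliability_stop = config$reliabilityStop,
                resi_stop = config$resiStop, stop_rule = config$stopRule,
                strata_cap = config$strataCap,
                scale_alpha = as.list(config$scaleAlpha),
                grid_step = config$gridStep),
           extra)
  jsonlite::write_json(man, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write the simulated response matrices to delimited text
#'
#' One `responses_<scale>.csv` per scale (with the generating `true_theta`
#' column) plus a `run_manifest.json` recording every seed and parameter.
#'
#' @param config a [studyConfig()] with `outDir` set.
#' @return invisible character vector of the files written.
#' @export
writeStudyMatrices <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  if (is.null(config$outDir)) stop("config$outDir must be set")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  data <- simulateStudyData(config)
  files <- vapply(names(data), function(sc) {
    f <- file.path(config$outDir, sprintf("responses_%s.csv", gsub("-", "_", sc)))
    writeResponseMatrix(data[[sc]], f)
    f
  }, "")
  .writeManifest(config, config$outDir)
  invisible(files)
}

#' Run the full CAT-vs-NAT comparison grid
#'
#' For every configured (scale, method) cell: full-bank scoring, an adaptive
#' session per person, and the comparison statistics of [compareCatNat()].
#' With `config$outDir` set, writes `comparison.csv` and the run manifest.
#'
#' @param config a [studyConfig()].
#' @param data optional pre-simulated list from [simulateStudyData()] (it is
#'   regenerated from the config seed when omitted).
#' @return `data.frame` with one row per (scale, method).
#' @export
runComparison <- function(config, data = NULL) {
  stopifnot(inherits(config, "StudyConfig"))
  sub <- .studySeeds(config)
  if (is.null(data)) data <- simulateStudyData(config)
  rows <- lapply(config$scales, function(sc)
    compareCatNat(data[[sc]], fixtureBank(sc), methods = config$methods,
                  seed = sub$cat[[sc]], minItems = config$minItems,
                  reliabilityStop = config$reliabilityStop,
                  resiStop = config$resiStop, stopRule = config$stopRule))
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "estimates") <- NULL; r }))
  rownames(out) <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(config$outDir, "comparison.csv"),
                     row.names = FALSE)
    .writeManifest(config, config$outDir)
  }
  out
}

#' Derive cutpoint reports for every configured scale and method
#'
#' Person measures feeding the procedure are the full-bank (NAT) estimates of
#' each method — the least noisy anchor; the strata count comes from the
#' configured per-scale reliabilities capped at `strataCap`. With
#' `config$outDir` set, writes `cutpoints.csv`.
#'
#' @inheritParams runComparison
#' @return `data.frame` with one row per (method, scale, stratum).
#' @export
runCutpointStudy <- function(config, data = NULL) {
  stopifnot(inherits(config, "StudyConfig"))
  if (is.null(data)) data <- simulateStudyData(config)
  rows <- list()
  for (mth in config$methods) for (sc in config$scales) {
    nat <- natEstimate(data[[sc]], fixtureBank(sc), mth)
    sr <- deriveCutpoints(nat$theta, alpha = config$scaleAlpha[[sc]],
                          cap = config$strataCap, gridStep = config$gridStep)
    rows[[paste(mth, sc)]] <- cbind(method = mth, scale = sc,
                                    as.data.frame(sr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(config$outDir, "cutpoints.csv"),
                     row.names = FALSE)
    .writeManifest(config, config$outDir)
  }
  out
}

#' Administer an adaptive test interactively
#'
#' Prompts one item at a time on `output`, reads integer categories from
#' `input` (re-prompting on out-of-range input), prints the provisional
#' measure, MSE (= SEM), `resi` and `corr` after every step, and finishes at
#' the stop rule with a final estimate and person-fit flags.
#'
#' @param bank an [ItemBank-class].
#' @param method estimator (default `"MAP"`, which is defined for any
#'   pattern).
#' @param input,output connections (defaults: stdin/stdout); pass a
#'   `textConnection` of scripted answers for non-interactive use.
#' @param seed optional seed for the random first item.
#' @param minItems,reliabilityStop,resiStop,stopRule stop rule, see
#'   [shouldStop()].
#' @return the finished [CatSession-class], invisibly.
#' @export
interactiveCat <- function(bank, method = c("MAP", "EAP", "MLE"),
                           input = stdin(), output = stdout(), seed = NULL,
                           minItems = 7L, reliabilityStop = 0.90,
                           resiStop = 0.05, stopRule = c("all", "any")) {
  method <- match.arg(method)
  stopRule <- match.arg(stopRule)
  stopifnot(is(bank, "ItemBank"))
  say <- function(...) writeLines(sprintf(...), con = output)
  mtop <- maxScore(bank)
  ids <- itemIds(bank)
  ask <- function(id, i) {
    repeat {
      say("Item %s (categories 0..%d): ", id, mtop[i])
      line <- readLines(input, n = 1L)
      if (length(line) == 0L) stop("input exhausted before the stop rule fired")
      x <- suppressWarnings(as.integer(trimws(line)))
      if (!is.na(x) && x >= 0L && x <= mtop[i]) return(x)
      say("  please answer an integer between 0 and %d", mtop[i])
    }
  }
  # replicate the engine loop so state can be echoed after every step
  comp <- .compileBank(bank)
  adm <- integer(0); xs <- integer(0); thetaTr <- numeric(0); semTr <- numeric(0)
  prov <- 0; est <- NULL; reason <- NA_character_
  .withSeed(seed, repeat {
    remaining <- setdiff(seq_along(comp), adm)
    if (length(remaining) == 0L) { reason <- "bank_exhausted"; break }
    i <- if (length(adm) == 0L) remaining[sample.int(length(remaining), 1L)]
    else remaining[which.max(vapply(remaining, function(j) .info(prov, comp[[j]]), 0))]
    x <- ask(ids[i], i)
    adm <- c(adm, i); xs <- c(xs, x)
    est <- .estimate(comp[adm], xs, method)
    prov <- est$theta
    thetaTr <- c(thetaTr, est$theta); semTr <- c(semTr, est$sem)
    resi <- .resiFrom(thetaTr); corr <- .corrFrom(thetaTr)
    say("  step %d: theta = %.3f, MSE = %.3f, resi = %s, corr = %s",
        length(adm), est$theta, est$sem,
        if (is.na(resi)) "NA" else sprintf("%.3f", resi),
        if (is.na(corr)) "NA" else sprintf("%.2f", corr))
    chk <- .stopCheck(length(adm), reliabilityFromSem(est$sem), resi,
                      minItems, reliabilityStop, resiStop, stopRule)
    if (chk$stop) { reason <- chk$reason; break }
  })
  session <- new("CatSession", bankName = bankName(bank), method = method,
                 administered = ids[adm], responses = xs,
                 thetaTrace = thetaTr, semTrace = semTr,
                 resi = .resiFrom(thetaTr), corr = .corrFrom(thetaTr),
                 stopReason = reason,
                 final = .asPersonEstimate(est, method, length(adm)))
  fit <- personFit(bank, xs, items = ids[adm], theta = est$theta)
  say("Done (%s): theta = %.3f, SEM = %.3f, outfit MNSQ = %.2f%s", reason,
      est$theta, est$sem, fit@outfitMnsq,
      if (length(fit@flagged))
        sprintf(", flagged*: %s", paste(fit@flagged, collapse = "; ")) else "")
  invisible(session)
}
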