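# Adaptive administration. Each step: pick the not-yet-administered item with
# maximal Fisher information at the provisional person measure (the first item
# is drawn at random from the pool), record the response, re-estimate, and
# test the compound stop rule. With the default conjunctive rule ("all"),
#
#   stop once n >= 7 items AND person reliability 1 - SEM^2 >= 0.90
#                          AND resi < 0.05,
#
# where resi is the mean absolute change of the provisional theta over the
# last three steps; a bank that cannot reach reliability 0.90 (such as the
# 23-item dichotomous CADL) is administered in full. The disjunctive variant
# ("any") stops once either the reliability or the resi criterion is met and
# yields much shorter tests. The bank running out always stops the session.

.stopCheck <- function(n, rel, resi, minItems, reliabilityStop, resiStop,
                       rule = "all") {
  if (n < minItems) return(list(stop = FALSE, reason = NA_character_))
  relOk <- rel >= reliabilityStop
  resiOk <- !is.na(resi) && resi < resiStop
  hit <- if (rule == "all") relOk && resiOk else relOk || resiOk
  if (!hit) return(list(stop = FALSE, reason = NA_character_))
  list(stop = TRUE, reason = if (relOk) "reliability" else "convergence")
}

.resiFrom <- function(thetaTr) {
  n <- length(thetaTr)
  if (n < 4L) return(NA_real_)
  mean(abs(diff(thetaTr[(n - 3L):n])))
}

.corrFrom <- function(thetaTr) {
  n <- length(thetaTr)
  if (n < 5L) return(NA_real_)
  last5 <- thetaTr[(n - 4L):n]
  if (stats::sd(last5) < 1e-12) return(0)  # perfectly flat trend
  stats::cor(last5, seq_len(5L))
}

#' Select the next CAT item by maximal information
#'
#' With nothing administered yet the first item is drawn uniformly at random
#' from the pool; afterwards the unadministered item with maximal Fisher
#' information at the provisional person measure is chosen (ties broken by
#' bank position).
#'
#' @param bank an [ItemBank-class].
#' @param provisionalTheta current provisional person measure.
#' @param administered character vector of already-administered item ids.
#' @param seed optional seed for the random first pick.
#' @return the selected item id.
#' @examples
#' selectNextItem(fixtureBank("CADL"), 0.5,
#'                administered = "FAI 6: local shopping")
#' @export
selectNextItem <- function(bank, provisionalTheta, administered = character(),
                           seed = NULL) {
  stopifnot(is(bank, "ItemBank"))
  ids <- itemIds(bank)
  bad <- setdiff(administered, ids)
  if (length(bad)) stop("unknown administered item id: ", bad[1L])
  remaining <- which(!ids %in% administered)
  if (length(remaining) == 0L) stop("item bank exhausted")
  if (length(administered) == 0L)
    return(ids[.withSeed(seed, remaining[sample.int(length(remaining), 1L)])])
  comp <- .compileBank(bank)
  infos <- vapply(remaining, function(i) .info(provisionalTheta, comp[[i]]), 0)
  ids[remaining[which.max(infos)]]
}

#' Evaluate the CAT stop rule on a session state
#'
#' @param session a [CatSession-class] (finished or in progress).
#' @param minItems minimum administered items before any stop (default 7).
#' @param reliabilityStop person-reliability threshold (default 0.90).
#' @param resiStop threshold on the mean of the last three absolute theta
#'   changes (default 0.05).
#' @param stopRule `"all"` (default) requires the reliability and the resi
#'   criterion jointly; `"any"` stops on whichever fires first.
#' @return a list with `stop` (logical) and `reason` (`"reliability"`,
#'   `"convergence"` or `NA`).
#' @export
shouldStop <- function(session, minItems = 7L, reliabilityStop = 0.90,
                       resiStop = 0.05, stopRule = c("all", "any")) {
  stopifnot(is(session, "CatSession"))
  stopRule <- match.arg(stopRule)
  n <- length(session@administered)
  if (n < 1L) stop("session has no administered items")
  rel <- reliabilityFromSem(session@semTrace[n])
  .stopCheck(n, rel, .resiFrom(session@thetaTrace), minItems,
             reliabilityStop, resiStop, stopRule)
}

#' Run one adaptive-testing session
#'
#' Administers items from `bank` adaptively until the stop rule fires (or the
#' bank is exhausted). Responses come from exactly one of three sources:
#' simulated from a known `trueTheta` via the model probabilities, looked up
#' in a pre-simulated complete response vector `responses`, or produced by a
#' `responder` callback (e.g. an interactive user).
#'
#' While an MLE session's pattern is still extreme (all categories at the
#' minimum or maximum), the provisional measure used for item selection is the
#' boundary value \eqn{\pm 4}.
#'
#' @param bank an [ItemBank-class].
#' @param method `"MLE"`, `"MAP"` or `"EAP"`.
#' @param trueTheta simulate responses at this true measure.
#' @param responses full-bank integer response vector aligned with the bank;
#'   the session reads the administered cells.
#' @param responder `function(item_id, item_index)` returning a category.
#' @param seed optional seed covering the random first item (and the response
#'   draws in `trueTheta` mode).
#' @param firstItem optional item id or index pinning the first item (for
#'   clinically deterministic sessions).
#' @param minItems,reliabilityStop,resiStop,stopRule stop-rule parameters,
#'   see [shouldStop()].
#' @return a finished [CatSession-class].
#' @examples
#' s <- runCat(fixtureBank("ADL-male"), "MAP", trueTheta = 0.3, seed = 7)
#' s
#' @export
runCat <- function(bank, method = c("MAP", "EAP", "MLE"), trueTheta = NULL,
                   responses = NULL, responder = NULL, seed = NULL,
                   firstItem = NULL, minItems = 7L, reliabilityStop = 0.90,
                   resiStop = 0.05, stopRule = c("all", "any")) {
  method <- match.arg(method)
  stopRule <- match.arg(stopRule)
  stopifnot(is(bank, "ItemBank"))
  nsrc <- (!is.null(trueTheta)) + (!is.null(responses)) + (!is.null(responder))
  if (nsrc != 1L)
    stop("provide exactly one of trueTheta, responses, responder")
  .withSeed(seed, .runCatImpl(bank, method, trueTheta, responses, responder,
                              firstItem, minItems, reliabilityStop, resiStop,
                              stopRule))
}

.runCatImpl <- function(bank, method, trueTheta, responses, responder,
                        firstItem = NULL, minItems = 7L,
                        reliabilityStop = 0.90, resiStop = 0.05,
                        stopRule = "all", comp = NULL, eapTabs = NULL) {
  if (is.null(comp)) comp <- .compileBank(bank)
  k <- length(comp)
  ids <- vapply(comp, `[[`, "", "id")
  if (!is.null(responses)) {
    responses <- as.integer(responses)
    if (length(responses) != k)
      stop("responses must cover the full bank (one cell per item)")
  }
  getResponse <- function(i) {
    x <- if (!is.null(trueTheta)) {
      ci <- comp[[i]]
      cum <- cumsum(.probs(trueTheta, ci))
      sum(stats::runif(1L) > cum[seq_len(ci$m)])
    } else if (!is.null(responses)) responses[i]
    else responder(ids[i], i)
    x <- as.integer(x)
    if (is.na(x) || x < 0L || x > comp[[i]]$m)
      stop(sprintf("invalid category for item \"%s\" (allowed 0..%d)",
                   ids[i], comp[[i]]$m))
    x
  }
  adm <- integer(0); xs <- integer(0)
  thetaTr <- numeric(0); semTr <- numeric(0)
  llEap <- numeric(length(.EAP_NODES))
  prov <- 0; est <- NULL; reason <- NA_character_
  repeat {
    remaining <- setdiff(seq_len(k), adm)
    if (length(remaining) == 0L) { reason <- "bank_exhausted"; break }
    i <- if (length(adm) == 0L) {
      if (!is.null(firstItem)) {
        fi <- if (is.character(firstItem)) match(firstItem, ids) else as.integer(firstItem)
        if (is.na(fi) || fi < 1L || fi > k) stop("unknown firstItem")
        fi
      } else remaining[sample.int(length(remaining), 1L)]
    } else {
      infos <- vapply(remaining, function(j) .info(prov, comp[[j]]), 0)
      remaining[which.max(infos)]
    }
    x <- getResponse(i)
    adm <- c(adm, i); xs <- c(xs, x)
    if (method == "EAP") {
      tab <- if (is.null(eapTabs)) .itemNodeLogProbs(comp[[i]]) else eapTabs[[i]]
      llEap <- llEap + tab[, x + 1L]
      est <- .eapFromLogLik(llEap)
    } else {
      est <- .estimate(comp[adm], xs, method)
    }
    prov <- est$theta
    thetaTr <- c(thetaTr, est$theta); semTr <- c(semTr, est$sem)
    chk <- .stopCheck(length(adm), reliabilityFromSem(est$sem),
                      .resiFrom(thetaTr), minItems, reliabilityStop, resiStop,
                      stopRule)
    if (chk$stop) { reason <- chk$reason; break }
  }
  if (is.null(est)) stop("empty bank")
  new("CatSession", bankName = bankName(bank), method = method,
      administered = ids[adm], responses = xs,
      thetaTrace = thetaTr, semTrace = semTr,
      resi = .resiFrom(thetaTr), corr = .corrFrom(thetaTr),
      stopReason = reason,
      final = .asPersonEstimate(est, method, length(adm)))
}

#' Run CAT for a whole cohort
#'
#' Administers one adaptive session per person. With
#' `responseSource = "matrix"` each administered response is read from the
#' complete pre-simulated matrix (so CAT and full-bank scoring see the same
#' realized responses); with `"fresh"` each response is drawn anew from the
#' model at the person's true theta, emulating a live adaptive administration
#' that is independent of the full-length one. One RNG stream, seeded once,
#' drives the random first items and any fresh draws.
#'
#' @param rm a complete [ResponseMatrix-class] (for `"fresh"` it must carry
#'   `trueThetas`).
#' @param bank the matching [ItemBank-class].
#' @param method estimator, see [runCat()].
#' @param seed optional integer seed.
#' @param responseSource `"matrix"` (default) or `"fresh"`.
#' @param ... stop-rule parameters passed to [runCat()].
#' @return list of [CatSession-class], one per person.
#' @seealso [cohortSummary()]
#' @export
runCatCohort <- function(rm, bank, method = c("MAP", "EAP", "MLE"),
                         seed = NULL, responseSource = c("matrix", "fresh"),
                         ...) {
  method <- match.arg(method)
  responseSource <- match.arg(responseSource)
  stopifnot(is(rm, "ResponseMatrix"), is(bank, "ItemBank"))
  r <- responses(rm)
  if (!identical(colnames(r), itemIds(bank)))
    stop("response matrix columns do not match the bank's items")
  comp <- .compileBank(bank)
  eapTabs <- if (method == "EAP") lapply(comp, .itemNodeLogProbs) else NULL
  if (responseSource == "fresh") {
    tt <- trueThetas(rm)
    if (length(tt) != nrow(r))
      stop("responseSource = \"fresh\" needs the matrix's trueThetas")
    return(.withSeed(seed, lapply(seq_len(nrow(r)), function(p)
      .runCatImpl(bank, method, tt[p], NULL, NULL, NULL, comp = comp,
                  eapTabs = eapTabs, ...))))
  }
  if (anyNA(r)) stop("cohort CAT needs a complete response matrix")
  .withSeed(seed, lapply(seq_len(nrow(r)), function(p)
    .runCatImpl(bank, method, NULL, r[p, ], NULL, NULL, comp = comp,
                eapTabs = eapTabs, ...)))
}

#' Summarize a list of CAT sessions
#'
#' @param sessions list of [CatSession-class] (e.g. from [runCatCohort()]).
#' @return `data.frame` with one row per person: final `theta`, `sem`,
#'   `n_items`, `stop_reason`, `at_boundary`.
#' @export
cohortSummary <- function(sessions) {
  data.frame(
    theta = vapply(sessions, function(s) s@final@theta, 0),
    sem = vapply(sessions, function(s) s@final@sem, 0),
    n_items = vapply(sessions, function(s) length(s@administered), 0L),
    stop_reason = vapply(sessions, function(s) s@stopReason, ""),
    at_boundary = vapply(sessions, function(s) s@final@atBoundary, TRUE)
  )
}

#' @rdname CatSession-class
#' @export
setMethod("administered", "CatSession", function(x) x@administered)

#' @rdname CatSession-class
#' @export
setMethod("thetaTrace", "CatSession", function(x) x@thetaTrace)

#' @rdname CatSession-class
#' @export
setMethod("semTrace", "CatSession", function(x) x@semTrace)

#' @rdname CatSession-class
#' @export
setMethod("stopReason", "CatSession", function(x) x@stopReason)

#' @rdname CatSession-class
#' @export
setMethod("finalEstimate", "CatSession", function(x) x@final)

#' @rdname CatSession-class
#' @export
setMethod("responses", "CatSession", function(x) x@responses)

setMethod("show", "CatSession", function(object) {
  n <- length(object@administered)
  cat(sprintf(
    "CatSession (%s on \"%s\"): %d items, stop = %s\n  theta = %.3f, SEM = %.3f, resi = %s, corr = %s\n",
    object@method, object@bankName, n, object@stopReason,
    object@final@theta, object@final@sem,
    if (is.na(object@resi)) "NA" else sprintf("%.3f", object@resi),
    if (is.na(object@corr)) "NA" else sprintf("%.2f", object@corr)))
  invisible(object)
})

#' Write a per-step session log
#'
#' One CSV row per administered item: step, item id, response, provisional
#' theta and SEM, the running `resi` and `corr` diagnostics, and the
#' standardized residual `z` of the response at the final measure (flagged
#' items are those with `|z| >= 2`).
#'
#' @param session a finished [CatSession-class].
#' @param bank the bank the session was run on.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSessionLog <- function(session, bank, path) {
  stopifnot(is(session, "CatSession"), is(bank, "ItemBank"))
  n <- length(session@administered)
  fit <- personFit(bank, session@responses, items = session@administered,
                   theta = session@final@theta)
  resi <- vapply(seq_len(n), function(t) .resiFrom(session@thetaTrace[1:t]), 0)
  corr <- vapply(seq_len(n), function(t) .corrFrom(session@thetaTrace[1:t]), 0)
  d <- data.frame(step = seq_len(n), item_id = session@administered,
                  response = session@responses,
                  theta = session@thetaTrace, sem = session@semTrace,
                  resi = resi, corr = corr,
                  z = unname(fit@zScores[session@administered]))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Person-fit statistics for a response pattern
#'
#' Standardized residuals \eqn{z_i = (x_i - E_i)/\sqrt{W_i}} (with \eqn{E_i}
#' the model-expected score and \eqn{W_i} the score variance at `theta`), the
#' unweighted outfit mean-square \eqn{\mathrm{mean}(z_i^2)}, the
#' information-weighted infit mean-square
#' \eqn{\sum_i (x_i - E_i)^2 / \sum_i W_i}, and the ids of items flagged as
#' unexpected responses (\eqn{|z_i| \ge 2.0}). Values near 1 indicate
#' model-consistent responding; outfit of 2 or more suggests a distorted or
#' careless pattern.
#'
#' Items whose score variance is numerically zero at `theta` (degenerate at an
#' extreme measure) are excluded from the mean squares with a warning.
#'
#' @param bank an [ItemBank-class].
#' @param x observed categories aligned with `items`.
#' @param items item ids or indices answered; defaults to the whole bank.
#' @param theta the person measure the residuals are taken at.
#' @return a [PersonFit-class].
#' @export
personFit <- function(bank, x, items = NULL, theta) {
  stopifnot(is(bank, "ItemBank"))
  if (length(theta) != 1L || !is.finite(theta)) stop("theta must be finite")
  if (is.null(items)) items <- seq_len(nItems(bank))
  if (length(x) != length(items) || length(x) < 1L)
    stop("need at least one response, aligned with items")
  comp <- .resolveItems(bank, items)
  x <- as.integer(x)
  e <- w <- numeric(length(comp))
  for (j in seq_along(comp)) {
    if (x[j] < 0L || x[j] > comp[[j]]$m)
      stop(sprintf("response %d out of range for item \"%s\"", x[j], comp[[j]]$id))
    mo <- .scoreMoments(theta, comp[[j]])
    e[j] <- mo$e; w[j] <- mo$w
  }
  ok <- w > 1e-12
  if (!all(ok))
    warning(sprintf("%d degenerate item(s) excluded from mean-square statistics",
                    sum(!ok)))
  if (!any(ok)) stop("all items degenerate at this theta; no fit statistics")
  z <- (x[ok] - e[ok]) / sqrt(w[ok])
  ids <- vapply(comp, `[[`, "", "id")
  names(z) <- ids[ok]
  new("PersonFit",
      infitMnsq = sum((x[ok] - e[ok])^2) / sum(w[ok]),
      outfitMnsq = mean(z^2),
      zScores = z, flagged = names(z)[abs(z) >= 2.0])
}

setMethod("show", "PersonFit", function(object) {
  cat(sprintf("PersonFit: infit MNSQ = %.2f, outfit MNSQ = %.2f, %d flagged (|z| >= 2)\n",
              object@infitMnsq, object@outfitMnsq, length(object@flagged)))
  invisible(object)
})
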