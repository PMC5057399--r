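#' Construct an item bank
#'
#' @param name scale name.
#' @param items `data.frame` with columns `item_id`, `model` (one of
#'   `"rasch_dichotomous"`, `"gpcm"`), `discrimination`, and `step_1` ..
#'   `step_3` (trailing steps `NA`). Rasch items must have discrimination 1 and
#'   a single step (the item difficulty delta).
#' @return a validated [ItemBank-class] object; row order is preserved.
#' @examples
#' toy <- itemBank("toy", data.frame(
#'   item_id = c("i1", "i2"), model = "rasch_dichotomous",
#'   discrimination = 1, step_1 = c(-1, 1), step_2 = NA, step_3 = NA))
#' nItems(toy)
#' @export
itemBank <- function(name, items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  for (col in c("step_1", "step_2", "step_3"))
    if (!col %in% names(items)) items[[col]] <- NA_real_
  items$item_id <- as.character(items$item_id)
  items$model <- as.character(items$model)
  items$discrimination <- as.numeric(items$discrimination)
  for (col in c("step_1", "step_2", "step_3"))
    items[[col]] <- as.numeric(items[[col]])
  rownames(items) <- NULL
  new("ItemBank", name = as.character(name), items = items)
}

#' @rdname ItemBank-class
#' @export
setMethod("bankName", "ItemBank", function(x) x@name)

#' @rdname ItemBank-class
#' @export
setMethod("nItems", "ItemBank", function(x) nrow(x@items))

#' @rdname ItemBank-class
#' @export
setMethod("itemIds", "ItemBank", function(x) x@items$item_id)

#' @rdname ItemBank-class
#' @export
setMethod("itemParameters", "ItemBank", function(x) x@items)

#' @describeIn ItemBank-class number of step difficulties of each item, i.e.
#'   the top score category (scores run 0..m).
#' @export
setMethod("maxScore", "ItemBank", function(x) {
  steps <- as.matrix(x@items[, c("step_1", "step_2", "step_3")])
  as.integer(rowSums(!is.na(steps)))
})

setMethod("show", "ItemBank", function(object) {
  m <- maxScore(object)
  cat(sprintf("ItemBank \"%s\": %d items (%s)\n", object@name, nItems(object),
              paste(sprintf("%d with %d categories", tabulate(m, max(m)),
                            seq_len(max(m)) + 1L)[tabulate(m, max(m)) > 0],
                    collapse = ", ")))
  cat(sprintf("  models: %s\n",
              paste(unique(object@items$model), collapse = ", ")))
  invisible(object)
})

# ---- delimited-text I/O ------------------------------------------------------

#' Read and write item banks as delimited text
#'
#' The external format is a UTF-8 CSV with header
#' `item_id,model,discrimination,step_1,step_2,step_3`; absent trailing steps
#' are empty cells. `writeBank()` round-trips all parameter values exactly
#' (they are written with full precision).
#'
#' @param path file to read or write.
#' @param name bank name to attach on read (defaults to the file base name).
#' @param sep field separator, `","` by default.
#' @return `loadBank()` a validated [ItemBank-class]; `writeBank()` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeBank(fixtureBank("CADL"), f)
#' identical(itemParameters(loadBank(f, name = "CADL")),
#'           itemParameters(fixtureBank("CADL")))
#' @export
loadBank <- function(path, name = NULL, sep = ",") {
  if (!file.exists(path)) stop("item-bank file does not exist: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, fill = TRUE)
  req <- c("item_id", "model", "discrimination", "step_1")
  if (nrow(raw) == 0L) stop("item-bank file is empty: ", path)
  if (!all(req %in% names(raw)))
    stop("item-bank file must have columns item_id, model, discrimination, step_1..step_3")
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "" | is.na(v), NA, v)))
  for (col in c("step_2", "step_3")) if (!col %in% names(raw)) raw[[col]] <- ""
  disc <- num(raw$discrimination)
  bad <- which(is.na(disc) | !nzchar(raw$item_id))
  if (length(bad))
    stop(sprintf("malformed item-bank row %d (item_id/discrimination)", bad[1L]))
  items <- data.frame(item_id = raw$item_id, model = raw$model,
                      discrimination = disc,
                      step_1 = num(raw$step_1), step_2 = num(raw$step_2),
                      step_3 = num(raw$step_3), stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  itemBank(name, items)
}

#' @rdname loadBank
#' @param bank an [ItemBank-class].
#' @export
writeBank <- function(bank, path, sep = ",") {
  stopifnot(is(bank, "ItemBank"))
  it <- bank@items
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  out <- data.frame(item_id = it$item_id, model = it$model,
                    discrimination = fmt(it$discrimination),
                    step_1 = fmt(it$step_1), step_2 = fmt(it$step_2),
                    step_3 = fmt(it$step_3), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged ADL/CADL item banks
#'
#' Three calibrated banks ship with the package: `"CADL"`, the 23-item
#' comprehensive ADL scale (Barthel Index + Frenchay Activities Index items)
#' under the dichotomous Rasch model, and `"ADL-male"` / `"ADL-female"`, the
#' 34-item GPCM ADL scale whose items 6-11 carry sex-specific discrimination
#' and first-step parameters.
#'
#' @param name `"CADL"`, `"ADL-male"` or `"ADL-female"`.
#' @return the requested [ItemBank-class].
#' @examples
#' fixtureBank("ADL-male")
#' @export
fixtureBank <- function(name = c("CADL", "ADL-male", "ADL-female")) {
  name <- match.arg(name)
  file <- c("CADL" = "bank_cadl.csv", "ADL-male" = "bank_adl_male.csv",
            "ADL-female" = "bank_adl_female.csv")[[name]]
  path <- system.file("extdata", file, package = "adlcat", mustWork = TRUE)
  loadBank(path, name = name)
}

# ---- internal compiled representation ---------------------------------------

# Per-item precomputation used by all numerical kernels:
#   x = 0:m score categories, s = cumulative step difficulties (s[1] = 0 for
#   the empty sum), so log P(x) = a*(x*theta - s[x+1]) - logZ(theta).
.compileBank <- function(bank) {
  it <- bank@items
  steps <- as.matrix(it[, c("step_1", "step_2", "step_3")])
  lapply(seq_len(nrow(it)), function(i) {
    b <- unname(steps[i, !is.na(steps[i, ])])
    list(id = it$item_id[i], a = it$discrimination[i], m = length(b),
         x = 0:length(b), s = c(0, cumsum(b)), b = b)
  })
}

.compileItem <- function(item_id, model, discrimination, steps) {
  list(id = item_id, a = discrimination, m = length(steps),
       x = 0:length(steps), s = c(0, cumsum(steps)), b = unname(steps))
}
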