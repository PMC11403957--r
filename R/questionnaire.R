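# Questionnaire structure: items, subscales, reverse scoring, and response I/O.

#' Construct and validate a questionnaire specification
#'
#' A `ccmq_spec` describes the structure of a Likert questionnaire: which
#' items belong to which subscale, which items are reverse scored within a
#' subscale, and the Likert bounds. The bundled default describes the 60-item
#' adult CCMQ with nine subscales (GTC, QDC, YaDC, YiDC, PDC, DHC, BSC, QSC,
#' SDC) of 6--8 items each; an item may belong to more than one subscale
#' (e.g. item 2 sits in both GTC and QDC).
#'
#' @param subscales named list of integer item-id vectors, one per subscale.
#' @param reverse named list (same names) of item ids reverse scored within
#'   that subscale; must be subsets of the corresponding member sets.
#' @param labels optional named character vector of item text labels, names
#'   are item ids.
#' @param likert_min,likert_max integer Likert bounds (default 1 and 5).
#' @param inferred optional named logical: subscales whose membership is
#'   reconstructed rather than documented.
#' @param min_size,max_size allowed subscale sizes (default 6 and 8).
#' @return an object of class `ccmq_spec`.
#' @export
ccmq_spec <- function(subscales, reverse = NULL, labels = NULL,
                      likert_min = 1L, likert_max = 5L,
                      inferred = NULL, min_size = 6L, max_size = 8L) {
  if (!is.list(subscales) || is.null(names(subscales)) ||
      any(!nzchar(names(subscales)))) {
    stop("subscales must be a named list of item-id vectors")
  }
  subscales <- lapply(subscales, function(x) as.integer(x))
  if (is.null(reverse)) reverse <- setNames(vector("list", length(subscales)),
                                            names(subscales))
  for (nm in names(subscales)) {
    mem <- subscales[[nm]]
    if (anyNA(mem) || anyDuplicated(mem)) {
      stop(sprintf("subscale %s: members must be unique non-missing ids", nm))
    }
    if (length(mem) < min_size || length(mem) > max_size) {
      stop(sprintf("subscale %s has %d items; expected between %d and %d",
                   nm, length(mem), min_size, max_size))
    }
    rev <- as.integer(reverse[[nm]] %||% integer(0))
    if (!all(rev %in% mem)) {
      stop(sprintf("subscale %s: reverse items not members: %s",
                   nm, paste(setdiff(rev, mem), collapse = ", ")))
    }
    reverse[[nm]] <- rev
  }
  likert_min <- as.integer(likert_min); likert_max <- as.integer(likert_max)
  if (is.na(likert_min) || is.na(likert_max) || likert_min >= likert_max) {
    stop("likert_min must be an integer strictly below likert_max")
  }
  items <- sort(unique(unlist(subscales)))
  lab <- setNames(sprintf("item %d", items), as.character(items))
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% names(lab)]
    lab[names(labels)] <- unlist(labels)
  }
  if (is.null(inferred)) {
    inferred <- setNames(rep(FALSE, length(subscales)), names(subscales))
  }
  structure(list(items = items, labels = lab, subscales = subscales,
                 reverse = reverse, inferred = inferred,
                 likert_min = likert_min, likert_max = likert_max),
            class = "ccmq_spec")
}

#' Load a questionnaire specification from JSON
#'
#' Reads a spec file with top-level keys `likert`, `subscales` (each entry
#' `name` / `items` / `reverse` / `inferred`) and optional `labels`. With no
#' path, loads the bundled CCMQ fixture, whose subscale memberships are
#' reconstructed from the largest published item combinations; subscales
#' whose full membership is not directly documented carry `inferred = TRUE`.
#'
#' @param path path to a spec JSON file, or `NULL` for the bundled default.
#' @return a validated [ccmq_spec] object.
#' @export
load_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ccmq_spec.json", package = "ccmqrapid")
  }
  if (!file.exists(path)) stop("spec file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("spec parse error: ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("likert", "subscales")) {
    if (is.null(raw[[key]])) stop("spec parse error: missing field '", key, "'")
  }
  subs <- lapply(raw$subscales, function(s) {
    if (is.null(s$name) || is.null(s$items)) {
      stop("spec parse error: subscale entry needs 'name' and 'items'")
    }
    s
  })
  subscales <- setNames(lapply(subs, function(s) unlist(s$items)),
                        vapply(subs, function(s) s$name, ""))
  reverse <- setNames(lapply(subs, function(s) unlist(s$reverse) %||% integer(0)),
                      names(subscales))
  inferred <- setNames(vapply(subs, function(s) isTRUE(s$inferred), TRUE),
                       names(subscales))
  labels <- if (!is.null(raw$labels)) unlist(raw$labels)
  ccmq_spec(subscales, reverse, labels = labels,
            likert_min = raw$likert$min %||% 1L,
            likert_max = raw$likert$max %||% 5L,
            inferred = inferred)
}

#' @export
print.ccmq_spec <- function(x, ...) {
  cat(sprintf("CCMQ questionnaire spec: %d items, %d subscales, Likert %d-%d\n",
              length(x$items), length(x$subscales), x$likert_min, x$likert_max))
  for (nm in names(x$subscales)) {
    cat(sprintf("  %-4s (%d items%s): %s%s\n", nm, length(x$subscales[[nm]]),
                if (length(x$reverse[[nm]])) paste0(", ",
                  length(x$reverse[[nm]]), " reverse") else "",
                paste(x$subscales[[nm]], collapse = " "),
                if (isTRUE(x$inferred[[nm]])) "  [inferred]" else ""))
  }
  invisible(x)
}

#' Construct a validated response matrix
#'
#' @param values integer matrix (respondents x items) of Likert responses.
#' @param spec a [ccmq_spec].
#' @param respondent_ids optional vector of row identifiers.
#' @return an integer matrix of class `ccmq_responses` with item-id column
#'   names and respondent-id row names.
#' @export
response_matrix <- function(values, spec, respondent_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- as.character(spec$items)
  want <- as.character(spec$items)
  if (!setequal(colnames(values), want) || ncol(values) != length(want)) {
    stop("response columns do not match spec item ids")
  }
  values <- values[, want, drop = FALSE]
  bad <- which(!is.finite(values) | values != round(values) |
                 values < spec$likert_min | values > spec$likert_max,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or out-of-range response at row %d, item %s (value %s)",
      bad[1, 1], colnames(values)[bad[1, 2]], values[bad[1, 1], bad[1, 2]]))
  }
  storage.mode(values) <- "integer"
  if (is.null(respondent_ids)) respondent_ids <- seq_len(nrow(values))
  rownames(values) <- as.character(respondent_ids)
  class(values) <- c("ccmq_responses", class(values))
  values
}

#' Read a respondent-by-item response CSV
#'
#' Expects a header of item ids (optionally preceded by a `respondent_id`
#' column) and one integer row per respondent. Rows with missing cells are
#' handled per `missing`: `"drop_row"` (default) removes them and records the
#' count in the `"n_discarded"` attribute — mirroring survey practice of
#' discarding invalid questionnaires — while `"error"` aborts.
#'
#' @param path CSV path.
#' @param spec a [ccmq_spec] the header must match.
#' @param missing missing-data policy, `"drop_row"` or `"error"`.
#' @return a `ccmq_responses` matrix with attribute `n_discarded`.
#' @export
load_responses <- function(path, spec, missing = c("drop_row", "error")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  ids <- NULL
  if (ncol(df) > 0 && colnames(df)[1] == "respondent_id") {
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  if (!setequal(colnames(df), as.character(spec$items))) {
    stop("header mismatch with spec: expected item ids ",
         paste(utils::head(spec$items, 3), collapse = ","), ",...")
  }
  suppressWarnings(vals <- vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) vals <- matrix(vals, 1, dimnames = list(NULL, colnames(df)))
  incomplete <- apply(vals, 1, anyNA)
  n_discarded <- sum(incomplete)
  if (n_discarded > 0) {
    if (missing == "error") {
      loc <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("missing/non-numeric value at row %d, item %s",
                   loc[1], colnames(vals)[loc[2]]))
    }
    message(sprintf("%d row%s discarded (missing or non-numeric cells)",
                    n_discarded, if (n_discarded == 1) "" else "s"))
    vals <- vals[!incomplete, , drop = FALSE]
    if (!is.null(ids)) ids <- ids[!incomplete]
  }
  out <- response_matrix(vals, spec, respondent_ids = ids)
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Write responses to CSV (numeric round-trip with [load_responses])
#'
#' @param responses a `ccmq_responses` matrix.
#' @param path output path.
#' @param respondent_id include the respondent-id column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, respondent_id = TRUE) {
  df <- as.data.frame(unclass(responses))
  colnames(df) <- colnames(responses)
  if (respondent_id) {
    df <- cbind(respondent_id = rownames(responses), df)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
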