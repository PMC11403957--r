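# Subscale scoring and nine-type body constitution classification.
#
# Raw Likert responses are reverse-adjusted where the subscale demands it,
# summed, and rescaled to a 0-100 "converted score":
#   converted = (sum(raw) - n_items) / (n_items * 4) * 100.
# Classification uses the published criteria: Gentleness (GTC) requires a
# converted GTC score of at least 60 together with all eight biased
# constitutions below 30; a biased constitution is "present" above 40 and a
# "tendency" between 30 and 40 inclusive.

#' Names of the nine body constitution types
#' @return character vector, GTC first followed by the eight biased types.
#' @export
bc_types <- function() c("GTC", "QDC", "YaDC", "YiDC", "PDC",
                         "DHC", "BSC", "QSC", "SDC")

#' Names of the eight biased constitution types
#' @return character vector.
#' @export
biased_types <- function() setdiff(bc_types(), "GTC")

#' Classification boundary constants
#'
#' All classification cutoffs live here so alternative boundary readings are
#' a one-line change. Defaults: GTC needs `converted >= gtc_min` (inclusive)
#' with every biased score strictly below `biased_low`; a biased type is
#' present strictly above `present_above` and a tendency on the closed
#' interval `[tendency_min, tendency_max]`.
#'
#' @param gtc_min minimum GTC converted score (default 60).
#' @param biased_low biased scores must be strictly below this for GTC
#'   (default 30).
#' @param present_above biased presence threshold, strict (default 40).
#' @param tendency_min,tendency_max closed tendency interval (defaults 30, 40).
#' @return a named list of boundaries.
#' @export
bc_criteria <- function(gtc_min = 60, biased_low = 30, present_above = 40,
                        tendency_min = 30, tendency_max = 40) {
  list(gtc_min = gtc_min, biased_low = biased_low,
       present_above = present_above,
       tendency_min = tendency_min, tendency_max = tendency_max)
}

#' Reverse-adjust a raw Likert response
#'
#' @param raw integer vector of raw responses in `[likert_min, likert_max]`.
#' @param reverse logical (recycled): reverse-scored item?
#' @param likert_min,likert_max Likert bounds.
#' @return `likert_min + likert_max - raw` where `reverse`, else `raw`
#'   (with the default 1--5 bounds: `6 - raw`).
#' @export
adjust_raw <- function(raw, reverse, likert_min = 1L, likert_max = 5L) {
  if (any(!is.finite(raw) | raw != round(raw) |
            raw < likert_min | raw > likert_max)) {
    stop(sprintf("raw response out of range [%d, %d]", likert_min, likert_max))
  }
  ifelse(rep_len(as.logical(reverse), length(raw)),
         likert_min + likert_max - raw, raw)
}

#' Converted score for one respondent on one subscale
#'
#' Applies reverse adjustment, sums, and rescales to 0--100:
#' `((sum - n) / (4 n)) * 100` for n member items on a 1--5 scale.
#'
#' @param raws named (by item id) or member-ordered vector of raw responses.
#' @param members integer item ids of the subscale.
#' @param reverse integer ids of reverse-scored members.
#' @param likert_min,likert_max Likert bounds.
#' @return converted score in `[0, 100]`.
#' @export
converted_score <- function(raws, members, reverse = integer(0),
                            likert_min = 1L, likert_max = 5L) {
  if (!is.null(names(raws))) {
    miss <- setdiff(as.character(members), names(raws))
    if (length(miss)) stop("missing response for item(s): ",
                           paste(miss, collapse = ", "))
    raws <- raws[as.character(members)]
  } else if (length(raws) != length(members)) {
    stop("need exactly one response per member item")
  }
  adj <- adjust_raw(raws, members %in% reverse, likert_min, likert_max)
  n <- length(members)
  span <- likert_max - likert_min
  (sum(adj) - n * likert_min) / (n * span) * 100
}

#' Score all respondents on all subscales
#'
#' Vectorized equivalent of calling [converted_score] per respondent and
#' subscale. Raw (reverse-adjusted) sums are attached as the `"raw_sums"`
#' attribute.
#'
#' @param responses a `ccmq_responses` matrix (see [load_responses]).
#' @param spec a [ccmq_spec].
#' @return data frame with `respondent_id` and one converted-score column per
#'   subscale; attribute `raw_sums` holds the matching integer sums.
#' @export
score_all <- function(responses, spec) {
  x <- unclass(responses)
  out <- data.frame(respondent_id = rownames(responses) %||%
                      seq_len(nrow(x)))[seq_len(nrow(x)), , drop = FALSE]
  raw_sums <- matrix(0L, nrow(x), length(spec$subscales),
                     dimnames = list(NULL, names(spec$subscales)))
  span <- spec$likert_max - spec$likert_min
  for (nm in names(spec$subscales)) {
    members <- spec$subscales[[nm]]
    cols <- x[, as.character(members), drop = FALSE]
    rev <- members %in% spec$reverse[[nm]]
    if (any(rev)) {
      cols[, rev] <- spec$likert_min + spec$likert_max - cols[, rev]
    }
    s <- as.integer(rowSums(cols))
    raw_sums[, nm] <- s
    n <- length(members)
    out[[nm]] <- (s - n * spec$likert_min) / (n * span) * 100
  }
  rownames(out) <- NULL
  attr(out, "raw_sums") <- raw_sums
  out
}

#' Classify respondents into the nine constitution types
#'
#' GTC is `"present"` iff its converted score meets the GTC minimum and every
#' biased converted score is strictly below the biased-low bound, else
#' `"absent"`. Each biased type is `"present"` strictly above the presence
#' bound, `"tendency"` on the closed tendency interval, else `"absent"`.
#' Several biased types can be present simultaneously.
#'
#' @param scores data frame from [score_all] (converted scores, one column
#'   per subscale).
#' @param criteria boundary constants, see [bc_criteria].
#' @return data frame with `respondent_id` and one status column per type.
#' @export
classify_bc <- function(scores, criteria = bc_criteria()) {
  miss <- setdiff(bc_types(), colnames(scores))
  if (length(miss)) stop("missing subscale score(s): ",
                         paste(miss, collapse = ", "))
  biased <- as.matrix(scores[, biased_types(), drop = FALSE])
  if (anyNA(biased) || anyNA(scores$GTC)) stop("missing subscale score value")
  out <- data.frame(respondent_id = scores$respondent_id %||%
                      seq_len(nrow(scores)))
  out$GTC <- ifelse(scores$GTC >= criteria$gtc_min &
                      apply(biased < criteria$biased_low, 1, all),
                    "present", "absent")
  for (nm in biased_types()) {
    s <- scores[[nm]]
    out[[nm]] <- ifelse(s > criteria$present_above, "present",
                        ifelse(s >= criteria$tendency_min &
                                 s <= criteria$tendency_max,
                               "tendency", "absent"))
  }
  out
}

#' Per-type prevalence summary
#'
#' Because respondents can exhibit several biased constitutions at once the
#' percentages are multi-label and need not sum to 100. Two variants are
#' reported side by side: strictly "present", and "present or tendency".
#'
#' @param classification data frame from [classify_bc].
#' @return data frame with columns `bc`, `n`, `present_pct`,
#'   `present_or_tendency_pct` (percentages on 0--100).
#' @export
prevalence_summary <- function(classification) {
  if (is.null(nrow(classification)) || nrow(classification) == 0) {
    stop("empty classification list")
  }
  n <- nrow(classification)
  rows <- lapply(bc_types(), function(nm) {
    st <- classification[[nm]]
    data.frame(bc = nm, n = n,
               present_pct = 100 * mean(st == "present"),
               present_or_tendency_pct =
                 100 * mean(st %in% c("present", "tendency")))
  })
  do.call(rbind, rows)
}
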