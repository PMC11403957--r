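# Synthetic Likert response generator.
#
# A graded-response-style model: each respondent draws one latent trait per
# subscale from a multivariate normal (biased traits mutually positively
# correlated, the Gentleness trait negatively correlated with them); each
# item loads on exactly one "primary" subscale trait with a discrimination
# coefficient, Gaussian noise is added, and the continuous value is cut at
# four increasing thresholds into the 1-5 Likert response. Items that are
# reverse scored within their primary subscale load negatively, so raw
# responses anti-correlate with the trait and reverse scoring re-aligns
# them. Per-subscale "planted" core items receive elevated discrimination
# and are the ground truth for item-selection recovery checks. Threshold
# placement puts most mass on low response categories, giving the
# left-leaning converted-score distributions typical of constitution
# surveys.

# Primary generating subscale per item: each item is driven by one latent
# trait even when it is scored under several subscales (double-membership
# items are driven by their biased subscale; GTC keeps 1, 53 and the
# reverse-keyed 54).
default_primary_map <- function() {
  list(GTC = c(1, 53, 54),
       QDC = c(2, 3, 4, 5, 6, 7, 22, 26),
       YaDC = c(17, 18, 19, 21, 52, 55),
       YiDC = c(16, 20, 29, 35, 38, 44, 46, 57),
       PDC = c(13, 15, 28, 42, 49, 50, 51, 58),
       DHC = c(39, 41, 48, 56, 59, 60),
       BSC = c(27, 33, 36, 37, 40, 43, 45),
       QSC = c(8, 9, 10, 11, 12, 14, 47),
       SDC = c(23, 24, 25, 30, 31, 32, 34))
}

# Latent trait means frozen from a one-off bisection calibration of the
# default generator toward survey-realistic presence rates (biased types
# roughly 9-36%, Gentleness ~14%); see the methods vignette.
default_subscale_means <- function() {
  c(GTC = 0, QDC = 0.71875, YaDC = 0.546875, YiDC = 0.15625,
    PDC = 0.34375, DHC = 0.40625, BSC = 0.3125, QSC = 0.4375,
    SDC = -0.375)
}

#' Simulation configuration
#'
#' @param n number of respondents.
#' @param spec a [ccmq_spec] (default: bundled CCMQ).
#' @param seed master seed recorded into all outputs.
#' @param subscale_means,subscale_sds named latent trait means / sds per
#'   subscale (defaults: calibrated means, unit sds).
#' @param inter_subscale_corr 9 x 9 latent correlation matrix (default:
#'   0.5 among biased types, -0.6 between GTC and each biased type).
#' @param discrimination base item discrimination (default 0.7).
#' @param planted named list of per-subscale core item ids receiving
#'   `planted_discrimination` (default: two core items per biased
#'   subscale; none for GTC, whose determination compounds all nine
#'   scores).
#' @param planted_discrimination elevated loading for planted items
#'   (default 1.4).
#' @param thresholds four strictly increasing cutpoints mapping the
#'   continuous item value to Likert 1-5 (default `c(0, 0.9, 1.8, 2.7)`).
#' @param noise_sd item-level Gaussian noise sd (default 1).
#' @param primary optional item-to-subscale generating map.
#' @return an object of class `ccmq_simconfig`.
#' @export
sim_config <- function(n = 2000L, spec = load_spec(), seed = 1L,
                       subscale_means = default_subscale_means(),
                       subscale_sds = NULL,
                       inter_subscale_corr = NULL,
                       discrimination = 0.7,
                       planted = NULL,
                       planted_discrimination = 1.4,
                       thresholds = c(0, 0.9, 1.8, 2.7),
                       noise_sd = 1,
                       primary = NULL) {
  subs <- names(spec$subscales)
  subscale_sds <- subscale_sds %||% stats::setNames(rep(1, length(subs)), subs)
  if (is.null(inter_subscale_corr)) {
    C <- matrix(0.5, length(subs), length(subs), dimnames = list(subs, subs))
    C["GTC", ] <- C[, "GTC"] <- -0.6
    diag(C) <- 1
    inter_subscale_corr <- C
  }
  if (!isTRUE(all.equal(inter_subscale_corr, t(inter_subscale_corr))) ||
      any(abs(diag(inter_subscale_corr) - 1) > 1e-8) ||
      min(eigen(inter_subscale_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("inter_subscale_corr is not a valid correlation matrix")
  }
  if (is.null(planted)) {
    # planted pairs are primary-own items, so one subscale's core items do
    # not inflate another subscale's loadings via double membership; GTC
    # has none because its determination is a compound of all nine
    # subscale scores, not of its own latent trait
    planted <- list(QDC = c(3, 6), YaDC = c(19, 52),
                    YiDC = c(20, 35), PDC = c(49, 50), DHC = c(39, 59),
                    BSC = c(40, 43), QSC = c(9, 14), SDC = c(24, 31))
    planted <- planted[subs[subs %in% names(planted)]]
  }
  for (nm in names(planted)) {
    bad <- setdiff(planted[[nm]], spec$subscales[[nm]])
    if (length(bad)) {
      stop(sprintf("planted item(s) %s outside subscale %s",
                   paste(bad, collapse = ", "), nm))
    }
  }
  primary <- primary %||% default_primary_map()
  pm <- stats::setNames(rep(NA_character_, length(spec$items)),
                        spec$items)
  for (nm in names(primary)) pm[as.character(primary[[nm]])] <- nm
  if (anyNA(pm)) stop("primary map does not cover all items")
  if (any(!unlist(lapply(names(primary), function(nm)
    primary[[nm]] %in% spec$subscales[[nm]])))) {
    stop("primary map assigns an item to a subscale it does not belong to")
  }
  if (discrimination < 0 || planted_discrimination < 0) {
    stop("discriminations must be non-negative")
  }
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be four strictly increasing cutpoints")
  }
  planted_ids <- unlist(planted, use.names = FALSE)
  items <- data.frame(
    item = spec$items,
    primary = unname(pm),
    # reverse-keyed within the primary subscale => negative loading
    sign = ifelse(vapply(spec$items, function(i)
      i %in% spec$reverse[[pm[[as.character(i)]]]], TRUE), -1, 1),
    discrimination = ifelse(spec$items %in% planted_ids,
                            planted_discrimination, discrimination))
  structure(list(n = as.integer(n), spec = spec, seed = as.integer(seed),
                 subscale_means = subscale_means[subs],
                 subscale_sds = subscale_sds[subs],
                 inter_subscale_corr = inter_subscale_corr[subs, subs],
                 items = items, planted = planted,
                 thresholds = thresholds, noise_sd = noise_sd),
            class = "ccmq_simconfig")
}

#' Simulate Likert responses with known structure
#'
#' @param config a [sim_config].
#' @return list with `responses` (a `ccmq_responses` matrix) and `truth`
#'   (latent traits, planted core items, generating parameters, seed).
#'   Bit-reproducible given the config seed.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "ccmq_simconfig"))
  set.seed(config$seed)
  subs <- names(config$subscale_means)
  Sigma <- diag(config$subscale_sds) %*% config$inter_subscale_corr %*%
    diag(config$subscale_sds)
  L <- MASS::mvrnorm(config$n, mu = config$subscale_means, Sigma = Sigma)
  colnames(L) <- subs
  it <- config$items
  cont <- L[, it$primary, drop = FALSE] *
    rep(it$sign * it$discrimination, each = config$n) +
    matrix(stats::rnorm(config$n * nrow(it), 0, config$noise_sd), config$n)
  resp <- matrix(1L, config$n, nrow(it))
  for (thr in config$thresholds) resp <- resp + (cont > thr)
  colnames(resp) <- as.character(it$item)
  responses <- response_matrix(resp, config$spec)
  truth <- list(latents = L, planted = config$planted,
                items = it, seed = config$seed,
                subscale_means = config$subscale_means,
                thresholds = config$thresholds, noise_sd = config$noise_sd)
  list(responses = responses, truth = truth)
}

#' Planted core items of a simulation configuration
#'
#' @param config a [sim_config].
#' @return named list of per-subscale planted item ids (ground truth for
#'   recovery checks).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "ccmq_simconfig"))
  config$planted
}

#' Calibrate latent means to target presence rates
#'
#' Adjusts each targeted subscale's latent mean by bisection until the
#' simulated presence fraction (from [classify_bc]) lands within `tol` of
#' the target at calibration size `n`. Evaluations reuse one fixed noise
#' realization (common random numbers), making the fraction a deterministic
#' monotone function of the mean. Biased types are calibrated before GTC,
#' whose compound criterion depends on them.
#'
#' @param config a [sim_config].
#' @param targets named vector of target presence fractions in (0, 1).
#' @param n calibration sample size (default 10000).
#' @param tol acceptable absolute deviation (default 0.02).
#' @param max_steps bisection step cap per target (default 50).
#' @return the calibrated `ccmq_simconfig`.
#' @export
calibrate_prevalence <- function(config, targets, n = 10000L, tol = 0.02,
                                 max_steps = 50L) {
  stopifnot(inherits(config, "ccmq_simconfig"))
  if (is.null(names(targets)) ||
      !all(names(targets) %in% names(config$subscale_means))) {
    stop("targets must be named by subscale")
  }
  if (any(targets <= 0 | targets >= 1)) {
    stop("targets must lie strictly inside (0, 1)")
  }
  eval_seed <- derive_seed(config$seed, 999)
  presence <- function(cfg, nm) {
    cfg$n <- as.integer(n); cfg$seed <- eval_seed
    sim <- simulate_responses(cfg)
    cls <- classify_bc(score_all(sim$responses, cfg$spec))
    mean(cls[[nm]] == "present")
  }
  order_nms <- names(targets)[order(names(targets) == "GTC")]  # GTC last
  for (nm in order_nms) {
    lo <- -4; hi <- 4
    f <- function(m) {
      cfg <- config; cfg$subscale_means[nm] <- m
      presence(cfg, nm) - targets[[nm]]
    }
    flo <- f(lo); fhi <- f(hi)
    if (flo > 0 || fhi < 0) {
      stop(sprintf(
        "cannot bracket target %.3f for %s (fraction range [%.3f, %.3f])",
        targets[[nm]], nm, flo + targets[[nm]], fhi + targets[[nm]]))
    }
    done <- FALSE
    for (step in seq_len(max_steps)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) <= tol) {
        config$subscale_means[nm] <- mid
        done <- TRUE
        break
      }
      if (fm < 0) lo <- mid else hi <- mid
    }
    if (!done) {
      stop(sprintf(
        "prevalence calibration for %s did not converge in %d steps (last interval [%.4f, %.4f], deviation %.4f)",
        nm, max_steps, lo, hi, f((lo + hi) / 2)))
    }
  }
  config
}
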