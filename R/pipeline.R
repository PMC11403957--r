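# End-to-end analysis: responses -> scores -> classification -> prevalence
# -> variable clustering -> per-subscale combination search -> comparison of
# supervised and cluster-based item selections.

#' Pipeline configuration
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param responses_path optional response CSV to analyse; when `NULL` a
#'   synthetic survey is generated from `simulation`.
#' @param simulation a [sim_config] (default: `sim_config(n = n, seed =
#'   seed)`).
#' @param n simulated sample size when `simulation` is not supplied.
#' @param spec a [ccmq_spec].
#' @param outdir output directory (`NULL` = do not write files).
#' @param cv_folds,holdout_frac cross-validation folds and held-out fraction.
#' @param varclus_threshold average-explained target for cluster-count
#'   selection, in (0, 1].
#' @param selection_threshold,elbow_ratio item-count selection rule
#'   parameters (see [select_num_items]).
#' @param zoo_families optional named list with `classification` /
#'   `regression` character vectors of zoo families.
#' @param explained_method passed to [explained_summary].
#' @return an object of class `ccmq_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, responses_path = NULL,
                            simulation = NULL, n = 2000L,
                            spec = load_spec(), outdir = NULL,
                            cv_folds = 5L, holdout_frac = 0.25,
                            varclus_threshold = 0.8,
                            selection_threshold = 0.8, elbow_ratio = 2,
                            zoo_families = NULL,
                            explained_method = "squared_correlation") {
  for (thr in c(varclus_threshold, selection_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr > 1) {
      stop("thresholds must lie in (0, 1]")
    }
  }
  if (is.null(responses_path) && is.null(simulation)) {
    simulation <- sim_config(n = n, spec = spec, seed = seed)
  }
  structure(list(seed = as.integer(seed), responses_path = responses_path,
                 simulation = simulation, spec = spec, outdir = outdir,
                 cv_folds = cv_folds, holdout_frac = holdout_frac,
                 varclus_threshold = varclus_threshold,
                 selection_threshold = selection_threshold,
                 elbow_ratio = elbow_ratio, zoo_families = zoo_families,
                 explained_method = explained_method),
            class = "ccmq_pipeline_config")
}

# Cluster-based item list per subscale: representatives that are members;
# when none of a subscale's members is a representative, the representative
# of the cluster holding most of its members stands in.
varclus_items_by_subscale <- function(repset, spec) {
  reps <- sort(repset$representatives$item)
  out <- list()
  for (nm in names(spec$subscales)) {
    members <- spec$subscales[[nm]]
    sel <- intersect(reps, members)
    if (length(sel) == 0) {
      overlap <- vapply(repset$clusters, function(cl)
        length(intersect(cl, members)), 0L)
      sel <- repset$representatives$item[which.max(overlap)]
    }
    out[[nm]] <- sort(sel)
  }
  out
}

#' Run the full rapid-determination analysis
#'
#' Stages: obtain responses (simulate or load), score and classify, summarize
#' prevalence, divisive variable clustering with representative selection,
#' exhaustive per-subscale combination search for both targets
#' (classification and score) with item-count selection and holdout reports,
#' holdout evaluation of the cluster-based item lists, and a comparison of
#' the three selection procedures. With `outdir` set, all tables are written
#' as CSV/JSON plus a run manifest; numeric outputs are byte-identical
#' across reruns with the same configuration.
#'
#' @param config a [pipeline_config].
#' @return a report bundle (list); see the individual stage functions.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ccmq_pipeline_config"))
  spec <- config$spec
  written <- character(0)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)  # no partial bundles
      stop_stage(stage, e)
    })
  }

  t0 <- proc.time()[3]
  say <- function(stage) {
    message(sprintf("[%6.1fs] %s", proc.time()[3] - t0, stage))
  }

  say("input")
  truth <- NULL
  responses <- with_stage("input", {
    if (!is.null(config$responses_path)) {
      load_responses(config$responses_path, spec)
    } else {
      sim <- simulate_responses(config$simulation)
      truth <- sim$truth
      sim$responses
    }
  })

  say("scoring")
  scoring <- with_stage("scoring", {
    scores <- score_all(responses, spec)
    classification <- classify_bc(scores)
    list(scores = scores, classification = classification,
         prevalence = prevalence_summary(classification))
  })

  say("varclus")
  varclus <- with_stage("varclus", {
    model <- correlation_model(unclass(responses))
    hierarchy <- build_hierarchy(model)
    sel <- select_partition(hierarchy, model,
                            threshold = config$varclus_threshold,
                            method = config$explained_method)
    list(model = model, hierarchy = hierarchy, selected_K = sel$selected_K,
         representatives = sel$representatives, curve = sel$curve,
         items_by_subscale = varclus_items_by_subscale(sel$representatives,
                                                       spec))
  })

  say("item selection")
  selection <- with_stage("item_selection", {
    out <- list(classification = list(), score = list())
    for (target in c("classification", "score")) {
      kind <- if (target == "classification") "classification" else
        "regression"
      zoo <- model_zoo(kind, config$zoo_families[[kind]])
      for (nm in names(spec$subscales)) {
        task <- prediction_task(responses, spec, nm, target = target)
        search <- best_per_k(task, zoo, cv_folds = config$cv_folds,
                             seed = derive_seed(config$seed,
                                                match(nm, bc_types())))
        pick <- select_num_items(search,
                                 threshold = config$selection_threshold,
                                 elbow_ratio = config$elbow_ratio)
        rep_seed <- derive_seed(config$seed, 100 + match(nm, bc_types()))
        report <- holdout_report(task, pick$combo, pick$family,
                                 seed = rep_seed,
                                 holdout_frac = config$holdout_frac)
        vc_items <- intersect(varclus$items_by_subscale[[nm]], task$pool)
        if (length(vc_items) == 0) vc_items <- varclus$items_by_subscale[[nm]]
        vc_task <- if (all(vc_items %in% task$pool)) task else
          prediction_task(responses, spec, nm, target = target,
                          pool = sort(unique(c(task$pool, vc_items))))
        vc_eval <- evaluate_combo(vc_task, vc_items, zoo,
                                  cv_folds = config$cv_folds,
                                  seed = derive_seed(config$seed,
                                                     match(nm, bc_types())))
        vc_report <- holdout_report(vc_task, vc_items, vc_eval$family,
                                    seed = rep_seed,
                                    holdout_frac = config$holdout_frac)
        out[[target]][[nm]] <- list(search = search, selection = pick,
                                    report = report,
                                    varclus_items = vc_items,
                                    varclus_family = vc_eval$family,
                                    varclus_report = vc_report)
      }
    }
    out
  })

  say("comparison")
  comparison <- with_stage("comparison", {
    cls_items <- lapply(selection$classification, function(s) s$selection$combo)
    score_items <- lapply(selection$score, function(s) s$selection$combo)
    compare_selections(cls_items, score_items, varclus$items_by_subscale,
                       reports = selection)
  })

  bundle <- list(config = config, responses = responses, truth = truth,
                 scoring = scoring, varclus = varclus, selection = selection,
                 comparison = comparison)

  if (!is.null(config$outdir)) {
    say("write")
    written <- with_stage("write", write_bundle(bundle, config$outdir))
    bundle$files <- written
  }
  say("done")
  invisible(bundle)
}

#' Compare supervised and cluster-based item selections
#'
#' Three procedures select items per subscale: the combination search with
#' the classification target, the combination search with the score target,
#' and variable clustering. The comparison reports each item's selection
#' frequency (0-3 procedures), the per-subscale item lists with their
#' overlap, and — when holdout reports are supplied — side-by-side metric
#' deltas between the supervised and the cluster-based item source.
#'
#' @param cls_items,score_items,varclus_items named lists (same subscale
#'   names) of selected item-id vectors.
#' @param reports optional selection stage output of [run_pipeline] carrying
#'   holdout reports for both item sources.
#' @return list with `frequency` (data frame item x procedures),
#'   `by_subscale` (data frame of lists and overlap) and `metrics` (deltas,
#'   when reports are given).
#' @export
compare_selections <- function(cls_items, score_items, varclus_items,
                               reports = NULL) {
  nms <- names(cls_items)
  if (!setequal(nms, names(score_items)) ||
      !setequal(nms, names(varclus_items))) {
    stop("mismatched subscale coverage across selection procedures")
  }
  all_items <- sort(unique(c(unlist(cls_items), unlist(score_items),
                             unlist(varclus_items))))
  freq <- data.frame(
    item = all_items,
    by_classification = all_items %in% unlist(cls_items),
    by_score = all_items %in% unlist(score_items),
    by_varclus = all_items %in% unlist(varclus_items))
  freq$n_procedures <- rowSums(freq[, -1])

  by_subscale <- do.call(rbind, lapply(nms, function(nm) {
    supervised <- sort(unique(c(cls_items[[nm]], score_items[[nm]])))
    ov <- intersect(supervised, varclus_items[[nm]])
    data.frame(subscale = nm,
               classification_items = paste(sort(cls_items[[nm]]),
                                            collapse = ","),
               score_items = paste(sort(score_items[[nm]]), collapse = ","),
               varclus_items = paste(sort(varclus_items[[nm]]),
                                     collapse = ","),
               n_overlap = length(ov),
               overlap = paste(ov, collapse = ","))
  }))

  metrics <- NULL
  if (!is.null(reports)) {
    metrics <- do.call(rbind, lapply(nms, function(nm) {
      s_cls <- reports$classification[[nm]]
      s_sc <- reports$score[[nm]]
      data.frame(subscale = nm,
                 auc_supervised = s_cls$report$auc,
                 auc_varclus = s_cls$varclus_report$auc,
                 auc_delta = s_cls$report$auc - s_cls$varclus_report$auc,
                 r2_supervised = s_sc$report$r2,
                 r2_varclus = s_sc$varclus_report$r2,
                 r2_delta = s_sc$report$r2 - s_sc$varclus_report$r2)
    }))
  }
  list(frequency = freq, by_subscale = by_subscale, metrics = metrics)
}

# Serialize the bundle. Full precision; no timestamps, so reruns with the
# same config byte-reproduce every file.
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(outdir, name)
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                  trim = TRUE))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wjson <- function(x, name) {
    path <- file.path(outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
  }

  wcsv(bundle$scoring$scores, "scores.csv")
  wcsv(bundle$scoring$classification, "classification.csv")
  wjson(bundle$scoring$prevalence, "prevalence.json")

  part <- bundle$varclus$hierarchy$partitions[[bundle$varclus$selected_K]]
  wcsv(data.frame(item = unlist(part),
                  cluster = rep(seq_along(part), lengths(part))),
       "varclus_partition.csv")
  wcsv(bundle$varclus$representatives$representatives,
       "varclus_representatives.csv")
  wcsv(bundle$varclus$curve, "varclus_curve.csv")

  for (target in c("classification", "score")) {
    tab <- do.call(rbind, lapply(names(bundle$selection[[target]]),
      function(nm) {
        s <- bundle$selection[[target]][[nm]]
        cbind(subscale = nm, s$search$table,
              selected = s$search$table$k == s$selection$selected_k)
      }))
    wcsv(tab, sprintf("selection_%s.csv", target))
  }
  summary <- lapply(c(classification = "classification", score = "score"),
    function(target) {
      lapply(bundle$selection[[target]], function(s) {
        list(selected_k = s$selection$selected_k, rule = s$selection$rule,
             combo = s$selection$combo, family = s$selection$family,
             holdout = as.list(s$report),
             varclus_items = s$varclus_items,
             varclus_holdout = as.list(s$varclus_report))
      })
    })
  wjson(summary, "selection_summary.json")

  wcsv(bundle$comparison$frequency, "comparison_frequency.csv")
  wcsv(bundle$comparison$by_subscale, "comparison_by_subscale.csv")
  if (!is.null(bundle$comparison$metrics)) {
    wcsv(bundle$comparison$metrics, "comparison_metrics.csv")
  }

  cfg <- bundle$config
  manifest <- list(
    seed = cfg$seed,
    n = nrow(bundle$responses),
    input = cfg$responses_path %||% "simulated",
    simulation = if (!is.null(cfg$simulation)) list(
      n = cfg$simulation$n, seed = cfg$simulation$seed,
      subscale_means = as.list(cfg$simulation$subscale_means),
      thresholds = cfg$simulation$thresholds,
      noise_sd = cfg$simulation$noise_sd,
      planted = cfg$simulation$planted),
    cv_folds = cfg$cv_folds, holdout_frac = cfg$holdout_frac,
    varclus_threshold = cfg$varclus_threshold,
    selection_threshold = cfg$selection_threshold,
    elbow_ratio = cfg$elbow_ratio,
    explained_method = cfg$explained_method,
    package_version = as.character(utils::packageVersion("ccmqrapid")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  wjson(manifest, "manifest.json")
  files
}
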