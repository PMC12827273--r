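# End-to-end orchestration: cohort (synthetic or supplied) -> confounder
# verification -> causal estimation and ranking -> placebo + counterfactual
# validation -> region selection -> network training and evaluation.
# Every stage draws its seed deterministically from the global seed and
# writes its artifact to the output directory.

#' Pipeline configuration
#'
#' @param input either a [cohort_config()] (synthetic cohort), or a path to
#'   a cohort CSV as written by [write_cohort()].
#' @param outcomes outcome targets (default both `"mmse"` and `"faq"`).
#' @param alpha CI-test significance level (default 0.05).
#' @param max_cond_size PC conditioning-set bound (default 3).
#' @param pc_regions regions passed to the discovery stage; `NULL` = all
#'   (can be slow on 120 regions), or an integer n meaning the n regions of
#'   largest outcome correlation, or a character vector of names.
#' @param k_whole,k_group selection sizes (defaults 30, 20).
#' @param n_permutations placebo permutations (default 100).
#' @param counterfactual_top number of selected regions given
#'   counterfactual curves per group (default 2).
#' @param cognet named list of [cognet_config()] overrides (e.g.
#'   `list(epochs = 50)`); `n_features` and `seed` are filled in by the
#'   pipeline.
#' @param run_model run the training/evaluation stage (default TRUE).
#' @param outdir output directory for artifacts.
#' @param seed global seed; stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = cohort_config(),
                            outcomes = c("mmse", "faq"),
                            alpha = 0.05, max_cond_size = 3L,
                            pc_regions = 12L,
                            k_whole = 30L, k_group = 20L,
                            n_permutations = 100L,
                            counterfactual_top = 2L,
                            cognet = list(), run_model = TRUE,
                            outdir = tempfile("petcog_run_"), seed = 1L) {
  if (!(inherits(input, "cohort_config") ||
        (is.character(input) && length(input) == 1))) {
    stopf("'input' must be a cohort_config or a cohort CSV path")
  }
  structure(list(input = input, outcomes = outcomes, alpha = alpha,
                 max_cond_size = as.integer(max_cond_size),
                 pc_regions = pc_regions, k_whole = as.integer(k_whole),
                 k_group = as.integer(k_group),
                 n_permutations = as.integer(n_permutations),
                 counterfactual_top = as.integer(counterfactual_top),
                 cognet = cognet, run_model = isTRUE(run_model),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, report, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
  report$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(res = res, report = report)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation or loading; confounder
#' verification (PC + univariate regressions); backdoor-adjusted effect
#' estimation for every outcome at whole-cohort and per-group scope with
#' ranking and union selection; placebo testing of the selected regions;
#' linear-SCM counterfactual curves per group; and training/evaluation of
#' the attention-transformer regressor restricted to the selected regions
#' plus demographics. All artifacts are written under `config$outdir`; the
#' run report (JSON) references each one. Re-running with an identical
#' config reproduces all numeric artifacts.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` (invisibly also written to
#'   `run_report.json`): per-stage artifacts, file paths, timings, config
#'   echo and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  art <- function(...) file.path(config$outdir, paste0(...))
  report <- list(version = as.character(utils::packageVersion("petcog")),
                 seed = config$seed, timings = list(), artifacts = list())

  # -- data -----------------------------------------------------------------
  st <- run_stage("data", report, {
    if (inherits(config$input, "cohort_config")) {
      cc <- config$input
      cc$seed <- derive_seed(config$seed, "cohort")
      gen <- generate_cohort(cc)
      write_cohort(gen$table, art("cohort.csv"))
      gen
    } else {
      list(table = read_cohort(config$input), truth = NULL)
    }
  })
  report <- st$report
  table <- st$res$table
  truth <- st$res$truth
  report$artifacts$cohort <- art("cohort.csv")
  regions <- cohort_regions(table)
  groups <- sort(unique(table$group))

  # -- confounder verification ---------------------------------------------
  st <- run_stage("discover", report, {
    pr <- config$pc_regions
    treat <- if (is.null(pr)) {
      regions
    } else if (is.numeric(pr)) {
      sc <- vapply(regions, function(r)
        max(abs(stats::cor(table[[r]], table[[config$outcomes[1]]])),
            na.rm = TRUE), 0)
      names(sort(sc, decreasing = TRUE))[seq_len(min(pr, length(regions)))]
    } else as.character(pr)
    rep_conf <- verify_confounders(table, treatments = treat,
                                   outcomes = config$outcomes,
                                   alpha = config$alpha,
                                   max_cond_size = config$max_cond_size)
    write_graph(attr(rep_conf, "graph"), art("causal_graph.tsv"))
    jsonlite::write_json(
      lapply(rep_conf, function(x) x),
      art("confounder_report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    rep_conf
  })
  report <- st$report
  confounders <- st$res
  report$artifacts$confounder_report <- art("confounder_report.json")
  report$artifacts$causal_graph <- art("causal_graph.tsv")

  # -- causal effect estimation and selection ------------------------------
  effects <- list(); selections <- list(); overlaps <- list()
  for (oc in config$outcomes) {
    st <- run_stage(paste0("estimate_", oc), report, {
      whole <- estimate_all_effects(table, oc, "whole")
      per_group <- lapply(stats::setNames(groups, groups), function(g)
        estimate_all_effects(table, oc, g))
      utils::write.csv(whole, art("effects_", oc, "_whole.csv"),
                       row.names = FALSE)
      for (g in groups) {
        utils::write.csv(per_group[[g]], art("effects_", oc, "_", g, ".csv"),
                         row.names = FALSE)
      }
      sel <- union_selection(whole, per_group, config$k_whole, config$k_group)
      jsonlite::write_json(sel, art("selection_", oc, ".json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      ov <- cross_group_overlap(lapply(per_group, rank_and_select,
                                       k = min(config$k_group,
                                               length(regions))))
      jsonlite::write_json(ov, art("overlap_", oc, ".json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      list(whole = whole, per_group = per_group, selection = sel,
           overlap = ov)
    })
    report <- st$report
    effects[[oc]] <- st$res[c("whole", "per_group")]
    selections[[oc]] <- st$res$selection
    overlaps[[oc]] <- st$res$overlap
    report$artifacts[[paste0("effects_", oc)]] <- art("effects_", oc, "_whole.csv")
    report$artifacts[[paste0("selection_", oc)]] <- art("selection_", oc, ".json")
  }

  # -- refutation -----------------------------------------------------------
  placebo <- list(); curves <- list()
  for (oc in config$outcomes) {
    st <- run_stage(paste0("refute_", oc), report, {
      sel_regions <- selections[[oc]]$region
      pl <- placebo_test(table, sel_regions, oc,
                         n_permutations = config$n_permutations,
                         seed = derive_seed(config$seed, paste0("placebo_", oc)))
      cmp <- compare_actual_vs_placebo(pl)
      utils::write.csv(cmp, art("placebo_", oc, ".csv"), row.names = FALSE)
      top <- sel_regions[seq_len(min(config$counterfactual_top,
                                     length(sel_regions)))]
      cf <- list()
      for (r in top) for (g in groups) {
        cv <- counterfactual_curve(table, r, oc, scope = g)
        cf[[paste(r, g, sep = ".")]] <-
          data.frame(region = r, group = g, grid = cv$grid,
                     predicted = cv$predicted)
      }
      cf_tab <- do.call(rbind, cf)
      utils::write.csv(cf_tab, art("counterfactual_", oc, ".csv"),
                       row.names = FALSE)
      list(placebo = pl, comparison = cmp, curves = cf_tab)
    })
    report <- st$report
    placebo[[oc]] <- st$res$comparison
    curves[[oc]] <- st$res$curves
    report$artifacts[[paste0("placebo_", oc)]] <- art("placebo_", oc, ".csv")
    report$artifacts[[paste0("counterfactual_", oc)]] <-
      art("counterfactual_", oc, ".csv")
  }

  # -- prediction network ---------------------------------------------------
  metrics <- list(); models <- list()
  if (config$run_model) {
    for (oc in config$outcomes) {
      st <- run_stage(paste0("model_", oc), report, {
        feats <- c(selections[[oc]]$region, "age", "gender")
        cn_args <- utils::modifyList(
          list(n_features = length(feats),
               seed = derive_seed(config$seed, paste0("cognet_", oc))),
          config$cognet)
        cn_args$n_features <- length(feats)
        cfg <- do.call(cognet_config, cn_args)
        sp <- split_data(table, cfg$split_ratio,
                         seed = derive_seed(config$seed, paste0("split_", oc)))
        model <- train_cognet(sp$train, feats, oc, cfg)
        m <- evaluate_model(model, sp$test)
        utils::write.csv(model$history, art("history_", oc, ".csv"),
                         row.names = FALSE)
        scatter <- data.frame(subject_id = sp$test$subject_id,
                              actual = sp$test[[oc]],
                              predicted = predict(model, sp$test))
        utils::write.csv(scatter, art("predictions_", oc, ".csv"),
                         row.names = FALSE)
        jsonlite::write_json(m, art("metrics_", oc, ".json"),
                             auto_unbox = TRUE, digits = NA)
        list(model = model, metrics = m)
      })
      report <- st$report
      metrics[[oc]] <- st$res$metrics
      models[[oc]] <- st$res$model
      report$artifacts[[paste0("metrics_", oc)]] <- art("metrics_", oc, ".json")
      report$artifacts[[paste0("predictions_", oc)]] <-
        art("predictions_", oc, ".csv")
    }
  }

  run <- structure(list(
    config = config, table = table, truth = truth,
    confounders = confounders, effects = effects, selections = selections,
    overlaps = overlaps, placebo = placebo, curves = curves,
    metrics = metrics, models = models,
    timings = report$timings, artifacts = report$artifacts,
    version = report$version), class = "run_report")

  config_echo <- list(
    input = if (inherits(config$input, "cohort_config"))
      "synthetic cohort" else config$input,
    outcomes = config$outcomes, alpha = config$alpha,
    max_cond_size = config$max_cond_size, k_whole = config$k_whole,
    k_group = config$k_group, n_permutations = config$n_permutations,
    cognet_overrides = config$cognet, run_model = config$run_model,
    outdir = config$outdir, seed = config$seed)
  json_report <- list(version = report$version, seed = config$seed,
                      outcomes = config$outcomes,
                      config = config_echo,
                      timings = report$timings,
                      artifacts = report$artifacts,
                      metrics = metrics,
                      n_subjects = nrow(table),
                      n_regions = length(regions))
  jsonlite::write_json(json_report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  run
}

#' Human-readable summary tables of a pipeline run
#'
#' Emits, per outcome: the ranked causal-score table (top `k_whole` rows),
#' the actual-vs-placebo comparison, the counterfactual curves, and (when
#' the model stage ran) the actual-vs-predicted test-set scatter data, as
#' delimited text under `<outdir>/report_*.csv`.
#'
#' @param run a `run_report` from [run_pipeline()].
#' @return named list of the emitted data.frames, invisibly.
#' @export
make_report_tables <- function(run) {
  stopifnot(inherits(run, "run_report"))
  outdir <- run$config$outdir
  out <- list()
  for (oc in names(run$effects)) {
    ranked <- utils::head(run$effects[[oc]]$whole, run$config$k_whole)
    out[[paste0("ranked_", oc)]] <- ranked
    utils::write.csv(ranked, file.path(outdir, paste0("report_ranked_", oc, ".csv")),
                     row.names = FALSE)
    out[[paste0("placebo_", oc)]] <- run$placebo[[oc]]
    utils::write.csv(run$placebo[[oc]],
                     file.path(outdir, paste0("report_placebo_", oc, ".csv")),
                     row.names = FALSE)
    out[[paste0("counterfactual_", oc)]] <- run$curves[[oc]]
    utils::write.csv(run$curves[[oc]],
                     file.path(outdir, paste0("report_counterfactual_", oc, ".csv")),
                     row.names = FALSE)
    pred_file <- run$artifacts[[paste0("predictions_", oc)]]
    if (!is.null(pred_file) && file.exists(pred_file)) {
      out[[paste0("scatter_", oc)]] <- utils::read.csv(pred_file)
      utils::write.csv(out[[paste0("scatter_", oc)]],
                       file.path(outdir, paste0("report_scatter_", oc, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(out)
}
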