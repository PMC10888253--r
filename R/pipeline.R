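# End-to-end orchestration: per-case analysis (read, pre-gate, cluster,
# classify, refine, report), model persistence, and synthetic training
# batches.  The command-line entry point in inst/cli wraps these
# functions.

#' Run configuration
#'
#' @param input character vector of case directories, each holding one FCS
#'   file per tube.
#' @param out output directory for reports.
#' @param panel_path optional panel YAML (default: bundled ALPS panel).
#' @param model_path optional model JSON from [save_models()].
#' @param seed base seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @param params per-stage parameter overrides (passed to [pregate()] and
#'   [cluster_events()]).
#' @return a `cg_run_config`.
#' @export
run_config <- function(input, out, panel_path = NULL, model_path = NULL,
                       seed = 1, params = list()) {
  structure(list(input = input, out = out, panel_path = panel_path,
                 model_path = model_path, seed = seed, params = params),
            class = "cg_run_config")
}

#' Analyze one case from in-memory samples
#'
#' The five-stage pipeline on a named or unnamed list of raw samples (one
#' per tube): tube matching, transform, pre-gating, clustering, forest
#' classification, rule refinement, enumeration, report assembly.
#'
#' @param samples list of raw `cg_sample` objects.
#' @param panel a `cg_panel`.
#' @param models named list of `cg_apc_model` per tube.
#' @param case_id case identifier.
#' @param params per-stage overrides.
#' @param run_config optional config echoed into provenance.
#' @return list with the `report` (`cg_report`) and per-tube intermediate
#'   `tube_results`.
#' @export
analyze_case <- function(samples, panel, models, case_id = "case",
                         params = list(), run_config = NULL) {
  tube_results <- list()
  for (s in samples) {
    s <- match_tube(s, panel)
    tube <- panel$tubes[[s$tube]]
    if (!s$transformed) s <- apply_transform(s)
    clean <- pregate(s, tube, params = params)
    clusters <- cluster_events(clean, tube, params = params)
    feats <- featurize(clusters, tube)
    model <- models[[tube$name]]
    if (is.null(model))
      cg_stop("cg_config_error", "no model available for tube '%s'", tube$name)
    lineages <- classify_clusters(model, feats)
    labels <- refine_subsets(clusters, lineages, tube, panel)
    table <- enumerate_subsets(labels, panel)
    tube_results[[tube$name]] <- list(clean = clean, clusters = clusters,
                                      labels = labels, table = table)
  }
  model_info <- list(
    models = lapply(models[names(tube_results)], function(m)
      list(version = m$version, seed = m$seed, n_train = m$n_train,
           oob_accuracy = m$oob_accuracy))
  )
  rc <- if (is.null(run_config)) NULL else
    list(run_seed = run_config$seed, panel_path = run_config$panel_path %||% "bundled")
  report <- build_report(case_id, panel, tube_results,
                         model_info = model_info, run_config = rc)
  list(report = report, tube_results = tube_results)
}

#' Analyze a batch of case directories
#'
#' Reads each case directory (one FCS file per tube), runs [analyze_case()]
#' and writes `<case>_report.json` plus a subset CSV per case to the
#' output directory.  Cases with a missing tube or a rejected sample are
#' skipped and recorded in the returned batch summary (also written as
#' `batch_summary.json`).
#'
#' @param run a [run_config()].
#' @param models optional preloaded models (else loaded from
#'   `run$model_path`).
#' @param panel optional preloaded panel.
#' @return invisible batch summary list.
#' @export
analyze <- function(run, models = NULL, panel = NULL) {
  stopifnot(inherits(run, "cg_run_config"))
  panel <- panel %||% load_panel(run$panel_path)
  models <- models %||% load_models(run$model_path)
  dir.create(run$out, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  for (dir in run$input) {
    case_id <- basename(dir)
    status <- tryCatch({
      files <- list.files(dir, pattern = "\\.(fcs|lmd|FCS|LMD)$", full.names = TRUE)
      files <- files[!grepl("truth", files)]
      samples <- lapply(files, read_fcs)
      matched <- vapply(samples, function(s)
        tryCatch(match_tube(s, panel)$tube, error = function(e) NA_character_), "")
      samples <- samples[!is.na(matched)]
      found <- matched[!is.na(matched)]
      missing <- setdiff(names(panel$tubes), found)
      if (length(missing))
        cg_stop("cg_data_error", "missing tube file(s): %s",
                paste(missing, collapse = ", "))
      res <- analyze_case(samples, panel, models, case_id = case_id,
                          params = run$params, run_config = run)
      write_report(res$report, file.path(run$out, paste0(case_id, "_report.json")))
      tabs <- do.call(rbind, lapply(res$tube_results, `[[`, "table"))
      write.csv(tabs, file.path(run$out, paste0(case_id, "_subsets.csv")),
                row.names = FALSE)
      list(case_id = case_id, status = "ok")
    }, cg_error = function(e)
      list(case_id = case_id, status = "skipped", error = conditionMessage(e)))
    summary[[case_id]] <- status
  }
  cg_write_json(unname(summary), file.path(run$out, "batch_summary.json"))
  invisible(summary)
}

#' Save / load per-tube classifier models
#'
#' Models persist as one JSON document holding, per tube, the forest
#' (flattened trees), label vocabulary, parameters and seed.
#'
#' @param models named list of `cg_apc_model`.
#' @param path JSON path.
#' @return `save_models`: the path invisibly; `load_models`: the model
#'   list.
#' @export
save_models <- function(models, path) {
  doc <- lapply(models, function(m) list(
    tube = m$tube, vocab = m$vocab, n_train = m$n_train, seed = m$seed,
    oob_accuracy = m$oob_accuracy, version = m$version,
    forest = list(
      labels = m$forest$labels, mtry = m$forest$mtry,
      n_trees = m$forest$n_trees, min_n = m$forest$min_n,
      seed = m$forest$seed, n_train = m$forest$n_train,
      oob_accuracy = m$forest$oob_accuracy,
      feature_names = m$forest$feature_names,
      trees = lapply(m$forest$trees, function(t) as.list(t))
    )))
  cg_write_json(doc, path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  if (is.null(path)) cg_stop("cg_config_error", "no model path given")
  doc <- cg_read_json(path)
  out <- lapply(doc, function(m) {
    fr <- m$forest
    num <- function(l) vapply(l, function(x)
      if (is.null(x)) NA_real_ else as.numeric(x), 1)
    trees <- lapply(fr$trees, function(t)
      data.frame(feature = as.integer(num(t$feature)),
                 threshold = num(t$threshold),
                 left = as.integer(num(t$left)),
                 right = as.integer(num(t$right)),
                 pred = as.integer(num(t$pred))))
    forest <- structure(list(
      trees = trees, labels = as.character(unlist(fr$labels)),
      mtry = fr$mtry, n_trees = fr$n_trees, min_n = fr$min_n,
      seed = fr$seed, feature_names = as.character(unlist(fr$feature_names)),
      n_train = fr$n_train, oob_accuracy = fr$oob_accuracy
    ), class = "cg_forest")
    structure(list(tube = m$tube, forest = forest,
                   vocab = as.character(unlist(m$vocab)),
                   n_train = m$n_train, seed = m$seed,
                   oob_accuracy = m$oob_accuracy, version = m$version),
              class = "cg_apc_model")
  })
  names(out) <- vapply(out, `[[`, "", "tube")
  out
}

#' Train per-tube models from a synthetic labeled batch
#'
#' Simulates `n_cases` cases (varying abundances by the Dirichlet-style
#' jitter), builds ground-truth labeled cluster features for every tube,
#' and trains one forest per tube.  This mirrors incremental training from
#' manually gated cases, with the simulator supplying the labels.
#'
#' @param panel a `cg_panel`.
#' @param n_cases labeled training cases (default 60).
#' @param n_events events per tube per case.
#' @param seed base seed; case i uses seed `seed * 100000 + i`.
#' @param jitter_concentration abundance jitter (default 5).
#' @param n_trees forest size.
#' @return list with `models` (per tube) and the `store`.
#' @export
train_from_synthetic <- function(panel, n_cases = 60, n_events = 5000,
                                 seed = 1, jitter_concentration = 5,
                                 n_trees = 200) {
  store <- new_store(panel)
  for (i in seq_len(n_cases)) {
    sc <- scenario("NORMAL", n_events = n_events,
                   doublet_rate = 0, debris_rate = 0,
                   seed = derive_seed(seed, 100000 + i),
                   jitter_concentration = jitter_concentration)
    case <- make_case(sc, panel)
    for (tb in names(panel$tubes)) {
      tr <- truth_training(case$samples[[tb]], case$truth[[tb]],
                           panel$tubes[[tb]], panel)
      store <- update_store(store, tb, tr$features, tr$labels,
                            case_id = sprintf("train_%03d", i))
    }
  }
  models <- lapply(names(panel$tubes), function(tb)
    train_classifier(store, tb, n_trees = n_trees, seed = derive_seed(seed, 7)))
  names(models) <- names(panel$tubes)
  list(models = models, store = store)
}

#' Parameter-recovery experiment
#'
#' The package's end-to-end validation: train per-tube forests on a
#' synthetic labeled batch, simulate an independent batch of cases with
#' jittered abundances, push every case through FCS files and the full
#' analyze pipeline, and correlate estimated against true subset
#' percentages across the batch.
#'
#' @param panel a `cg_panel` (default: bundled ALPS panel).
#' @param n_train labeled training cases (default 60).
#' @param n_cases evaluation cases (default 60).
#' @param n_events events per tube per evaluation case (default 20000).
#' @param seed base seed driving every random draw.
#' @param subsets subsets (with their canonical tubes) summarized by
#'   `min_r`.
#' @param use_files route each case through FCS write/read (default
#'   `TRUE`).
#' @param dir scratch directory for case files.
#' @return list: `concordance` (full [evaluate_batch()] table), `min_r`
#'   over the requested subsets, `n_cases`, `models`.
#' @export
parameter_recovery <- function(panel = load_panel(), n_train = 60,
                               n_cases = 60, n_events = 20000, seed = 1,
                               subsets = data.frame(
                                 tube = c("ALPS-T", "ALPS-T", "ALPS-B",
                                          "ALPS-T", "ALPS-T", "ALPS-T"),
                                 subset = c("T cells", "B cells", "NK cells",
                                            "CD4 T cells", "CD8 T cells",
                                            "TCRab+ DNT")),
                               use_files = TRUE, dir = tempfile("cg_batch")) {
  trained <- train_from_synthetic(panel, n_cases = n_train,
                                  seed = derive_seed(seed, 900001))
  est <- list(); ref <- list()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_cases)) {
    cid <- sprintf("case_%03d", i)
    sc <- scenario("NORMAL", n_events = n_events,
                   seed = derive_seed(seed, i), jitter_concentration = 5)
    case <- make_case(sc, panel)
    samples <- case$samples
    if (use_files) {
      cdir <- file.path(dir, cid)
      write_case(case, cdir, case_id = cid)
      files <- list.files(cdir, pattern = "\\.fcs$", full.names = TRUE)
      samples <- lapply(files, read_fcs)
      unlink(cdir, recursive = TRUE)
    }
    res <- analyze_case(samples, panel, trained$models, case_id = cid)
    est[[i]] <- report_estimates(res$report, cid)
    ref[[i]] <- batch_truth(list(case), cid)
  }
  conc <- evaluate_batch(do.call(rbind, est), do.call(rbind, ref))
  key <- paste(conc$tube, conc$subset)
  want <- paste(subsets$tube, subsets$subset)
  min_r <- min(conc$r[match(want, key)])
  list(concordance = conc, min_r = min_r, n_cases = n_cases,
       models = trained$models)
}
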