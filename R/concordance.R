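# Parameter-recovery validation: per-subset Pearson correlation between
# pipeline estimates and reference (ground-truth or manual) percentages
# across a batch of cases.

#' Pearson correlation between paired percentage vectors
#'
#' @param x,y equal-length numeric vectors (>= 3 values each).
#' @return the product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    cg_stop("cg_correlation_error", "need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    cg_stop("cg_correlation_error",
            "correlation undefined: zero variance in one input")
  cor(x, y)
}

#' Extract per-subset estimates from a case report
#'
#' @param report a `cg_report` (built or read back from JSON).
#' @param case_id identifier to attach (defaults to the report's).
#' @return long data frame: `case_id`, `tube`, `subset`, `pct_of_lymphs`.
#' @export
report_estimates <- function(report, case_id = NULL) {
  case_id <- case_id %||% report$case_id
  rows <- lapply(names(report$tubes), function(tb) {
    s <- report$tubes[[tb]]$subsets
    if (is.data.frame(s)) {
      data.frame(case_id = case_id, tube = tb, subset = s$subset,
                 pct_of_lymphs = s$pct_of_lymphs, stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(s, function(r)
        data.frame(case_id = case_id, tube = tb, subset = r$subset,
                   pct_of_lymphs = as.numeric(r$pct_of_lymphs),
                   stringsAsFactors = FALSE)))
    }
  })
  do.call(rbind, rows)
}

#' Batch concordance between estimated and reference percentages
#'
#' Aligns estimates and reference by case, tube and subset (the
#' percent-of-lymphocytes scale by default), fills absent estimate rows
#' with zero (a subset the pipeline found empty), and reports per-subset
#' Pearson r, case count, mean bias and a pass flag at the configured
#' threshold.  Subsets absent from the reference in more than half the
#' cases are excluded with a warning; subsets with degenerate (zero
#' variance) reference or estimates surface an explicit note instead of a
#' correlation.
#'
#' @param estimates,reference long data frames with columns `case_id`,
#'   `tube`, `subset`, and the value column `value_col`.
#' @param value_col value column name (default `"pct_of_lymphs"`).
#' @param r_threshold pass threshold on r (default 0.9).
#' @return a `cg_concordance` data frame: `tube`, `subset`, `n`, `r`,
#'   `bias`, `pass`, `note`.
#' @export
evaluate_batch <- function(estimates, reference, value_col = "pct_of_lymphs",
                           r_threshold = 0.9) {
  n_cases <- length(unique(reference$case_id))
  keys <- unique(reference[, c("tube", "subset")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    tb <- keys$tube[i]; sb <- keys$subset[i]
    ref <- reference[reference$tube == tb & reference$subset == sb, ]
    if (nrow(ref) < n_cases / 2) {
      warning(sprintf("subset '%s' (%s) present in fewer than half the cases; excluded",
                      sb, tb))
      return(NULL)
    }
    est <- estimates[estimates$tube == tb & estimates$subset == sb, ]
    ev <- est[[value_col]][match(ref$case_id, est$case_id)]
    ev[is.na(ev)] <- 0
    rv <- ref[[value_col]]
    r <- tryCatch(pearson_r(ev, rv), cg_correlation_error = function(e) NA_real_)
    note <- if (is.na(r)) "undefined correlation (zero variance)" else ""
    data.frame(tube = tb, subset = sb, n = length(rv), r = r,
               bias = mean(ev - rv), pass = !is.na(r) & r >= r_threshold,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  class(out) <- c("cg_concordance", class(out))
  attr(out, "r_threshold") <- r_threshold
  out
}

#' Truth tables of a batch in long format
#'
#' @param cases list of [make_case()] results.
#' @param case_ids identifiers (default `case_1` ...).
#' @return long reference data frame for [evaluate_batch()].
#' @export
batch_truth <- function(cases, case_ids = NULL) {
  case_ids <- case_ids %||% paste0("case_", seq_along(cases))
  do.call(rbind, lapply(seq_along(cases), function(i) {
    do.call(rbind, lapply(cases[[i]]$truth_tables, function(tt)
      data.frame(case_id = case_ids[i], tube = tt$tube, subset = tt$subset,
                 pct_of_lymphs = tt$pct_of_lymphs, stringsAsFactors = FALSE)))
  }))
}
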