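# Stage-5 reporting: hierarchical subset enumeration, ALPS criteria,
# reference-range flags, disease-pattern interpretation, and a canonical
# machine-readable JSON report.

#' Enumerate subsets from labeled events
#'
#' Counts events per taxonomy node of the tube (a cluster contributes its
#' size to every node on its label path plus its secondary memberships) and
#' derives percent-of-parent and percent-of-lymphocytes, both recomputable
#' from the counts exactly.  A node appears in the table when its parent
#' has a non-zero count, so empty lineages keep a zero row while their
#' children are absent.
#'
#' @param labels a [refine_subsets()] result.
#' @param panel the `cg_panel`.
#' @return a `SubsetTable` data frame: `subset`, `tube`, `parent`,
#'   `count`, `pct_of_parent`, `pct_of_lymphs`, `secondary`.
#' @export
enumerate_subsets <- function(labels, panel) {
  stopifnot(inherits(labels, "cg_labels"))
  nodes <- tube_taxonomy(panel, labels$tube)
  node_names <- vapply(nodes, `[[`, "", "name")
  counts <- setNames(rep(0, length(node_names)), node_names)
  sizes <- labels$clusters$size
  for (c in seq_len(nrow(labels$clusters))) {
    member <- intersect(c(labels$paths[[c]], labels$secondary[[c]]), node_names)
    counts[member] <- counts[member] + sizes[c]
  }
  lymph <- counts["lymphocytes"]
  if (is.na(lymph) || lymph == 0)
    cg_stop("cg_enumeration_error", "zero lymphocytes in tube '%s'", labels$tube)

  rows <- lapply(nodes, function(n) {
    parent_count <- if (is.na(n$parent)) counts[n$name] else counts[n$parent]
    if (!is.na(n$parent) && (is.na(parent_count) || parent_count == 0))
      return(NULL)
    data.frame(subset = n$name, tube = n$tube,
               parent = if (is.na(n$parent)) "" else n$parent,
               count = unname(counts[n$name]),
               pct_of_parent = unname(100 * counts[n$name] / parent_count),
               pct_of_lymphs = unname(100 * counts[n$name] / lymph),
               secondary = n$secondary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Evaluate the ALPS double-negative T-cell criteria
#'
#' Computes the TCRab+ DNT population as a percentage of total lymphocytes
#' and of CD3+ T cells; the flag is the OR of the two configured
#' thresholds (defaults: > 1.5% of lymphocytes, > 2.5% of CD3+ T cells).
#'
#' @param table a [enumerate_subsets()] table (or several rbind-ed tubes).
#' @param criteria the `alps_criteria` list of a `cg_panel`.
#' @return an `ALPSResult` list: `dnt_pct_of_lymphs`, `dnt_pct_of_cd3`,
#'   `flag`, `criteria`.
#' @export
evaluate_alps <- function(table, criteria) {
  tb <- table[table$tube == criteria$tube, , drop = FALSE]
  dnt <- tb[tb$subset == criteria$dnt_subset, , drop = FALSE]
  tc <- tb[tb$subset == criteria$t_subset, , drop = FALSE]
  lymph <- tb[tb$subset == "lymphocytes", , drop = FALSE]
  if (nrow(tc) != 1 || nrow(lymph) != 1)
    cg_stop("cg_evaluation_error",
            "subset table lacks '%s' or 'lymphocytes' rows for tube %s",
            criteria$t_subset, criteria$tube)
  # a DNT node absent from the table under a populated T-cell parent is an
  # empty subset, not a malformed table
  dnt_count <- if (nrow(dnt) == 1) dnt$count else 0
  pct_lymph <- 100 * dnt_count / lymph$count
  pct_cd3 <- if (tc$count > 0) 100 * dnt_count / tc$count else 0
  list(
    dnt_pct_of_lymphs = pct_lymph,
    dnt_pct_of_cd3 = pct_cd3,
    flag = (pct_lymph > criteria$dnt_pct_of_lymphs) ||
           (pct_cd3 > criteria$dnt_pct_of_cd3),
    criteria = criteria[c("dnt_pct_of_lymphs", "dnt_pct_of_cd3")]
  )
}

#' Flag subsets outside their reference ranges
#'
#' @param table a subset table (any number of tubes rbind-ed).
#' @param ranges the `reference_ranges` data frame of a `cg_panel`
#'   (subset, tube, low, high, denominator).
#' @return data frame with one row per evaluable range: `subset`, `tube`,
#'   `value` (percent of the configured denominator), `low`, `high`,
#'   `flag` in `low`/`high`/`in_range`.
#' @export
apply_reference_ranges <- function(table, ranges) {
  if (is.null(ranges) || nrow(ranges) == 0) return(data.frame())
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    tb <- table[table$tube == r$tube, , drop = FALSE]
    den <- tb[tb$subset == r$denominator, , drop = FALSE]
    if (nrow(den) != 1)
      cg_stop("cg_config_error",
              "reference range for '%s': denominator '%s' absent from table",
              r$subset, r$denominator)
    if (den$count == 0) return(NULL)
    sub <- tb[tb$subset == r$subset, , drop = FALSE]
    value <- if (nrow(sub) == 1) 100 * sub$count / den$count else 0
    flag <- "in_range"
    if (!is.na(r$low) && value < r$low) flag <- "low"
    if (!is.na(r$high) && value > r$high) flag <- "high"
    data.frame(subset = r$subset, tube = r$tube, value = value,
               low = r$low, high = r$high, denominator = r$denominator,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) data.frame() else out
}

#' Pattern-level interpretation codes
#'
#' Emits interpretation codes with human-readable rationales:
#' `ALPS_PATTERN` when the DNT criteria flag fires; `DIGEORGE_PATTERN`
#' when CD45RA+ T cells are low, CD45RO+ T cells high and switched memory
#' B cells low; `XLA_PATTERN` when B cells are at most 0.1% of
#' lymphocytes in every tube carrying a B-cell node; `NORMAL` otherwise.
#' These are screening patterns, not diagnoses.
#'
#' @param table combined subset table.
#' @param flags a [apply_reference_ranges()] result.
#' @param alps an [evaluate_alps()] result.
#' @param xla_b_pct_max B-cell percent-of-lymphocytes ceiling for the XLA
#'   pattern (default 0.1).
#' @return list of `list(code, rationale)`.
#' @export
evaluate_patterns <- function(table, flags, alps, xla_b_pct_max = 0.1) {
  out <- list()
  if (isTRUE(alps$flag))
    out <- c(out, list(list(
      code = "ALPS_PATTERN",
      rationale = sprintf(
        "TCRab+ DNT at %.2f%% of lymphocytes and %.2f%% of CD3+ T cells exceeds threshold (>%.1f%% or >%.1f%%)",
        alps$dnt_pct_of_lymphs, alps$dnt_pct_of_cd3,
        alps$criteria$dnt_pct_of_lymphs, alps$criteria$dnt_pct_of_cd3))))

  fl <- function(subset, what) {
    r <- flags[flags$subset == subset, , drop = FALSE]
    nrow(r) == 1 && r$flag == what
  }
  if (fl("CD45RA+ T cells", "low") && fl("CD45RO+ T cells", "high") &&
      fl("switched memory B cells", "low")) {
    ra <- flags[flags$subset == "CD45RA+ T cells", ]
    ro <- flags[flags$subset == "CD45RO+ T cells", ]
    sm <- flags[flags$subset == "switched memory B cells", ]
    out <- c(out, list(list(
      code = "DIGEORGE_PATTERN",
      rationale = sprintf(
        "CD45RA+ T cells %.1f%% (low, ref %.0f-%.0f), CD45RO+ T cells %.1f%% (high), switched memory B cells %.1f%% (low, ref >%.0f)",
        ra$value, ra$low, ra$high, ro$value, sm$value, sm$low))))
  }

  brows <- table[table$subset == "B cells" & !is.na(table$pct_of_lymphs), ,
                 drop = FALSE]
  if (nrow(brows) > 0 && all(brows$pct_of_lymphs <= xla_b_pct_max))
    out <- c(out, list(list(
      code = "XLA_PATTERN",
      rationale = sprintf(
        "B cells at %s%% of lymphocytes (absent, <= %.1f%% in all tubes)",
        paste(sprintf("%.3f", brows$pct_of_lymphs), collapse = "/"),
        xla_b_pct_max))))

  if (length(out) == 0)
    out <- list(list(code = "NORMAL",
                     rationale = "all evaluated subsets within configured ranges"))
  out
}

#' Assemble the case report
#'
#' Combines per-tube QC metrics, subset tables, ALPS evaluation,
#' reference-range flags, pattern codes and model provenance into a
#' `cg_report` that serializes to canonical JSON (fixed key order, full
#' numeric precision) and round-trips losslessly.
#'
#' @param case_id case identifier.
#' @param panel the `cg_panel`.
#' @param tube_results named list (by tube) of
#'   `list(clean, clusters, labels, table)` as produced by the pipeline.
#' @param model_info optional provenance list (model version, seed,
#'   training size).
#' @param run_config optional run configuration, echoed for provenance.
#' @return a `cg_report`.
#' @export
build_report <- function(case_id, panel, tube_results, model_info = NULL,
                         run_config = NULL) {
  full_table <- do.call(rbind, lapply(tube_results, `[[`, "table"))
  alps <- evaluate_alps(full_table, panel$alps_criteria)
  flags <- apply_reference_ranges(full_table, panel$reference_ranges)
  patterns <- evaluate_patterns(full_table, flags, alps)

  tubes <- lapply(tube_results, function(tr) {
    qc <- tr$clean$qc
    lc <- tr$labels$clusters
    list(
      qc = list(
        n_input = length(tr$clean$mask),
        n_surviving = sum(tr$clean$mask),
        pass_min_events = qc$pass_min_events,
        min_events_required = qc$min_events_required,
        n_bins_dropped = nrow(qc$bins_dropped),
        fractions_removed = as.list(tr$clean$fractions_removed),
        viability_proxy = tr$clean$viability_proxy
      ),
      low_confidence_clusters = lc$id[lc$low_confidence],
      subsets = tr$table[, c("subset", "parent", "count",
                             "pct_of_parent", "pct_of_lymphs", "secondary")]
    )
  })

  qc_warnings <- character(0)
  for (tb in names(tubes))
    if (!isTRUE(tubes[[tb]]$qc$pass_min_events))
      qc_warnings <- c(qc_warnings, sprintf(
        "tube %s: %d events acquired, below the required minimum of %d",
        tb, tubes[[tb]]$qc$n_input, tubes[[tb]]$qc$min_events_required))

  structure(list(
    case_id = case_id,
    panel_version = panel$version,
    tubes = tubes,
    alps = alps,
    reference_flags = flags,
    patterns = patterns,
    qc_warnings = as.list(qc_warnings),
    provenance = c(list(package_version =
                          as.character(utils::packageVersion("cytogate"))),
                   model_info %||% list(), run_config %||% list())
  ), class = "cg_report")
}

#' Write / read a case report
#'
#' @param report a `cg_report` (or the parsed list from [read_report()]).
#' @param path JSON path.
#' @return `write_report`: the path, invisibly; `read_report`: the parsed
#'   report.
#' @export
write_report <- function(report, path) {
  cg_write_json(unclass(report), path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(cg_read_json(path), class = "cg_report")
}

#' Diagnostic scatterplot pages
#'
#' Writes the standard 2D review plots as PNG files: FSC-A/FSC-H with the
#' fitted doublet separator, and marker biplots of the gating steps that a
#' reviewer back-gates (CD4/CD8 within T cells where available).
#'
#' @param tube_results as in [build_report()].
#' @param dir output directory.
#' @return paths of written files, invisibly.
#' @export
report_plots <- function(tube_results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in names(tube_results)) {
    tr <- tube_results[[tb]]
    sc <- tr$clean$sample$events
    f <- file.path(dir, sprintf("%s_scatter.png", gsub("[^A-Za-z0-9-]", "_", tb)))
    grDevices::png(f, width = 600, height = 600)
    graphics::plot(sc[, "FSC-A"], sc[, "FSC-H"], pch = ".", col = "grey40",
                   xlab = "FSC-A", ylab = "FSC-H", main = tb)
    m <- tr$clean$doublet_model
    graphics::abline(m$intercept, m$slope, col = "red")
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
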