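# Shared fixtures.  Everything is generated in code; the trained model
# fixture is cached as JSON under tempdir() so the cost is paid once per
# test session.

fixture_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- load_panel()
  .fx$panel
}
.fx <- new.env(parent = emptyenv())
.fx$panel <- NULL

fixture_models <- function() {
  path <- file.path(tempdir(), "cg_test_models.json")
  if (!file.exists(path)) {
    trained <- train_from_synthetic(fixture_panel(), n_cases = 10,
                                    n_events = 3000, seed = 42, n_trees = 150)
    save_models(trained$models, path)
  }
  load_models(path)
}

fixture_case <- function(name = "NORMAL", n_events = 6000, seed = 7, ...) {
  make_case(scenario(name, n_events = n_events, seed = seed, ...),
            fixture_panel())
}

# A bare two-channel sample (one fluorescence channel plus TIME) for QC
# plumbing tests.
toy_sample <- function(n, values = NULL, seed = 1) {
  set.seed(seed)
  time <- sort(runif(n, 0, 100))
  v <- if (is.null(values)) rnorm(n) else values
  ev <- cbind(FL1 = v, TIME = time)
  cg_sample(ev, data.frame(name = c("FL1", "TIME"), stain = c("CD3", ""),
                           range = 1e6), time = time)
}

# Independent brute-force merger used as the oracle for merge_clusters:
# each round it recomputes adjacency and saddle densities from the raw
# kNN edge list and cluster codes from scratch, tests every pair, and
# merges the best-ratio qualifying pair (ties to the smallest id pair).
brute_force_merge <- function(seeds, marker_values, levels, rho_merge = 0.5) {
  assignment <- seeds$assignment
  dens <- seeds$density
  nn <- seeds$nn_index
  n <- length(assignment)
  edges_i <- rep.int(seq_len(n), ncol(nn))
  edges_j <- as.vector(nn)
  repeat {
    ids <- sort(unique(assignment))
    codes <- lapply(ids, function(c) {
      m <- marker_values[assignment == c, , drop = FALSE]
      vapply(colnames(m), function(mk)
        discretize(median(m[, mk]), levels[[mk]]), 1L)
    })
    names(codes) <- ids
    peaks <- vapply(ids, function(c) max(dens[assignment == c]), 1)
    names(peaks) <- ids
    best <- NULL; best_ratio <- rho_merge
    for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
      if (bi <= ai) next
      a <- ids[ai]; b <- ids[bi]
      cross <- (assignment[edges_i] == a & assignment[edges_j] == b) |
               (assignment[edges_i] == b & assignment[edges_j] == a)
      if (!any(cross)) next
      saddle <- max(pmin(dens[edges_i[cross]], dens[edges_j[cross]]))
      if (!all(codes[[as.character(a)]] == codes[[as.character(b)]])) next
      ratio <- saddle / min(peaks[as.character(a)], peaks[as.character(b)])
      if (ratio > best_ratio + 1e-12) { best <- c(a, b); best_ratio <- ratio }
    }
    if (is.null(best)) break
    assignment[assignment == best[2]] <- best[1]
  }
  match(assignment, sort(unique(assignment)))
}

# partitions are equal up to relabeling iff their contingency table is a
# permutation-like matrix (one nonzero block per row and column)
partition_equal <- function(a, b) {
  tb <- table(a, b) > 0
  all(rowSums(tb) == 1) && all(colSums(tb) == 1)
}

# Minimal subset table for report-layer tests.
mini_table <- function(lymph = 100000, t = 40000, dnt = 0, tube = "ALPS-T") {
  data.frame(
    subset = c("lymphocytes", "T cells", "TCRab+ DNT"),
    tube = tube, parent = c("", "lymphocytes", "DNT"),
    count = c(lymph, t, dnt),
    pct_of_parent = c(100, 100 * t / lymph, NA),
    pct_of_lymphs = c(100, 100 * t / lymph, 100 * dnt / lymph),
    secondary = FALSE, stringsAsFactors = FALSE
  )
}
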