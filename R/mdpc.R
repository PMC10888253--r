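# Density-phenotype coupled bottom-up clustering: five-level per-marker
# expression discretization, kNN density mode seeking, and cluster merging
# gated on both density continuity and phenotype identity.

#' Fit the five-level expression discretizer for one channel
#'
#' The negative mode `mu0` is the lowest-intensity major density mode of
#' the transformed intensities; its spread `sigma0` is the reflected MAD of
#' values at or below `mu0`.  The negative/dim boundary is
#' `b1 = mu0 + 2 sigma0`, and the interval from `b1` to the 99.9th
#' percentile is split into four equal-width bands giving `b2`, `b3`, `b4`
#' (dim, partial, positive, bright).  Channels with no dynamic range above
#' the negative mode collapse to all-negative with a warning.
#'
#' @param values transformed intensities for one channel (>= 1000 values).
#' @return a `cg_levels` object with `mu0`, `sigma0`, strictly increasing
#'   boundaries `b` (length 4) and a `degenerate` flag.
#' @export
fit_discretizer <- function(values) {
  if (length(values) < 1000)
    cg_stop("cg_data_error", "discretizer needs >= 1000 values (got %d)",
            length(values))
  rng <- diff(range(values))
  if (rng == 0) {
    warning("constant channel; expression levels collapse to negative")
    b1 <- values[1] + 1e-6
    return(structure(list(mu0 = values[1], sigma0 = 0,
                          b = b1 + (0:3) * 1e-6, degenerate = TRUE),
                     class = "cg_levels"))
  }
  d <- density(values, n = 512)
  y <- d$y; x <- d$x; k <- length(y)
  is_peak <- c(y[1] > y[2],
               y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
               y[k] > y[k - 1])
  major <- which(is_peak & y >= 0.05 * max(y))
  mu0 <- x[major[1]]

  lo <- values[values <= mu0]
  sigma0 <- 1.4826 * median(mu0 - lo)
  if (!is.finite(sigma0) || sigma0 == 0) sigma0 <- rng * 1e-3
  b1 <- mu0 + 2 * sigma0
  q999 <- quantile(values, 0.999, names = FALSE)
  if (q999 <= b1 + 1e-6 * rng) {
    warning("no dynamic range above the negative mode; levels collapse to negative")
    eps <- max(1e-6, rng * 1e-6)
    return(structure(list(mu0 = mu0, sigma0 = sigma0,
                          b = b1 + (0:3) * eps, degenerate = TRUE),
                     class = "cg_levels"))
  }
  w <- (q999 - b1) / 4
  structure(list(mu0 = mu0, sigma0 = sigma0, b = b1 + (0:3) * w,
                 degenerate = FALSE),
            class = "cg_levels")
}

#' Discretize intensities into the five-level scale
#'
#' Half-open bands: `(-Inf, b1)` negative, `[b1, b2)` dim, `[b2, b3)`
#' partial, `[b3, b4)` positive, `[b4, Inf)` bright.  A value equal to a
#' boundary belongs to the upper band (left-closed convention), and the
#' level index is non-decreasing in the value.
#'
#' @param values numeric vector on the transformed scale.
#' @param levels a [fit_discretizer()] result.
#' @param as_name return level names instead of indices 0-4.
#' @return integer levels 0-4 (or names).
#' @export
discretize <- function(values, levels, as_name = FALSE) {
  stopifnot(inherits(levels, "cg_levels"))
  idx <- findInterval(values, levels$b)
  if (as_name) cg_level_names[idx + 1L] else as.integer(idx)
}

#' Seed clusters by kNN density mode seeking
#'
#' Density is estimated as the inverse mean distance to the `k` nearest
#' neighbours over all dimensions concurrently.  Each event links to its
#' nearest strictly-higher-density neighbour within its k-neighbourhood
#' (ties broken by event index, so the result is deterministic and
#' duplication-invariant).  An event with no higher-density neighbour
#' among its k nearest is a peak candidate.  kNN density estimates
#' fluctuate, so a single population throws off spurious local peaks; a
#' candidate is therefore re-linked to its nearest higher-density point
#' anywhere when both conditions of the population-separation criterion
#' fail to hold: the fine-grained density profile along the straight
#' segment between them never dips below `root_rho` times the candidate's
#' density (no valley) and, when per-event phenotype codes are supplied,
#' the two events discretize identically on every marker.  A mode that
#' differs in phenotype or sits behind a real density valley survives,
#' however small its population.  Link-forest roots are density modes and
#' each tree is one seed cluster.  Clusters smaller than
#' `min_cluster_size` are dissolved into the nearest retained cluster by
#' centroid distance.
#'
#' @param X standardized event matrix (events x dimensions).
#' @param k neighbour count.
#' @param min_cluster_size smallest allowed seed cluster.
#' @param root_rho density-continuity threshold for peak candidates
#'   (default 0.5, matching the merge stage): a candidate can only be
#'   absorbed when the path density toward its nearest higher-density
#'   point never falls below this fraction of its own density.
#' @param event_codes optional integer matrix of per-event five-level
#'   marker codes; when given, a peak candidate is never absorbed into an
#'   event with a different phenotype code.
#' @return list with `assignment` (1..K per event), `density`, `nn_index`
#'   (n x k), `k`.
#' @export
seed_clusters <- function(X, k, min_cluster_size = 25, root_rho = 0.5,
                          event_codes = NULL) {
  n <- nrow(X)
  if (n < 2 * k) {
    return(list(assignment = rep(1L, n), density = rep(1, n),
                nn_index = NULL, k = k))
  }
  nn <- .cg_knn(X, as.integer(k))
  dens <- 1 / pmax(rowMeans(nn$nn.dist), 1e-12)

  idx <- nn$nn.index
  dmat <- matrix(dens[idx], nrow = n)
  self <- seq_len(n)
  higher <- (dmat > dens) | (dmat == dens & idx < self)
  first <- max.col(higher, ties.method = "first")
  has <- higher[cbind(self, first)]
  parent <- ifelse(has, idx[cbind(self, first)], 0L)

  # continuity pruning for peak candidates: walk the straight segment to
  # the nearest higher-density event; no density valley means the "peak"
  # is estimator noise inside one population and links onward
  cand <- which(parent == 0L)
  if (length(cand) > 1) {
    tX <- t(X)
    # a fine-grained density (small k) resolves valleys that the k-smoothed
    # estimate bridges when clusters are close relative to their kNN radius
    k_path <- max(5L, ceiling(k / 10))
    fine_density <- function(p) {
      d2 <- colSums((tX - p)^2)
      nearest <- sqrt(sort(d2, partial = k_path + 1)[seq_len(k_path + 1)])
      1 / max(mean(nearest[-1]), 1e-12)  # drop the point itself if present
    }
    ord <- order(-dens, self)
    rank_of <- integer(n); rank_of[ord] <- seq_len(n)
    for (i in cand) {
      if (rank_of[i] == 1L) next  # global density maximum
      better <- ord[seq_len(rank_of[i] - 1L)]
      d2 <- colSums((tX[, better, drop = FALSE] - X[i, ])^2)
      j <- better[which.min(d2)]
      if (!is.null(event_codes) &&
          !all(event_codes[i, ] == event_codes[j, ])) next
      steps <- seq(0.125, 0.875, by = 0.125)
      valley <- min(vapply(steps, function(t)
        fine_density((1 - t) * X[i, ] + t * X[j, ]), 1))
      if (valley >= root_rho * fine_density(X[i, ])) parent[i] <- j
    }
  }

  # resolve each event to its mode root; parents always have higher
  # priority, so processing in decreasing priority order suffices
  ord <- order(-dens, self)
  assignment <- integer(n)
  n_clusters <- 0L
  for (i in ord) {
    if (parent[i] == 0L) {
      n_clusters <- n_clusters + 1L
      assignment[i] <- n_clusters
    } else {
      assignment[i] <- assignment[parent[i]]
    }
  }

  # dissolve undersized clusters into the nearest retained centroid
  sizes <- tabulate(assignment, n_clusters)
  keep <- which(sizes >= min_cluster_size)
  if (length(keep) == 0) keep <- which.max(sizes)
  if (length(keep) < n_clusters) {
    cent <- rowsum(X, assignment) / sizes
    small <- assignment %in% setdiff(seq_len(n_clusters), keep)
    d2 <- outer(rowSums(cent[keep, , drop = FALSE]^2), rep(1, sum(small))) -
      2 * cent[keep, , drop = FALSE] %*% t(X[small, , drop = FALSE])
    assignment[small] <- keep[apply(d2, 2, which.min)]
  }
  relabel <- match(assignment, sort(unique(assignment)))
  list(assignment = as.integer(relabel), density = dens, nn_index = idx, k = k)
}

#' Phenotype code of a set of events
#'
#' The per-marker median of the member intensities, discretized through the
#' channel's five-level scale.
#'
#' @param values matrix of transformed marker intensities (members x
#'   markers, columns named).
#' @param levels named list of `cg_levels`, one per marker.
#' @return integer vector of levels 0-4, one per marker.
#' @export
phenotype_of <- function(values, levels) {
  vapply(colnames(values), function(m)
    discretize(median(values[, m]), levels[[m]]), 1L)
}

# Cross-cluster saddle densities from the kNN graph: for each unordered
# cluster pair, the maximum over cross edges of min(density_i, density_j).
saddle_matrix <- function(assignment, density, nn_index, n_clusters) {
  n <- nrow(nn_index); k <- ncol(nn_index)
  ii <- rep.int(seq_len(n), k)
  jj <- as.vector(nn_index)
  ca <- assignment[ii]; cb <- assignment[jj]
  cross <- ca != cb
  ca <- ca[cross]; cb <- cb[cross]
  ed <- pmin(density[ii[cross]], density[jj[cross]])
  a <- pmin(ca, cb); b <- pmax(ca, cb)
  key <- (a - 1L) * n_clusters + b
  agg <- tapply(ed, key, max)
  S <- matrix(0, n_clusters, n_clusters)
  keys <- as.integer(names(agg))
  ai <- (keys - 1L) %/% n_clusters + 1L
  bi <- keys - (ai - 1L) * n_clusters
  S[cbind(ai, bi)] <- agg
  S[cbind(bi, ai)] <- agg
  S
}

#' Merge seed clusters under density continuity and phenotype identity
#'
#' Two adjacent clusters merge only when (a) their five-level phenotype
#' codes agree on every marker and (b) the density saddle between them,
#' relative to the smaller peak density, exceeds `rho_merge` (a deep valley
#' blocks the merge even with identical phenotype).  Pairs are merged
#' best-first by saddle-to-peak ratio; codes are recomputed after every
#' merge and the process stops when no pair qualifies.
#'
#' @param seeds a [seed_clusters()] result.
#' @param marker_values transformed marker matrix for the same events.
#' @param levels named list of per-marker `cg_levels`.
#' @param rho_merge saddle-to-peak threshold in (0, 1] (default 0.5).
#' @return list with final `assignment`, per-cluster `codes` matrix,
#'   `peaks`, and the merge `history`.
#' @export
merge_clusters <- function(seeds, marker_values, levels, rho_merge = 0.5) {
  assignment <- seeds$assignment
  K <- max(assignment)
  if (K == 1 || is.null(seeds$nn_index)) {
    codes <- t(vapply(seq_len(K), function(c)
      phenotype_of(marker_values[assignment == c, , drop = FALSE], levels),
      integer(ncol(marker_values))))
    return(list(assignment = assignment, codes = codes,
                peaks = vapply(split(seeds$density, assignment), max, 1),
                history = data.frame()))
  }
  dens <- seeds$density
  S <- saddle_matrix(assignment, dens, seeds$nn_index, K)
  peaks <- vapply(split(dens, assignment), max, 1)
  codes <- t(vapply(seq_len(K), function(c)
    phenotype_of(marker_values[assignment == c, , drop = FALSE], levels),
    integer(ncol(marker_values))))
  alive <- rep(TRUE, K)
  history <- list()

  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    best <- NULL; best_ratio <- rho_merge
    for (ai in seq_along(live)[-length(live)]) {
      a <- live[ai]
      for (b in live[(ai + 1):length(live)]) {
        if (S[a, b] <= 0) next
        if (!all(codes[a, ] == codes[b, ])) next
        ratio <- S[a, b] / min(peaks[a], peaks[b])
        if (ratio > best_ratio + 1e-12) { best <- c(a, b); best_ratio <- ratio }
      }
    }
    if (is.null(best)) break
    a <- best[1]; b <- best[2]
    assignment[assignment == b] <- a
    S[a, ] <- pmax(S[a, ], S[b, ]); S[, a] <- S[a, ]
    S[a, a] <- 0
    peaks[a] <- max(peaks[a], peaks[b])
    codes[a, ] <- phenotype_of(marker_values[assignment == a, , drop = FALSE], levels)
    alive[b] <- FALSE
    history[[length(history) + 1]] <- c(into = a, from = b, ratio = best_ratio)
  }

  relabel <- match(assignment, sort(unique(assignment)))
  final <- sort(unique(assignment))
  list(assignment = as.integer(relabel),
       codes = codes[final, , drop = FALSE],
       peaks = peaks[final],
       history = if (length(history)) as.data.frame(do.call(rbind, history))
                 else data.frame())
}

#' Cluster a cleaned sample
#'
#' Orchestrates the automatic gating engine on a pre-gated sample:
#' per-channel five-level discretizers, kNN density seed clustering over
#' all fluorescence markers (on the shared asinh scale) plus FSC-A/SSC-A
#' (rescaled to a comparable unit), and phenotype-gated density merging.  Deterministic given
#' parameters and input order; samples larger than `max_events` are
#' clustered on a fixed-seed uniform subsample and remaining events join
#' the nearest cluster centroid.
#'
#' @param clean a [pregate()] result (sample must be tube-matched and
#'   transformed).
#' @param tube the `cg_tube`.
#' @param params optional overrides: `k_max` (default 100), `rho_merge`
#'   (0.5), `min_cluster_frac` (0.001), `min_cluster_abs` (25),
#'   `max_events` (50000), `subsample_seed` (1).
#' @return a `cg_clusters` object.
#' @export
cluster_events <- function(clean, tube, params = list()) {
  p <- modifyList(list(k_max = 100, rho_merge = 0.5, min_cluster_frac = 0.001,
                       min_cluster_abs = 25, max_events = 50000,
                       subsample_seed = 1), params)
  sample <- clean$sample
  if (!sample$transformed)
    cg_stop("cg_state_error", "cluster_events expects a transformed sample")
  M <- marker_matrix(sample)
  sc <- scatter_columns(sample, tube)
  n <- nrow(M)

  # Distance space: fluorescence channels already share the asinh scale
  # (population separations of ~3-5 units against ~0.3-unit spreads), so
  # they enter as-is; scatter is rescaled to a comparable unit.  Per-channel
  # median/MAD standardization is deliberately avoided: mixture channels
  # have inflated MADs (compressing real separation) while blank channels
  # have noise-sized MADs (inflating noise).
  scatter_unit <- function(v) {
    u <- quantile(v, 0.95, names = FALSE) / 6
    if (u <= 0) u <- max(sd(v), 1)
    v / u
  }
  X <- cbind(M, fsc_a = scatter_unit(sc[, "fsc_a"]),
             ssc_a = scatter_unit(sc[, "ssc_a"]))

  levels <- lapply(colnames(M), function(m) fit_discretizer(M[, m]))
  names(levels) <- colnames(M)

  sub <- seq_len(n)
  if (n > p$max_events)
    sub <- sort(with_seed(p$subsample_seed, sample.int(n, p$max_events)))

  k <- min(p$k_max, ceiling(sqrt(length(sub))))
  min_size <- max(p$min_cluster_abs, ceiling(p$min_cluster_frac * length(sub)))
  event_codes <- vapply(colnames(M), function(m) discretize(M[sub, m], levels[[m]]),
                        integer(length(sub)))
  seeds <- seed_clusters(X[sub, , drop = FALSE], k, min_cluster_size = min_size,
                         event_codes = event_codes)
  merged <- merge_clusters(seeds, M[sub, , drop = FALSE], levels,
                           rho_merge = p$rho_merge)

  assignment <- integer(n)
  assignment[sub] <- merged$assignment
  K <- max(merged$assignment)
  if (length(sub) < n) {
    cent <- rowsum(X[sub, , drop = FALSE], merged$assignment) /
      tabulate(merged$assignment, K)
    rest <- setdiff(seq_len(n), sub)
    d2 <- outer(rowSums(cent^2), rep(1, length(rest))) -
      2 * cent %*% t(X[rest, , drop = FALSE])
    assignment[rest] <- apply(d2, 2, which.min)
  }

  # final cluster statistics over all members
  sizes <- tabulate(assignment, K)
  medians <- t(vapply(seq_len(K), function(c)
    apply(M[assignment == c, , drop = FALSE], 2, median),
    numeric(ncol(M))))
  colnames(medians) <- colnames(M)
  codes <- t(vapply(seq_len(K), function(c)
    vapply(colnames(M), function(m) discretize(medians[c, m], levels[[m]]), 1L),
    integer(ncol(M))))
  colnames(codes) <- colnames(M)

  clusters <- data.frame(
    id = seq_len(K),
    size = sizes,
    frac = sizes / n,
    peak_density = merged$peaks,
    fsc_med = vapply(seq_len(K), function(c) median(sc[assignment == c, "fsc_a"]), 1),
    ssc_med = vapply(seq_len(K), function(c) median(sc[assignment == c, "ssc_a"]), 1),
    code = apply(codes, 1, function(r)
      paste(paste0(colnames(M), ":", substr(cg_level_names[r + 1], 1, 3)),
            collapse = "|"))
  )

  structure(list(
    assignment = assignment,
    clusters = clusters,
    medians = medians,
    codes = codes,
    levels = levels,
    markers = colnames(M),
    scatter_q95 = c(fsc = quantile(sc[, "fsc_a"], 0.95, names = FALSE),
                    ssc = quantile(sc[, "ssc_a"], 0.95, names = FALSE)),
    params = p
  ), class = "cg_clusters")
}

#' Export a cluster set as tables
#'
#' @param clusters a `cg_clusters`.
#' @param dir output directory; writes `clusters.csv` (event index, cluster
#'   id) and `cluster_summary.csv`.
#' @return the directory, invisibly.
#' @export
export_clusters <- function(clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(event = seq_along(clusters$assignment),
                       cluster = clusters$assignment),
            file.path(dir, "clusters.csv"), row.names = FALSE)
  write.csv(cbind(clusters$clusters,
                  as.data.frame(clusters$medians)),
            file.path(dir, "cluster_summary.csv"), row.names = FALSE)
  invisible(dir)
}
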