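test_that("discretizer recovers the negative mode of a two-Gaussian channel", {
  set.seed(51)
  x <- c(rnorm(5000, 0, 0.1), rnorm(5000, 4, 0.3))
  lv <- fit_discretizer(x)
  # the negative mode sits at 0 with spread 0.1, so b1 = mu0 + 2 sigma0
  # is about 0.2
  expect_equal(lv$b[1], 0.2, tolerance = 0.1)
  expect_true(discretize(4.0, lv) >= 3)  # positive or bright
  expect_false(lv$degenerate)
})

test_that("discretizer boundaries shift with the data (translation equivariance)", {
  set.seed(52)
  x <- c(rnorm(3000, 0, 0.2), rnorm(2000, 3, 0.3))
  lv <- fit_discretizer(x)
  lv_shift <- fit_discretizer(x + 1.5)
  expect_equal(lv_shift$b, lv$b + 1.5, tolerance = 0.05)
})

test_that("degenerate channels collapse to negative with a warning", {
  expect_warning(lv <- fit_discretizer(rep(2.5, 1500)))
  expect_true(lv$degenerate)
  expect_true(all(diff(lv$b) > 0))
  expect_equal(discretize(2.5, lv), 0L)
})

test_that("five half-open bands with a left-closed boundary convention", {
  set.seed(53)
  x <- c(rnorm(3000, 0, 0.2), rnorm(3000, 4, 0.4))
  lv <- fit_discretizer(x)
  expect_length(lv$b, 4)
  expect_true(all(diff(lv$b) > 0))
  expect_equal(cg_level_names,
               c("negative", "dim", "partial", "positive", "bright"))
  expect_equal(discretize(lv$b[1], lv), 1L)             # boundary -> upper band
  expect_equal(discretize(lv$b[1] - 1e-9, lv), 0L)
  probes <- sort(runif(1000, min(x) - 1, max(x) + 1))
  lev <- discretize(probes, lv)
  expect_true(all(diff(lev) >= 0))
})

test_that("seed clustering separates two Gaussians and partitions everything", {
  set.seed(54)
  X <- rbind(matrix(rnorm(5000 * 3, 0, 0.3), ncol = 3),
             matrix(rnorm(5000 * 3, 4, 0.3), ncol = 3))
  truth <- rep(1:2, each = 5000)
  seeds <- seed_clusters(X, k = 60, min_cluster_size = 50)
  expect_equal(max(seeds$assignment), 2)
  expect_true(partition_equal(seeds$assignment, truth) ||
              mean(seeds$assignment[1:5000] == seeds$assignment[1]) > 0.99)
  acc <- max(mean(seeds$assignment == truth), mean(seeds$assignment == 3 - truth))
  expect_gte(acc, 0.99)

  U <- matrix(runif(1000 * 3), ncol = 3)
  su <- seed_clusters(U, k = 30, min_cluster_size = 25)
  expect_gte(max(su$assignment), 1)
  expect_true(all(su$assignment >= 1))
  expect_length(su$assignment, 1000)
})

test_that("duplicating a dataset preserves the merged cluster structure", {
  set.seed(55)
  # tight modes placed mid-band, so fragment medians discretize stably
  X <- rbind(matrix(rnorm(800 * 2, 0, 0.15), ncol = 2),
             matrix(rnorm(800 * 2, 4, 0.15), ncol = 2))
  colnames(X) <- c("M1", "M2")
  run <- function(M, k, min_size) {
    lv <- lapply(colnames(M), function(m) fit_discretizer(M[, m]))
    names(lv) <- colnames(M)
    seeds <- seed_clusters(M, k = k, min_cluster_size = min_size)
    merge_clusters(seeds, M, lv, rho_merge = 0.5)
  }
  # doubling every event halves the effective neighbour count, so the
  # duplicated run uses 2k; mode noise differs event-wise but the merged
  # population structure is identical
  m1 <- run(X, k = 20, min_size = 30)
  m2 <- run(rbind(X, X), k = 40, min_size = 60)
  expect_equal(max(m2$assignment), max(m1$assignment))
  expect_true(partition_equal(m2$assignment[seq_len(nrow(X))],
                              m1$assignment))
})

test_that("phenotype codes are member medians pushed through the levels", {
  set.seed(56)
  x <- c(rnorm(2000, 0, 0.2), rnorm(2000, 4.5, 0.3))
  lv <- list(CD3 = fit_discretizer(x))
  vals <- matrix(rnorm(50, 4.5, 0.3), ncol = 1, dimnames = list(NULL, "CD3"))
  expect_gte(phenotype_of(vals, lv)[["CD3"]], 3)
  one <- matrix(0.05, 1, 1, dimnames = list(NULL, "CD3"))
  expect_equal(phenotype_of(one, lv)[["CD3"]], discretize(0.05, lv$CD3))
  expect_equal(phenotype_of(rbind(vals, vals), lv), phenotype_of(vals, lv))
})

merge_instance <- function(seed, n_modes, n_per = 450, sep = 3) {
  set.seed(seed)
  centers <- matrix(sample(0:1, n_modes * 3, replace = TRUE) * sep +
                      rnorm(n_modes * 3, 0, 0.6), ncol = 3)
  X <- do.call(rbind, lapply(seq_len(n_modes), function(i)
    sweep(matrix(rnorm(n_per * 3, 0, 0.45), ncol = 3), 2, centers[i, ], `+`)))
  colnames(X) <- c("M1", "M2", "M3")
  # a draw where all centers tie on one axis gives a rangeless channel
  levels <- suppressWarnings(
    lapply(colnames(X), function(m) fit_discretizer(X[, m])))
  names(levels) <- colnames(X)
  seeds <- seed_clusters(X, k = 30, min_cluster_size = 20)
  list(X = X, levels = levels, seeds = seeds)
}

test_that("merge agrees with the brute-force pairwise oracle on random instances", {
  for (seed in c(61, 62, 63, 64, 65, 66)) {
    inst <- merge_instance(seed, n_modes = sample(3:6, 1))
    if (max(inst$seeds$assignment) > 8 || is.null(inst$seeds$nn_index)) next
    fast <- merge_clusters(inst$seeds, inst$X, inst$levels, rho_merge = 0.5)
    slow <- brute_force_merge(inst$seeds, inst$X, inst$levels, rho_merge = 0.5)
    expect_true(partition_equal(fast$assignment, slow), label =
                  sprintf("oracle equivalence on instance %d", seed))
  }
})

test_that("over-seeded single Gaussian merges; distinct phenotypes never merge", {
  set.seed(71)
  X <- matrix(rnorm(3000 * 2, 1.5, 0.15), ncol = 2,
              dimnames = list(NULL, c("M1", "M2")))
  # force over-seeding with a tiny neighbourhood
  seeds <- seed_clusters(X, k = 12, min_cluster_size = 15)
  lv <- lapply(colnames(X), function(m) fit_discretizer(c(X[, m], rnorm(2000, -2, 0.3))))
  names(lv) <- colnames(X)
  merged <- merge_clusters(seeds, X, lv, rho_merge = 0.3)
  expect_equal(max(merged$assignment), 1)

  # two populations differing in M1's band must stay apart at any density
  set.seed(72)
  Y <- rbind(matrix(c(rnorm(1500, 0, 0.25), rnorm(1500, 2, 0.25)), ncol = 2),
             matrix(c(rnorm(1500, 4.5, 0.25), rnorm(1500, 2, 0.25)), ncol = 2))
  colnames(Y) <- c("M1", "M2")
  lvy <- lapply(colnames(Y), function(m) fit_discretizer(Y[, m]))
  names(lvy) <- colnames(Y)
  sy <- seed_clusters(Y, k = 40, min_cluster_size = 25)
  my <- merge_clusters(sy, Y, lvy, rho_merge = 0.01)
  codes <- my$codes
  expect_gte(max(my$assignment), 2)
  expect_false(any(duplicated(apply(codes, 1, paste, collapse = ","))))
})

test_that("raising rho_merge never decreases the final cluster count", {
  inst <- merge_instance(73, n_modes = 4)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8), function(rho)
    max(merge_clusters(inst$seeds, inst$X, inst$levels, rho_merge = rho)$assignment),
    1)
  expect_true(all(diff(counts) >= 0))
})

test_that("full clustering recovers the simulated populations deterministically", {
  case <- fixture_case(n_events = 10000, seed = 74,
                       doublet_rate = 0, debris_rate = 0)
  panel <- fixture_panel()
  tube <- panel$tubes[["ALPS-T"]]
  s <- match_tube(apply_transform(case$samples[["ALPS-T"]]), panel)
  clean <- pregate(s, tube)
  cl <- cluster_events(clean, tube)

  expect_gte(nrow(cl$clusters), 6)
  expect_lte(nrow(cl$clusters), 14)
  expect_equal(sum(cl$clusters$size), sum(clean$mask))

  pop <- case$truth[["ALPS-T"]]$population[clean$mask]
  for (p in unique(pop)) {
    if (mean(pop == p) < 0.02) next
    tab <- table(cl$assignment[pop == p])
    main <- as.integer(names(which.max(tab)))
    purity <- max(tab) / sum(cl$assignment == main)
    expect_gte(purity, 0.80)
  }

  # determinism: identical rerun, and permutation-invariant partition
  cl2 <- cluster_events(clean, tube)
  expect_identical(cl$assignment, cl2$assignment)
  set.seed(75)
  perm <- sample(nrow(clean$sample$events))
  clean_p <- clean
  clean_p$sample$events <- clean$sample$events[perm, ]
  cl3 <- cluster_events(clean_p, tube)
  expect_true(partition_equal(cl$assignment[perm], cl3$assignment))
})
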