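cluster_fixture <- function(tube_name = "ALPS-T", n = 6000, seed = 81) {
  panel <- fixture_panel()
  case <- fixture_case(n_events = n, seed = seed)
  s <- match_tube(apply_transform(case$samples[[tube_name]]), panel)
  tube <- panel$tubes[[tube_name]]
  clean <- pregate(s, tube)
  list(clusters = cluster_events(clean, tube), tube = tube, panel = panel,
       clean = clean, truth = case$truth[[tube_name]])
}

test_that("cluster features are keyed by sorted marker name", {
  fx <- cluster_fixture()
  X <- featurize(fx$clusters, fx$tube)
  markers <- sort(fx$tube$channels$marker_norm)
  expect_equal(colnames(X),
               c(rbind(paste0("med_", markers), paste0("lvl_", markers)),
                 "frac", "fsc_med", "ssc_med"))
  expect_equal(nrow(X), nrow(fx$clusters$clusters))
  expect_equal(sum(X[, "frac"]), 1, tolerance = 1e-12)

  # a cluster set missing a tube marker is a hard error, never a silent zero
  broken <- fx$clusters
  broken$markers <- setdiff(broken$markers, "CD4")
  broken$medians <- broken$medians[, broken$markers]
  broken$codes <- broken$codes[, broken$markers]
  expect_error(featurize(broken, fx$tube), class = "cg_feature_error")
})

test_that("features and predictions transfer across fluorochrome/channel relabeling", {
  panel <- fixture_panel()
  models <- fixture_models()
  case <- fixture_case(n_events = 5000, seed = 82)
  s <- case$samples[["ALPS-T"]]

  # same stains, new detector names and fluorochromes, permuted channels
  perm <- c(5, 3, 1, 2, 4, 8, 6, 7, 9, 12, 10, 11, 13)
  ch2 <- s$channels[perm, ]
  ch2$name <- ifelse(nzchar(ch2$stain), paste0("DET", seq_len(nrow(ch2))), ch2$name)
  s2 <- cg_sample(`colnames<-`(s$events[, perm], ch2$name), ch2, time = s$time)

  run <- function(sample) {
    m <- match_tube(apply_transform(sample), panel)
    tube <- panel$tubes[[m$tube]]
    clean <- pregate(m, tube)
    cl <- cluster_events(clean, tube)
    f <- featurize(cl, tube)
    list(f = f, pred = classify_clusters(models[[m$tube]], f))
  }
  a <- run(s); b <- run(s2)
  expect_equal(unname(a$f), unname(b$f))
  expect_equal(a$pred, b$pred)
})

test_that("training requires two labels with five examples each, then is reproducible", {
  panel <- fixture_panel()
  store <- new_store(panel)
  fx <- cluster_fixture()
  X <- featurize(fx$clusters, fx$tube)

  one_label <- update_store(store, "ALPS-T", X[rep(1, 6), , drop = FALSE],
                            rep("T cells", 6))
  expect_error(train_classifier(one_label, "ALPS-T"),
               class = "cg_training_error")
  thin <- update_store(one_label, "ALPS-T", X[rep(1, 2), , drop = FALSE],
                       rep("B cells", 2))
  err <- tryCatch(train_classifier(thin, "ALPS-T"), error = identity)
  expect_s3_class(err, "cg_training_error")
  expect_match(conditionMessage(err), "B cells")

  trained <- train_from_synthetic(panel, n_cases = 10, n_events = 2500,
                                  seed = 9, n_trees = 100)
  expect_gte(trained$models[["ALPS-T"]]$oob_accuracy, 0.95)

  again <- train_from_synthetic(panel, n_cases = 10, n_events = 2500,
                                seed = 9, n_trees = 100)
  p1 <- classify_clusters(trained$models[["ALPS-T"]], X)
  p2 <- classify_clusters(again$models[["ALPS-T"]], X)
  expect_identical(p1, p2)
})

test_that("prediction probabilities are proper and flag ambiguity", {
  models <- fixture_models()
  fx <- cluster_fixture()
  X <- featurize(fx$clusters, fx$tube)
  m <- models[["ALPS-T"]]
  prob <- predict(m$forest, X)
  expect_equal(unname(rowSums(prob)), rep(1, nrow(X)))
  pred <- classify_clusters(m, X)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))

  # engineered midpoint between two training templates is low confidence
  t_row <- X[which.max(fx$clusters$medians[, "CD3"]), ]
  nk_row <- X[which.min(fx$clusters$medians[, "CD3"] +
                          fx$clusters$medians[, "CD19"]), ]
  mid <- (t_row + nk_row) / 2
  Xmid <- matrix(mid, 1, dimnames = list("1", names(mid)))
  pm <- classify_clusters(m, Xmid)
  expect_true(pm$low_confidence || pm$probability < 0.95)

  empty <- X[0, , drop = FALSE]
  expect_equal(nrow(classify_clusters(m, empty)), 0)

  wrong <- X[, rev(seq_len(ncol(X)))]
  expect_error(classify_clusters(m, wrong), class = "cg_feature_error")
})

test_that("the store is append-only, vocabulary-checked and serializable", {
  panel <- fixture_panel()
  store <- new_store(panel)
  fx <- cluster_fixture()
  X <- featurize(fx$clusters, fx$tube)
  labels <- rep(c("T cells", "B cells"), length.out = nrow(X))

  s1 <- update_store(store, "ALPS-T", X, labels, case_id = "c1")
  expect_equal(store_size(s1)[["ALPS-T"]], nrow(X))
  s2 <- update_store(s1, "ALPS-T", X, labels, case_id = "c2")
  expect_equal(store_size(s2)[["ALPS-T"]], 2 * nrow(X))
  expect_identical(s2$entries[["ALPS-T"]]$features[seq_len(nrow(X)), ],
                   s1$entries[["ALPS-T"]]$features)

  expect_error(update_store(s1, "ALPS-T", X, rep("plasma cells", nrow(X))),
               class = "cg_vocab_error")

  f <- tempfile(fileext = ".json")
  save_store(s2, f)
  back <- load_store(f)
  expect_equal(back$vocab, s2$vocab)
  expect_equal(back$entries[["ALPS-T"]]$labels, s2$entries[["ALPS-T"]]$labels)
  expect_equal(back$entries[["ALPS-T"]]$features, s2$entries[["ALPS-T"]]$features)
})

test_that("rule refinement assigns diagnostic subsets from phenotype codes", {
  panel <- fixture_panel()
  tube <- panel$tubes[["ALPS-T"]]
  markers <- tube$channels$marker_norm

  code_for <- function(levels) {
    v <- setNames(rep(0L, length(markers)), markers)
    v[names(levels)] <- as.integer(levels)
    v
  }
  codes <- rbind(
    code_for(c(CD3 = 4, TCRAB = 3)),                    # DNT, TCRab+
    code_for(c(CD3 = 4, CD4 = 3, CD25 = 3)),            # CD4 T (CD127 neg -> Treg-like)
    code_for(c(CD3 = 4, CD4 = 2, CD8 = 2))              # T with no subset match
  )
  fake <- structure(list(
    assignment = rep(1:3, times = c(50, 30, 20)),
    clusters = data.frame(id = 1:3, size = c(50, 30, 20), frac = c(.5, .3, .2),
                          peak_density = 1, fsc_med = 1, ssc_med = 1, code = ""),
    medians = codes * 0, codes = codes, levels = list(),
    markers = markers, scatter_q95 = c(fsc = 1, ssc = 1), params = list()
  ), class = "cg_clusters")

  labels <- refine_subsets(fake, rep("T cells", 3), tube, panel)
  expect_equal(labels$clusters$deepest,
               c("TCRab+ DNT", "Treg-like", "T cells"))
  expect_true("DNT" %in% labels$paths[[1]])

  # switched memory B in the ALPS-B tube
  tube_b <- panel$tubes[["ALPS-B"]]
  mb <- tube_b$channels$marker_norm
  cb <- setNames(rep(0L, length(mb)), mb)
  cb[c("CD19", "CD27", "KAPPA")] <- 3L
  fake_b <- fake
  fake_b$markers <- mb
  fake_b$codes <- rbind(cb, cb, cb)
  labels_b <- refine_subsets(fake_b, rep("B cells", 3), tube_b, panel)
  expect_equal(labels_b$clusters$deepest[1], "switched memory B cells")
  expect_true("kappa+ B cells" %in% labels_b$secondary[[1]])
})

test_that("event labels conserve counts and roll up to parents exactly", {
  panel <- fixture_panel()
  models <- fixture_models()
  case <- fixture_case(n_events = 6000, seed = 83)
  res <- analyze_case(case$samples, panel, models, case_id = "rollup")
  for (tb in names(res$tube_results)) {
    tab <- res$tube_results[[tb]]$table
    prim <- tab[!tab$secondary, ]
    for (parent in unique(prim$parent)) {
      if (parent == "") next
      kids <- prim[prim$parent == parent, ]
      pc <- prim$count[prim$subset == parent]
      if (length(pc) == 1)
        expect_lte(sum(kids$count), pc)
    }
    # percentages recompute from counts
    lymph <- tab$count[tab$subset == "lymphocytes"]
    expect_equal(tab$pct_of_lymphs, 100 * tab$count / lymph, tolerance = 1e-9)
  }
})
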