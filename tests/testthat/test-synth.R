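test_that("simulated population fractions respect the specification", {
  panel <- fixture_panel()
  tube <- panel$tubes[["ALPS-T"]]
  templates <- default_templates()[["ALPS-T"]]
  ab <- c(cd4_t = 0.32, cd8_t = 0.18, dnt_ab = 0.01, gd_t = 0.03,
          treg = 0.03, b = 0.12, nk = 0.10, mono = 0.21)
  sim <- simulate_tube(tube, templates, ab, n = 10000, seed = 101)
  frac <- table(sim$truth$population) / 10000
  for (p in names(ab)) {
    se <- sqrt(ab[[p]] * (1 - ab[[p]]) / 10000)
    expect_lt(abs(frac[[p]] - ab[[p]]), 3 * se + 1e-9)
  }
  # reproducibility is bit-exact; different seeds differ
  sim2 <- simulate_tube(tube, templates, ab, n = 10000, seed = 101)
  expect_identical(sim$sample$events, sim2$sample$events)
  sim3 <- simulate_tube(tube, templates, ab, n = 10000, seed = 102)
  expect_false(identical(sim$sample$events, sim3$sample$events))

  expect_error(simulate_tube(tube, templates, ab * 0.9, n = 100, seed = 1),
               class = "cg_config_error")
  one <- ab * 0; one["b"] <- 1
  simb <- simulate_tube(tube, templates, one, n = 500, seed = 1)
  expect_true(all(simb$truth$population == "b"))
})

test_that("doublet injection: exact count, construction geometry, invertibility", {
  panel <- fixture_panel()
  tube <- panel$tubes[["ALPS-T"]]
  templates <- default_templates()[["ALPS-T"]]
  ab <- c(cd4_t = 0.6, cd8_t = 0.4, dnt_ab = 0, gd_t = 0, treg = 0,
          b = 0, nk = 0, mono = 0)
  sim <- simulate_tube(tube, templates, ab, n = 20000, seed = 103)
  pre <- sort(sim$sample$events[, "FSC-A"])

  inj <- inject_doublets(sim, rate = 0.05, seed = 104)
  expect_equal(sum(inj$truth$artifact == "doublet"), 1000)
  expect_equal(nrow(inj$sample$events), 21000)

  d <- inj$truth$artifact == "doublet"
  ratio <- inj$sample$events[, "FSC-A"] / inj$sample$events[, "FSC-H"]
  expect_gte(mean(ratio[d]) / mean(ratio[!d]), 1.5)

  # masking tagged events recovers the pre-injection sample exactly
  expect_equal(sort(inj$sample$events[!d, "FSC-A"]), pre)
  expect_identical(inject_doublets(sim, rate = 0, seed = 1), sim)
})

test_that("debris injection sits far below the leukocyte scatter", {
  sim0 <- make_case(scenario("NORMAL", n_events = 5000, seed = 105,
                             doublet_rate = 0, debris_rate = 0),
                    fixture_panel())
  sim <- list(sample = sim0$samples[["ALPS-T"]], truth = sim0$truth[["ALPS-T"]])
  inj <- inject_debris(sim, rate = 0.08, seed = 106)
  d <- inj$truth$artifact == "debris"
  expect_equal(sum(d), 400)
  expect_lt(quantile(inj$sample$events[d, "FSC-A"], 0.95),
            quantile(inj$sample$events[!d, "FSC-A"], 0.05))
  expect_equal(sort(inj$sample$events[!d, "SSC-A"]),
               sort(sim$sample$events[, "SSC-A"]))
})

test_that("drift injection doubles the windowed raw signal and tags it", {
  sim0 <- make_case(scenario("NORMAL", n_events = 8000, seed = 107,
                             doublet_rate = 0, debris_rate = 0),
                    fixture_panel())
  sim <- list(sample = sim0$samples[["ALPS-T"]], truth = sim0$truth[["ALPS-T"]])
  inj <- inject_drift(sim, window = 0.1, gain = 2, channel = "CD45", seed = 108)
  d <- inj$truth$artifact == "drift"
  expect_equal(mean(d), 0.1, tolerance = 0.05)

  ci <- match("CD45", normalize_marker(inj$sample$channels$stain))
  expect_gte(median(inj$sample$events[d, ci]) /
               median(inj$sample$events[!d, ci]), 1.5)

  expect_identical(inject_drift(sim, window = 0.1, gain = 1,
                                channel = "CD45", seed = 1), sim)
})

test_that("templated levels are recovered by the discretizer geometry", {
  case <- fixture_case(n_events = 10000, seed = 109,
                       doublet_rate = 0, debris_rate = 0)
  panel <- fixture_panel()
  s <- match_tube(apply_transform(case$samples[["ALPS-T"]]), panel)
  M <- cytogate:::marker_matrix(s)
  truth <- case$truth[["ALPS-T"]]
  templates <- default_templates()[["ALPS-T"]]
  # the absolute five-level geometry is anchored at the negative mode, so
  # only channels with a sizeable negative population are checked (CD45 has
  # none by design: every leukocyte expresses it)
  frac <- table(truth$population) / nrow(truth)
  anchored <- function(mk) {
    neg <- vapply(templates, function(t) {
      l <- unname(t$levels[mk])
      (is.na(l) || l == 0) && frac[[t$name]] >= 0.05
    }, TRUE)
    any(neg)
  }
  for (tp in templates) {
    rows <- truth$population == tp$name
    if (sum(rows) < 200) next
    for (mk in names(tp$levels)) {
      if (!anchored(mk)) next
      lv <- fit_discretizer(M[, mk])
      if (lv$degenerate) next
      got <- discretize(M[rows, mk], lv)
      expect_gte(mean(abs(got - tp$levels[[mk]]) <= 1), 0.90)
    }
  }
})

test_that("scenario worlds satisfy their stated invariants", {
  panel <- fixture_panel()
  alps <- make_case(scenario("ALPS", n_events = 4000, seed = 110), panel)
  tt <- alps$truth_tables[["ALPS-T"]]
  dnt <- tt$count[tt$subset == "TCRab+ DNT"]
  tcells <- tt$count[tt$subset == "T cells"]
  expect_gte(100 * dnt / tcells, 10)

  xla_sc <- scenario("XLA", n_events = 4000, seed = 111)
  ab <- xla_sc$abundances[["ALPS-B"]]
  b_ab <- sum(ab[grep("_b_", names(ab))])
  lymph_ab <- 1 - ab[["mono"]]
  expect_lte(100 * b_ab / lymph_ab, 0.05)  # the stated world
  xla <- make_case(xla_sc, panel)
  tb <- xla$truth_tables[["ALPS-B"]]
  expect_lte(tb$pct_of_lymphs[tb$subset == "B cells"], 0.15)  # binomial noise at n = 4000

  dig <- make_case(scenario("DIGEORGE", n_events = 6000, seed = 112), panel)
  ta <- dig$truth_tables[["ACT-T"]]
  ra_pct <- 100 * ta$count[ta$subset == "CD45RA+ T cells"] /
    ta$count[ta$subset == "T cells"]
  expect_lte(ra_pct, 10)
  bb <- dig$truth_tables[["ALPS-B"]]
  swb_pct <- 100 * bb$count[bb$subset == "switched memory B cells"] /
    bb$count[bb$subset == "B cells"]
  expect_lte(swb_pct, 2.5)

  # distinct seeds give distinct cases under one specification
  seeds <- lapply(1:3, function(i)
    make_case(scenario("NORMAL", n_events = 1000, seed = i), panel))
  evs <- lapply(seeds, function(c) c$samples[["ALPS-T"]]$events)
  expect_false(identical(evs[[1]], evs[[2]]))
  expect_false(identical(evs[[2]], evs[[3]]))

  expect_error(scenario("ALPS", dnt_of_t = 0.05), class = "cg_config_error")
})

test_that("written cases produce readable FCS files and truth CSVs", {
  case <- fixture_case(n_events = 1200, seed = 113)
  dir <- tempfile("case_out")
  write_case(case, dir, case_id = "demo")
  fcs <- list.files(dir, pattern = "\\.fcs$")
  expect_length(fcs, 3)
  expect_length(list.files(dir, pattern = "truth\\.csv$"), 3)
  expect_true(file.exists(file.path(dir, "demo_manifest.yaml")))
  back <- read_fcs(file.path(dir, fcs[1]))
  expect_gt(nrow(back$events), 1200 * 0.99)
})
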