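test_that("subset enumeration arithmetic and empty-lineage handling", {
  panel <- fixture_panel()
  tube <- panel$tubes[["ALPS-T"]]
  markers <- tube$channels$marker_norm
  blank <- matrix(0L, 3, length(markers), dimnames = list(NULL, markers))
  blank[1, c("CD3", "CD4")] <- c(4L, 3L)
  blank[2, "CD3"] <- 4L
  blank[2, "CD8"] <- 3L
  fake <- structure(list(
    assignment = rep(1:3, times = c(210, 490, 300)),
    clusters = data.frame(id = 1:3, size = c(210, 490, 300),
                          frac = c(.21, .49, .30), peak_density = 1,
                          fsc_med = 1, ssc_med = 1, code = ""),
    medians = blank * 0, codes = blank, levels = list(),
    markers = markers, scatter_q95 = c(fsc = 1, ssc = 1), params = list()
  ), class = "cg_clusters")
  labels <- refine_subsets(fake, c("T cells", "T cells", "NK cells"),
                           tube, panel)
  tab <- enumerate_subsets(labels, panel)

  expect_equal(tab$count[tab$subset == "lymphocytes"], 1000)
  expect_equal(tab$count[tab$subset == "T cells"], 700)
  expect_equal(tab$pct_of_parent[tab$subset == "CD4 T cells"], 30)
  expect_equal(tab$pct_of_lymphs[tab$subset == "CD4 T cells"], 21)

  # zero B cells: row present at 0, children absent
  expect_equal(tab$count[tab$subset == "B cells"], 0)
  expect_false("naive B cells" %in% tab$subset)

  # zero lymphocytes is a reported error
  labels0 <- refine_subsets(fake, rep("Monocytes", 3), tube, panel)
  expect_error(enumerate_subsets(labels0, panel),
               class = "cg_enumeration_error")
})

test_that("ALPS flag uses OR logic over both criteria", {
  crit <- fixture_panel()$alps_criteria
  # 30% of CD3 (the hallmark presentation) flags
  r <- evaluate_alps(mini_table(lymph = 1e5, t = 4e4, dnt = 12000), crit)
  expect_equal(r$dnt_pct_of_cd3, 30)
  expect_true(r$flag)
  # both below threshold: 2.4% of CD3 and 1.4% of lymphocytes
  r2 <- evaluate_alps(mini_table(lymph = 42000, t = 25000, dnt = 588), crit)
  expect_lt(r2$dnt_pct_of_cd3, 2.5)
  expect_lt(r2$dnt_pct_of_lymphs, 1.5)
  expect_false(r2$flag)
  # lymphocyte arm alone triggers (1.6% of lymphocytes, 2.0% of CD3)
  r3 <- evaluate_alps(mini_table(lymph = 100000, t = 80000, dnt = 1600), crit)
  expect_equal(r3$dnt_pct_of_lymphs, 1.6)
  expect_equal(r3$dnt_pct_of_cd3, 2.0)
  expect_true(r3$flag)

  bad <- mini_table()[1, , drop = FALSE]  # lymphocytes only
  expect_error(evaluate_alps(bad, crit), class = "cg_evaluation_error")
})

test_that("ALPS flag flips exactly at the configured thresholds", {
  crit <- fixture_panel()$alps_criteria
  lymph <- 1e6; t_count <- 4e5
  flag_at <- function(dnt)
    evaluate_alps(mini_table(lymph = lymph, t = t_count, dnt = dnt), crit)$flag
  # CD3 arm: threshold at 2.5% of 4e5 = 10000 (strict inequality)
  expect_false(flag_at(10000))
  expect_true(flag_at(10001))
  # binary search must land on the same boundary
  lo <- 0; hi <- 20000
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (flag_at(mid)) hi <- mid else lo <- mid
  }
  expect_equal(hi, 10001)
  # lymphocyte arm: with T = 90% the lymph criterion (1.5% of 1e6) binds first
  flag_lymph <- function(dnt)
    evaluate_alps(mini_table(lymph = lymph, t = 9e5, dnt = dnt), crit)$flag
  expect_false(flag_lymph(15000))
  expect_true(flag_lymph(15001))
})

range_table <- function(ra = 80, ro = 850, swb = 19) {
  rbind(
    data.frame(subset = c("lymphocytes", "T cells", "CD45RA+ T cells",
                          "CD45RO+ T cells"),
               tube = "ACT-T", parent = c("", "lymphocytes", "T cells", "T cells"),
               count = c(1200, 1000, ra, ro),
               pct_of_parent = NA, pct_of_lymphs = NA,
               secondary = c(FALSE, FALSE, TRUE, TRUE)),
    data.frame(subset = c("lymphocytes", "B cells", "switched memory B cells"),
               tube = "ALPS-B", parent = c("", "lymphocytes", "B cells"),
               count = c(1200, 1000, swb),
               pct_of_parent = NA, pct_of_lymphs = NA,
               secondary = FALSE)
  )
}

test_that("reference-range flags catch the reported DiGeorge presentation", {
  panel <- fixture_panel()
  flags <- apply_reference_ranges(range_table(), panel$reference_ranges)
  ra <- flags[flags$subset == "CD45RA+ T cells", ]
  expect_equal(ra$value, 8)
  expect_equal(ra$flag, "low")          # 8% against 30-60%
  sm <- flags[flags$subset == "switched memory B cells", ]
  expect_equal(sm$value, 1.9)
  expect_equal(sm$flag, "low")          # <2% against >5%
  ro <- flags[flags$subset == "CD45RO+ T cells", ]
  expect_equal(ro$flag, "high")

  ok <- apply_reference_ranges(range_table(ra = 450, ro = 500, swb = 120),
                               panel$reference_ranges)
  expect_true(all(ok$flag == "in_range"))
})

test_that("pattern codes: DiGeorge, ALPS, XLA and the normal fallback", {
  panel <- fixture_panel()
  crit <- panel$alps_criteria

  tab <- range_table()
  flags <- apply_reference_ranges(tab, panel$reference_ranges)
  alps_neg <- list(flag = FALSE, dnt_pct_of_lymphs = 0.5, dnt_pct_of_cd3 = 1,
                   criteria = crit)
  codes <- vapply(evaluate_patterns(tab, flags, alps_neg), `[[`, "", "code")
  expect_true("DIGEORGE_PATTERN" %in% codes)

  alps_pos <- list(flag = TRUE, dnt_pct_of_lymphs = 12, dnt_pct_of_cd3 = 30,
                   criteria = crit)
  codes2 <- vapply(evaluate_patterns(mini_table(1e5, 4e4, 12000),
                                     data.frame(), alps_pos), `[[`, "", "code")
  expect_true("ALPS_PATTERN" %in% codes2)

  xla_tab <- data.frame(subset = c("lymphocytes", "B cells"),
                        tube = "ALPS-B", parent = c("", "lymphocytes"),
                        count = c(50000, 20), pct_of_parent = NA,
                        pct_of_lymphs = c(100, 0.04), secondary = FALSE)
  codes3 <- vapply(evaluate_patterns(xla_tab, data.frame(), alps_neg),
                   `[[`, "", "code")
  expect_true("XLA_PATTERN" %in% codes3)

  norm_tab <- range_table(ra = 450, ro = 500, swb = 120)
  norm_tab$pct_of_lymphs <- ifelse(norm_tab$subset == "B cells", 83,
                                   norm_tab$pct_of_lymphs)
  nf <- apply_reference_ranges(norm_tab, panel$reference_ranges)
  codes4 <- vapply(evaluate_patterns(norm_tab, nf, alps_neg), `[[`, "", "code")
  expect_equal(codes4, "NORMAL")
})

test_that("reports serialize canonically and round-trip byte-identically", {
  panel <- fixture_panel()
  models <- fixture_models()
  case <- fixture_case(n_events = 5000, seed = 91)
  res <- analyze_case(case$samples, panel, models, case_id = "rt")
  f1 <- tempfile(fileext = ".json")
  write_report(res$report, f1)

  back <- read_report(f1)
  f2 <- tempfile(fileext = ".json")
  write_report(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(back$case_id, "rt")
  expect_false(isTRUE(back$tubes[["ALPS-T"]]$qc$pass_min_events))
  expect_gte(length(back$qc_warnings), 1)  # below the 100k event floor
})
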