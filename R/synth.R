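# Synthetic 3-tube case generator with per-event ground truth.
#
# Populations are defined as per-marker target levels on the same
# five-level geometry the discretizer recovers: level means on the
# transformed (asinh, cofactor 150) scale with Gaussian spread, inverted to
# raw FCS intensities.  Scatter comes from mode-specific bivariate
# Gaussians with FSC-H proportional to FSC-A along the singlet ridge.
# Artifact injectors (doublets, debris, acquisition drift) tag every event
# they create or touch, so each pre-gating stage can be scored against
# exact ground truth.

# transformed-scale means/sds for levels negative..bright
.level_means <- c(0.20, 1.8, 3.2, 4.6, 6.2)
.level_sds <- c(0.25, 0.35, 0.35, 0.35, 0.40)

.scatter_modes <- list(
  lymphocyte = list(fsc = c(250000, 40000), ssc = c(80000, 25000)),
  monocyte = list(fsc = c(400000, 60000), ssc = c(200000, 50000)),
  granulocyte = list(fsc = c(450000, 70000), ssc = c(450000, 90000))
)
.singlet_slope <- 0.95
.raw_max <- 2^20

template <- function(name, lineage, nodes, scatter, levels, spread = 1) {
  list(name = name, lineage = lineage, nodes = nodes, scatter = scatter,
       levels = levels, spread = spread)
}

#' Default population templates per tube
#'
#' The minimal population set reproducing every reported subset of the
#' panel: T-cell subsets (CD4, CD8, TCRab+ DNT, gamma-delta, Treg-like),
#' B and NK lineages and monocytes in the ALPS-T tube; naive/memory
#' (CD45RA/CD45RO) and activated T cells in the ACT-T tube; naive,
#' switched and non-switched memory B cells with a 60/40 kappa/lambda
#' split, T, NK and monocytes in the ALPS-B tube.  Levels are indices 0-4
#' on the five-level scale; markers omitted from a template are negative.
#'
#' @return named list (by tube) of template lists.
#' @export
default_templates <- function() {
  lv <- function(...) {
    v <- c(...)
    stopifnot(all(v >= 0 & v <= 4))
    v
  }
  list(
    "ALPS-T" = list(
      template("cd4_t", "T cells", c("T cells", "CD4 T cells"), "lymphocyte",
               lv(CD3 = 4, CD4 = 3, CD127 = 3, TCRAB = 3, CD45 = 4)),
      template("cd8_t", "T cells", c("T cells", "CD8 T cells"), "lymphocyte",
               lv(CD3 = 4, CD8 = 3, CD127 = 3, TCRAB = 3, CD45 = 4)),
      template("dnt_ab", "T cells", c("T cells", "DNT", "TCRab+ DNT"), "lymphocyte",
               lv(CD3 = 4, TCRAB = 3, CD127 = 3, CD45 = 4)),
      template("gd_t", "T cells", c("T cells", "gd T cells"), "lymphocyte",
               lv(CD3 = 4, TCRGD = 3, CD45 = 4)),
      template("treg", "T cells", c("T cells", "CD4 T cells", "Treg-like"),
               "lymphocyte",
               lv(CD3 = 4, CD4 = 3, CD25 = 3, TCRAB = 3, CD45 = 4)),
      template("b", "B cells", "B cells", "lymphocyte",
               lv(CD19 = 3, CD45 = 4)),
      template("nk", "NK cells", "NK cells", "lymphocyte",
               lv(CD45 = 4)),
      template("mono", "Monocytes", character(0), "monocyte",
               lv(CD4 = 1, CD45 = 3))
    ),
    "ACT-T" = list(
      template("cd4_ra", "T cells", c("T cells", "CD4 T cells", "CD45RA+ T cells"),
               "lymphocyte",
               lv(CD3 = 4, CD4 = 3, CD45RA = 3, CD45 = 4)),
      template("cd4_ro", "T cells", c("T cells", "CD4 T cells", "CD45RO+ T cells"),
               "lymphocyte",
               lv(CD3 = 4, CD4 = 3, CD45RO = 3, CD45 = 4)),
      template("cd8_ra", "T cells", c("T cells", "CD8 T cells", "CD45RA+ T cells"),
               "lymphocyte",
               lv(CD3 = 4, CD8 = 3, CD45RA = 3, CD45 = 4)),
      template("cd8_ro", "T cells", c("T cells", "CD8 T cells", "CD45RO+ T cells"),
               "lymphocyte",
               lv(CD3 = 4, CD8 = 3, CD45RO = 3, CD45 = 4)),
      template("act_t", "T cells",
               c("T cells", "CD4 T cells", "CD45RO+ T cells", "activated T cells"),
               "lymphocyte",
               lv(CD3 = 4, CD4 = 3, CD45RO = 3, CD69 = 3, HLADR = 3, CD45 = 4)),
      template("non_t", "non-T lymphocytes", "non-T lymphocytes", "lymphocyte",
               lv(CD45 = 4)),
      template("mono", "Monocytes", character(0), "monocyte",
               lv(CD4 = 1, HLADR = 3, CD45 = 3))
    ),
    "ALPS-B" = list(
      template("t", "T cells", "T cells", "lymphocyte",
               lv(CD3 = 4, CD5 = 3, CD45 = 4)),
      template("nk", "NK cells", "NK cells", "lymphocyte",
               lv(CD56 = 3, CD45 = 4)),
      template("naive_b_k", "B cells",
               c("B cells", "naive B cells", "kappa+ B cells"), "lymphocyte",
               lv(CD19 = 3, IGD = 3, KAPPA = 3, CD45 = 4)),
      template("naive_b_l", "B cells",
               c("B cells", "naive B cells", "lambda+ B cells"), "lymphocyte",
               lv(CD19 = 3, IGD = 3, LAMBDA = 3, CD45 = 4)),
      template("sw_b_k", "B cells",
               c("B cells", "switched memory B cells", "kappa+ B cells"),
               "lymphocyte",
               lv(CD19 = 3, CD27 = 3, KAPPA = 3, CD45 = 4)),
      template("sw_b_l", "B cells",
               c("B cells", "switched memory B cells", "lambda+ B cells"),
               "lymphocyte",
               lv(CD19 = 3, CD27 = 3, LAMBDA = 3, CD45 = 4)),
      template("nsw_b_k", "B cells",
               c("B cells", "non-switched memory B cells", "kappa+ B cells"),
               "lymphocyte",
               lv(CD19 = 3, CD27 = 3, IGD = 3, KAPPA = 3, CD45 = 4)),
      template("nsw_b_l", "B cells",
               c("B cells", "non-switched memory B cells", "lambda+ B cells"),
               "lymphocyte",
               lv(CD19 = 3, CD27 = 3, IGD = 3, LAMBDA = 3, CD45 = 4)),
      template("mono", "Monocytes", character(0), "monocyte",
               lv(CD45 = 3))
    )
  )
}

.normal_abundances <- list(
  "ALPS-T" = c(cd4_t = 0.32, cd8_t = 0.18, dnt_ab = 0.01, gd_t = 0.03,
               treg = 0.03, b = 0.12, nk = 0.10, mono = 0.21),
  "ACT-T" = c(cd4_ra = 0.20, cd4_ro = 0.15, cd8_ra = 0.12, cd8_ro = 0.08,
              act_t = 0.02, non_t = 0.22, mono = 0.21),
  "ALPS-B" = c(t = 0.50, nk = 0.10, naive_b_k = 0.048, naive_b_l = 0.032,
               sw_b_k = 0.015, sw_b_l = 0.010, nsw_b_k = 0.015,
               nsw_b_l = 0.010, mono = 0.27)
)

rescale_group <- function(ab, members, target_total) {
  other <- setdiff(names(ab), members)
  cur <- sum(ab[members])
  stopifnot(cur > 0)
  ab[members] <- ab[members] * target_total / cur
  # keep the tube total at 1 by rescaling the rest
  rest <- sum(ab[other])
  ab[other] <- ab[other] * (1 - target_total) / rest
  ab
}

#' Define a synthetic case scenario
#'
#' Scenario abundances are the stated disease worlds: `ALPS` reallocates T
#' cells so TCRab+ DNT reach `dnt_of_t` of T events (default 30%, the
#' hallmark worked case); `DIGEORGE` lowers CD45RA+ T cells to `ra_of_t`
#' of T (default 8%) and switched memory B cells to `swb_of_b` of B
#' (default 1.5%); `XLA` removes B cells (abundance `b_of_total`, default
#' 0.03% of events).  Defaults elsewhere: 20000 events per tube, 2%
#' doublets, 2% debris, no drift.
#'
#' @param name one of `NORMAL`, `ALPS`, `DIGEORGE`, `XLA`.
#' @param n_events events per tube before artifact injection.
#' @param doublet_rate,debris_rate artifact rates.
#' @param drift `FALSE` or a list `(window, gain, channel)`.
#' @param seed case seed.
#' @param dnt_of_t,ra_of_t,swb_of_b,b_of_total scenario severity knobs.
#' @param jitter_concentration when non-`NULL`, per-template abundances
#'   are jittered by independent Gamma(c, c) multipliers (a symmetric
#'   Dirichlet-style spread about the scenario means; c = 5 gives the
#'   between-case variation used for concordance batches).
#' @return a `cg_scenario`.
#' @export
scenario <- function(name = c("NORMAL", "ALPS", "DIGEORGE", "XLA"),
                     n_events = 20000, doublet_rate = 0.02, debris_rate = 0.02,
                     drift = FALSE, seed = 1,
                     dnt_of_t = 0.30, ra_of_t = 0.08, swb_of_b = 0.015,
                     b_of_total = 0.0003, jitter_concentration = NULL) {
  name <- match.arg(name)
  ab <- .normal_abundances
  if (name == "ALPS") {
    a <- ab[["ALPS-T"]]
    t_members <- c("cd4_t", "cd8_t", "dnt_ab", "gd_t", "treg")
    t_total <- sum(a[t_members])
    a["dnt_ab"] <- t_total * dnt_of_t
    rest <- setdiff(t_members, "dnt_ab")
    a[rest] <- a[rest] * (t_total - a["dnt_ab"]) / sum(a[rest])
    ab[["ALPS-T"]] <- a
  } else if (name == "DIGEORGE") {
    a <- ab[["ACT-T"]]
    t_members <- c("cd4_ra", "cd4_ro", "cd8_ra", "cd8_ro", "act_t")
    t_total <- sum(a[t_members])
    ra <- c("cd4_ra", "cd8_ra")
    ra_total <- t_total * ra_of_t
    a[ra] <- a[ra] * ra_total / sum(a[ra])
    ro <- c("cd4_ro", "cd8_ro", "act_t")
    a[ro] <- a[ro] * (t_total - ra_total) / sum(a[ro])
    ab[["ACT-T"]] <- a
    b <- ab[["ALPS-B"]]
    b_members <- grep("_b_", names(b), value = TRUE)
    b_total <- sum(b[b_members])
    sw <- c("sw_b_k", "sw_b_l")
    sw_total <- b_total * swb_of_b
    b[sw] <- b[sw] * sw_total / sum(b[sw])
    oth <- setdiff(b_members, sw)
    b[oth] <- b[oth] * (b_total - sw_total) / sum(b[oth])
    ab[["ALPS-B"]] <- b
  } else if (name == "XLA") {
    for (tb in names(ab)) {
      members <- grep("^b$|_b_", names(ab[[tb]]), value = TRUE)
      if (length(members))
        ab[[tb]] <- rescale_group(ab[[tb]], members, b_of_total)
    }
  }
  for (tb in names(ab)) stopifnot(abs(sum(ab[[tb]]) - 1) < 1e-9)

  # scenario invariants on the stated abundances
  at <- ab[["ALPS-T"]]
  t_tot <- sum(at[c("cd4_t", "cd8_t", "dnt_ab", "gd_t", "treg")])
  if (name == "ALPS" && at["dnt_ab"] / t_tot < 0.10)
    cg_stop("cg_config_error", "ALPS scenario requires DNT >= 10%% of T events")
  if (name == "XLA" && at["b"] > 0.0005)
    cg_stop("cg_config_error", "XLA scenario requires B <= 0.05%% of events")

  structure(list(name = name, abundances = ab, n_events = n_events,
                 doublet_rate = doublet_rate, debris_rate = debris_rate,
                 drift = drift, seed = seed,
                 jitter_concentration = jitter_concentration),
            class = "cg_scenario")
}

jitter_abundances <- function(ab, concentration) {
  g <- rgamma(length(ab), shape = concentration, rate = concentration)
  w <- ab * g
  w / sum(w)
}

#' Simulate one tube of events
#'
#' Draws a population per event (categorical by abundance), marker
#' intensities from the population's per-level Gaussians on the
#' transformed scale (inverted to raw FCS intensities, clipped to
#' `[0, 2^20]`), scatter from the population's scatter mode with
#' `FSC-H = 0.95 FSC-A + noise`, and sorted uniform acquisition times.
#'
#' @param tube a `cg_tube`.
#' @param templates template list for the tube (see the defaults).
#' @param abundances named abundance vector over the templates, summing
#'   to 1.
#' @param n number of events.
#' @param seed RNG seed (bit-identical output per seed).
#' @param cofactor fluorescence transform cofactor matching the analysis
#'   scale.
#' @return list with the raw-scale `sample` (a `cg_sample`) and `truth`
#'   data frame (`population`, `lineage`, `artifact`).
#' @export
simulate_tube <- function(tube, templates, abundances, n, seed = 1,
                          cofactor = 150) {
  tnames <- vapply(templates, `[[`, "", "name")
  if (!setequal(names(abundances), tnames))
    cg_stop("cg_config_error", "abundances must name every template of the tube")
  if (abs(sum(abundances) - 1) > 1e-6)
    cg_stop("cg_config_error", "abundances must sum to 1 (got %.6f)",
            sum(abundances))
  markers <- tube$channels$marker_norm
  with_seed(seed, {
    pop <- base::sample(tnames, n, replace = TRUE, prob = abundances[tnames])
    pi <- match(pop, tnames)
    lvl <- t(vapply(templates, function(tp) {
      v <- rep(0L, length(markers)); names(v) <- markers
      v[names(tp$levels)] <- as.integer(tp$levels)
      v
    }, integer(length(markers))))
    spread <- vapply(templates, `[[`, 1, "spread")
    fluor <- matrix(0, n, length(markers))
    for (m in seq_along(markers)) {
      mu <- .level_means[lvl[pi, m] + 1L]
      s <- .level_sds[lvl[pi, m] + 1L] * spread[pi]
      fluor[, m] <- mu + s * rnorm(n)
    }
    raw <- pmin(pmax(inverse_transform_values(fluor, cofactor), 0), .raw_max)

    mode <- vapply(templates, `[[`, "", "scatter")[pi]
    fsc <- ssc <- numeric(n)
    for (md in unique(mode)) {
      i <- mode == md
      sm <- .scatter_modes[[md]]
      fsc[i] <- rnorm(sum(i), sm$fsc[1], sm$fsc[2])
      ssc[i] <- rnorm(sum(i), sm$ssc[1], sm$ssc[2])
    }
    fsc <- pmin(pmax(fsc, 1000), .raw_max)
    ssc <- pmin(pmax(ssc, 500), .raw_max)
    fsc_h <- pmax(.singlet_slope * fsc + rnorm(n, 0, 5000), 500)
    time <- sort(runif(n, 0, 1200))

    events <- cbind(fsc, fsc_h, ssc, raw, time)
    channels <- data.frame(
      name = c(tube$scatter_channels[["fsc_a"]], tube$scatter_channels[["fsc_h"]],
               tube$scatter_channels[["ssc_a"]], tube$channels$detector,
               if (is.na(tube$time_channel)) "TIME" else tube$time_channel),
      stain = c("", "", "", tube$channels$marker, ""),
      range = .raw_max,
      stringsAsFactors = FALSE
    )
    sample <- cg_sample(events, channels, time = time,
                        keywords = list("$TIMESTEP" = "1"))
    truth <- data.frame(
      population = pop,
      lineage = vapply(templates, `[[`, "", "lineage")[pi],
      artifact = "singlet",
      stringsAsFactors = FALSE
    )
    list(sample = sample, truth = truth)
  })
}

resort_by_time <- function(sim) {
  ti <- match("TIME", toupper(gsub("[^A-Z0-9]", "", colnames(sim$sample$events))))
  ord <- order(sim$sample$events[, ti])
  sim$sample$events <- sim$sample$events[ord, , drop = FALSE]
  sim$sample$time <- sim$sample$events[, ti]
  sim$truth <- sim$truth[ord, , drop = FALSE]
  rownames(sim$truth) <- NULL
  sim
}

#' Inject doublets
#'
#' Appends `round(rate * n)` events, each the channel-wise sum of two
#' sampled singlets in area channels and fluorescence, with FSC-H the
#' maximum of the pair plus 5% noise -- the area-over-height excess the
#' doublet gate keys on.  Injected events are tagged `"doublet"` in the
#' truth table.
#'
#' @param sim a [simulate_tube()] result.
#' @param rate doublet fraction relative to the current event count.
#' @param seed RNG seed.
#' @return the augmented `sim`.
#' @export
inject_doublets <- function(sim, rate, seed = 1) {
  if (rate == 0) return(sim)
  n <- nrow(sim$sample$events)
  m <- round(rate * n)
  if (m == 0) return(sim)
  singlet <- which(sim$truth$artifact == "singlet")
  ev <- sim$sample$events
  cn <- colnames(ev)
  norm <- gsub("[^A-Z0-9]", "", toupper(cn))
  hi <- which(norm == "FSCH"); ti <- which(norm == "TIME")
  sum_cols <- setdiff(seq_along(cn), c(hi, ti))
  with_seed(seed, {
    i1 <- base::sample(singlet, m, replace = TRUE)
    i2 <- base::sample(singlet, m, replace = TRUE)
    new <- ev[i1, , drop = FALSE]
    new[, sum_cols] <- ev[i1, sum_cols, drop = FALSE] + ev[i2, sum_cols, drop = FALSE]
    new[, hi] <- pmax(ev[i1, hi], ev[i2, hi]) * (1 + 0.05 * rnorm(m))
    new[, ti] <- ev[i1, ti]
    sim$sample$events <- rbind(ev, new)
    sim$truth <- rbind(sim$truth,
                       data.frame(population = rep(NA_character_, m),
                                  lineage = rep(NA_character_, m),
                                  artifact = rep("doublet", m),
                                  stringsAsFactors = FALSE))
  })
  resort_by_time(sim)
}

#' Inject debris
#'
#' Appends `round(rate * n)` low-scatter events: exponential FSC-A/SSC-A
#' far below the leukocyte modes, near-zero fluorescence, tagged
#' `"debris"`.
#'
#' @inheritParams inject_doublets
#' @export
inject_debris <- function(sim, rate, seed = 1) {
  if (rate == 0) return(sim)
  n <- nrow(sim$sample$events)
  m <- round(rate * n)
  if (m == 0) return(sim)
  ev <- sim$sample$events
  cn <- colnames(ev)
  norm <- gsub("[^A-Z0-9]", "", toupper(cn))
  ai <- which(norm == "FSCA"); hi <- which(norm == "FSCH")
  si <- which(norm == "SSCA"); ti <- which(norm == "TIME")
  fl <- setdiff(seq_along(cn), c(ai, hi, si, ti))
  with_seed(seed, {
    new <- matrix(0, m, ncol(ev), dimnames = list(NULL, cn))
    new[, ai] <- rexp(m, 1 / 15000)
    new[, si] <- rexp(m, 1 / 8000)
    new[, hi] <- pmax(.singlet_slope * new[, ai] * (1 + 0.02 * rnorm(m)), 100)
    new[, fl] <- pmax(inverse_transform_values(
      matrix(rnorm(m * length(fl), 0.1, 0.1), m), 150), 0)
    new[, ti] <- runif(m, min(ev[, ti]), max(ev[, ti]))
    sim$sample$events <- rbind(ev, new)
    sim$truth <- rbind(sim$truth,
                       data.frame(population = rep(NA_character_, m),
                                  lineage = rep(NA_character_, m),
                                  artifact = rep("debris", m),
                                  stringsAsFactors = FALSE))
  })
  resort_by_time(sim)
}

#' Inject acquisition drift
#'
#' Multiplies one channel's raw intensity by `gain` inside a contiguous
#' window covering `window` of the acquisition time span; affected
#' (previously singlet) events are tagged `"drift"`.
#'
#' @param sim a simulation.
#' @param window fraction of the time span affected.
#' @param gain multiplicative gain (1 is a no-op).
#' @param channel marker name (normalized match) or detector name.
#' @param seed RNG seed for the window placement.
#' @export
inject_drift <- function(sim, window, gain, channel, seed = 1) {
  if (gain == 1 || window == 0) return(sim)
  ev <- sim$sample$events
  ci <- match(normalize_marker(channel),
              normalize_marker(sim$sample$channels$stain))
  if (is.na(ci)) ci <- match(channel, colnames(ev))
  if (is.na(ci)) cg_stop("cg_config_error", "drift channel '%s' not found", channel)
  tt <- sim$sample$time
  span <- diff(range(tt))
  t0 <- with_seed(seed, min(tt) + runif(1, 0, 1 - window) * span)
  hit <- tt >= t0 & tt < t0 + window * span
  ev[hit, ci] <- ev[hit, ci] * gain
  sim$sample$events <- ev
  sim$truth$artifact[hit & sim$truth$artifact == "singlet"] <- "drift"
  sim
}

# Ground-truth subset percentages for one tube (singlet events only).
truth_subset_pcts <- function(truth, templates, panel, tube_name) {
  nodes <- tube_taxonomy(panel, tube_name)
  node_names <- vapply(nodes, `[[`, "", "name")
  counts <- setNames(rep(0, length(node_names)), node_names)
  singlet <- truth[truth$artifact == "singlet", , drop = FALSE]
  tnames <- vapply(templates, `[[`, "", "name")
  for (tp in templates) {
    sz <- sum(singlet$population == tp$name)
    if (sz == 0) next
    member <- if (tp$lineage %in% node_names)
      intersect(c("lymphocytes", tp$nodes), node_names) else character(0)
    counts[member] <- counts[member] + sz
  }
  lymph <- counts[["lymphocytes"]]
  data.frame(subset = node_names, tube = tube_name, count = unname(counts),
             pct_of_lymphs = unname(100 * counts / max(lymph, 1)),
             stringsAsFactors = FALSE)
}

#' Generate a full 3-tube synthetic case
#'
#' Simulates every tube of the panel under the scenario, applies the
#' configured artifact injectors, and returns the raw samples plus the
#' complete truth: per-event labels and artifact tags, and per-tube true
#' subset percentages (computed over singlet events).
#'
#' @param sc a [scenario()].
#' @param panel a `cg_panel`.
#' @param templates template list (defaults to [default_templates()]).
#' @return list with `samples`, `truth` (per-event, per tube),
#'   `truth_tables` (per-subset true percentages per tube), `scenario`.
#' @export
make_case <- function(sc, panel, templates = default_templates()) {
  stopifnot(inherits(sc, "cg_scenario"))
  samples <- list(); truths <- list(); tables <- list()
  for (i in seq_along(panel$tubes)) {
    tb <- panel$tubes[[i]]
    ab <- sc$abundances[[tb$name]]
    if (!is.null(sc$jitter_concentration))
      ab <- with_seed(derive_seed(sc$seed, 1000 + i),
                      jitter_abundances(ab, sc$jitter_concentration))
    sim <- simulate_tube(tb, templates[[tb$name]], ab, sc$n_events,
                         seed = derive_seed(sc$seed, i))
    sim <- inject_doublets(sim, sc$doublet_rate, seed = derive_seed(sc$seed, 10 + i))
    sim <- inject_debris(sim, sc$debris_rate, seed = derive_seed(sc$seed, 20 + i))
    if (is.list(sc$drift))
      sim <- inject_drift(sim, sc$drift$window, sc$drift$gain, sc$drift$channel,
                          seed = derive_seed(sc$seed, 30 + i))
    samples[[tb$name]] <- sim$sample
    truths[[tb$name]] <- sim$truth
    tables[[tb$name]] <- truth_subset_pcts(sim$truth, templates[[tb$name]],
                                           panel, tb$name)
  }
  list(samples = samples, truth = truths, truth_tables = tables, scenario = sc)
}

#' Ground-truth training clusters for a case tube
#'
#' Groups the tube's singlet events by true population and featurizes each
#' group exactly as the pipeline featurizes discovered clusters (medians
#' and five-level codes on the transformed scale, fractions, normalized
#' scatter medians), yielding labeled examples for the classifier without
#' running the clustering engine.
#'
#' @param sample raw `cg_sample` for the tube (as from [make_case()]).
#' @param truth matching truth data frame.
#' @param tube the `cg_tube`.
#' @param panel the `cg_panel`.
#' @param templates tube template list.
#' @return list `features` (matrix) and `labels` (lineage per row).
#' @export
truth_training <- function(sample, truth, tube, panel,
                           templates = default_templates()[[tube$name]]) {
  sample <- match_tube(apply_transform(sample), panel)
  singlet <- which(truth$artifact == "singlet")
  M <- marker_matrix(sample)[singlet, , drop = FALSE]
  sc <- scatter_columns(sample, tube)[singlet, , drop = FALSE]
  pop <- truth$population[singlet]
  levels <- lapply(colnames(M), function(m) fit_discretizer(M[, m]))
  names(levels) <- colnames(M)

  present <- intersect(vapply(templates, `[[`, "", "name"), unique(pop))
  K <- length(present)
  medians <- t(vapply(present, function(p)
    apply(M[pop == p, , drop = FALSE], 2, median), numeric(ncol(M))))
  colnames(medians) <- colnames(M)
  codes <- t(vapply(seq_len(K), function(c)
    vapply(colnames(M), function(m) discretize(medians[c, m], levels[[m]]), 1L),
    integer(ncol(M))))
  colnames(codes) <- colnames(M)
  sizes <- vapply(present, function(p) sum(pop == p), 1L)

  pseudo <- structure(list(
    assignment = match(pop, present),
    clusters = data.frame(
      id = seq_len(K), size = sizes, frac = sizes / length(pop),
      peak_density = NA_real_,
      fsc_med = vapply(present, function(p) median(sc[pop == p, "fsc_a"]), 1),
      ssc_med = vapply(present, function(p) median(sc[pop == p, "ssc_a"]), 1),
      code = ""),
    medians = medians, codes = codes, levels = levels,
    markers = colnames(M),
    scatter_q95 = c(fsc = quantile(sc[, "fsc_a"], 0.95, names = FALSE),
                    ssc = quantile(sc[, "ssc_a"], 0.95, names = FALSE)),
    params = list()
  ), class = "cg_clusters")

  lineages <- vapply(templates, `[[`, "", "lineage")
  names(lineages) <- vapply(templates, `[[`, "", "name")
  list(features = featurize(pseudo, tube), labels = unname(lineages[present]))
}

#' Write a simulated case to disk
#'
#' Emits one FCS file per tube plus a per-tube truth CSV and a scenario
#' manifest (YAML).
#'
#' @param case a [make_case()] result.
#' @param dir output directory (created).
#' @param case_id base name for the files.
#' @return the directory, invisibly.
#' @export
write_case <- function(case, dir, case_id = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(case$samples)) {
    safe <- gsub("[^A-Za-z0-9-]", "_", tb)
    write_fcs(case$samples[[tb]], file.path(dir, sprintf("%s_%s.fcs", case_id, safe)))
    write.csv(cbind(event = seq_len(nrow(case$truth[[tb]])), case$truth[[tb]]),
              file.path(dir, sprintf("%s_%s_truth.csv", case_id, safe)),
              row.names = FALSE)
  }
  sc <- case$scenario
  manifest <- list(case_id = case_id, scenario = sc$name,
                   n_events = sc$n_events, doublet_rate = sc$doublet_rate,
                   debris_rate = sc$debris_rate, seed = sc$seed)
  writeLines(yaml::as.yaml(manifest), file.path(dir, paste0(case_id, "_manifest.yaml")))
  invisible(dir)
}
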