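make_table <- function(...) {
  # rows: feature, sample, intensity triples
  tibble::tibble(...)
}

two_group_design <- function(n_bio = 2, n_tech = 2,
                             groups = c("ctl", "exp")) {
  tidyr::expand_grid(group = groups,
                     biological_replicate = seq_len(n_bio),
                     technical_replicate = seq_len(n_tech)) |>
    dplyr::mutate(sample = sprintf("%s_b%d_t%d", group, biological_replicate,
                                   technical_replicate), .before = 1)
}

test_that("normalization equalizes run totals at the mean total", {
  tab <- make_table(
    feature = c("p1", "p2", "p1", "p2"),
    sample = c("s1", "s1", "s2", "s2"),
    intensity = c(40, 60, 150, 50)
  )
  out <- normalize_intensities(tab)
  totals <- tapply(out$intensity, out$sample, sum)
  expect_equal(as.numeric(totals), c(150, 150))
  # scale factors 1.5 and 0.75
  expect_equal(out$intensity[out$sample == "s1"], c(60, 90))
  expect_equal(out$intensity[out$sample == "s2"], c(112.5, 37.5))
  # within-run proportions preserved
  expect_equal(out$intensity[2] / out$intensity[1], 60 / 40)
})

test_that("normalization leaves equal-total and single-run tables unchanged", {
  tab <- make_table(feature = c("p1", "p1"), sample = c("s1", "s2"),
                    intensity = c(100, 100))
  expect_equal(normalize_intensities(tab)$intensity, c(100, 100))
  single <- make_table(feature = "p1", sample = "s1", intensity = 7)
  expect_equal(normalize_intensities(single)$intensity, 7)
})

test_that("normalization run totals agree to 1e-9 relative on random tables", {
  set.seed(1)
  tab <- tibble::tibble(
    feature = sample(sprintf("p%02d", 1:30), 400, replace = TRUE),
    sample = sample(sprintf("s%d", 1:8), 400, replace = TRUE),
    intensity = rexp(400) + 0.01
  ) |>
    dplyr::distinct(feature, sample, .keep_all = TRUE)
  totals <- tapply(normalize_intensities(tab)$intensity,
                   normalize_intensities(tab)$sample, sum)
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)
})

test_that("rollup sums peptides and propagates absence", {
  tab <- make_table(
    feature = c("pepA", "pepB", "pepA"),
    sample = c("s1", "s1", "s2"),
    intensity = c(3, 7, 5)
  )
  map <- tibble::tibble(peptide = c("pepA", "pepB"), protein = "prot1")
  out <- rollup_proteins(tab, map)
  expect_equal(out$intensity[out$sample == "s1"], 10)
  expect_equal(out$intensity[out$sample == "s2"], 5)  # pepB absent in s2
  # a protein absent in a run iff all its peptides absent there
  expect_setequal(out$sample, c("s1", "s2"))
})

test_that("rollup matches a brute-force group-and-sum oracle", {
  set.seed(2)
  tab <- tibble::tibble(
    feature = sample(sprintf("pep%02d", 1:40), 300, replace = TRUE),
    sample = sample(sprintf("s%d", 1:6), 300, replace = TRUE),
    intensity = runif(300, 1, 100)
  ) |>
    dplyr::distinct(feature, sample, .keep_all = TRUE)
  map <- tibble::tibble(peptide = sprintf("pep%02d", 1:40),
                        protein = sprintf("prot%02d", rep(1:10, each = 4)))
  out <- rollup_proteins(tab, map)
  oracle <- stats::aggregate(
    intensity ~ protein + sample,
    data = merge(as.data.frame(tab), as.data.frame(map),
                 by.x = "feature", by.y = "peptide"),
    FUN = sum
  )
  merged <- merge(as.data.frame(out), oracle,
                  by.x = c("feature", "sample"), by.y = c("protein", "sample"))
  expect_equal(nrow(merged), nrow(out))
  expect_equal(merged$intensity.x, merged$intensity.y, tolerance = 1e-12)
})

test_that("unmapped peptides error by default and drop on request", {
  tab <- make_table(feature = c("pepA", "pepX"), sample = c("s1", "s1"),
                    intensity = c(1, 2))
  map <- tibble::tibble(peptide = "pepA", protein = "prot1")
  expect_error(rollup_proteins(tab, map), "no protein mapping")
  expect_warning(out <- rollup_proteins(tab, map, unmapped = "drop"),
                 "Dropping")
  expect_equal(out$feature, "prot1")
})

test_that("technical replicate averaging keeps detection counts", {
  design <- two_group_design(n_bio = 1, n_tech = 2, groups = "g")
  tab <- make_table(
    feature = c("p1", "p1", "p2"),
    sample = c("g_b1_t1", "g_b1_t2", "g_b1_t1"),
    intensity = c(4, 6, 8)
  )
  out <- average_technical_replicates(tab, design)
  p1 <- out[out$feature == "p1", ]
  expect_equal(p1$intensity, 5)        # mean of 4 and 6
  expect_equal(p1$n_detected, 2L)
  p2 <- out[out$feature == "p2", ]
  expect_equal(p2$intensity, 8)        # detected in one run only
  expect_equal(p2$n_detected, 1L)
  expect_equal(p2$n_technical, 2L)
})

test_that("replicate averaging matches a brute-force per-animal oracle", {
  set.seed(3)
  design <- two_group_design(n_bio = 3, n_tech = 2)
  tab <- tidyr::expand_grid(feature = sprintf("p%02d", 1:15),
                            sample = design$sample) |>
    dplyr::slice_sample(prop = 0.8) |>
    dplyr::mutate(intensity = runif(dplyr::n(), 1, 50))
  out <- average_technical_replicates(tab, design)
  df <- merge(as.data.frame(tab), as.data.frame(design), by = "sample")
  oracle <- stats::aggregate(
    intensity ~ feature + group + biological_replicate, data = df, FUN = mean
  )
  merged <- merge(as.data.frame(out), oracle,
                  by = c("feature", "group", "biological_replicate"))
  expect_equal(nrow(merged), nrow(out))
  expect_equal(merged$intensity.x, merged$intensity.y, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)              # n = 1 unchanged
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))  # rank-n cancellation
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is permutation-invariant and order-preserving", {
  set.seed(5)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group statistics match textbook Welch and Student formulas", {
  design <- two_group_design(n_bio = 3, n_tech = 1)
  ctrl_vals <- c(10, 12, 11)
  exp_vals <- c(20, 22, 21)
  tab <- tibble::tibble(
    feature = "p1",
    sample = design$sample,
    intensity = c(ctrl_vals, exp_vals)
  )
  de <- tidy(differential_expression(tab, design, "ctl", "exp"))
  expect_equal(de$fold_change, mean(exp_vals) / mean(ctrl_vals))
  oracle <- stats::t.test(log2(exp_vals), log2(ctrl_vals))
  expect_equal(de$p_value, oracle$p.value, tolerance = 1e-12)

  de_raw <- tidy(differential_expression(tab, design, "ctl", "exp",
                                         log_scale = FALSE, var_equal = TRUE))
  oracle_raw <- stats::t.test(exp_vals, ctrl_vals, var.equal = TRUE)
  expect_equal(de_raw$p_value, oracle_raw$p.value, tolerance = 1e-12)
})

test_that("identical group values give fold change 1 and log2 fc 0", {
  design <- two_group_design(n_bio = 2, n_tech = 1)
  tab <- tibble::tibble(feature = "p1", sample = design$sample,
                        intensity = rep(5, 4))
  de <- tidy(differential_expression(tab, design, "ctl", "exp"))
  expect_equal(de$fold_change, 1)
  expect_equal(de$log2_fc, 0)
})

test_that("sentinel codes mark group-wide non-detection exclusively", {
  design <- two_group_design(n_bio = 2, n_tech = 2)
  # p_up absent from all ctl runs; p_down absent from all exp runs
  tab <- dplyr::bind_rows(
    tibble::tibble(feature = "p_up",
                   sample = design$sample[design$group == "exp"],
                   intensity = c(10, 11, 12, 13)),
    tibble::tibble(feature = "p_down",
                   sample = design$sample[design$group == "ctl"],
                   intensity = c(20, 21, 22, 23)),
    tibble::tibble(feature = "p_both", sample = design$sample,
                   intensity = rep(5, 8))
  )
  de <- tidy(differential_expression(tab, design, "ctl", "exp"))
  expect_equal(de$sentinel[de$protein == "p_up"], "100")
  expect_equal(de$fold_change[de$protein == "p_up"], 100)
  expect_equal(de$sentinel[de$protein == "p_down"], "0.1")
  expect_equal(de$fold_change[de$protein == "p_down"], 0.1)
  expect_true(is.na(de$p_value[de$protein == "p_up"]))
  expect_equal(de$sentinel[de$protein == "p_both"], "none")
  # no protein carries both codes by construction of the case analysis
  expect_false(any(table(de$protein[de$sentinel != "none"]) > 1))
})

test_that("DEP calling applies the threshold conjunction exactly", {
  base <- tibble::tibble(
    protein = sprintf("p%02d", 1:6),
    mean_control = 1, mean_experimental = 1,
    fold_change = c(1.0, 1.25, 1.25, 1.25, 0.5, 1.15),
    log2_fc = log2(c(1.0, 1.25, 1.25, 1.25, 0.5, 1.15)),
    p_value = 0.01,
    adj_p_value = c(0.05, 0.05, 0.2, 0.05, 0.01, 0.01),
    overexpressing_group = "exp",
    n_present = c(6L, 6L, 6L, 4L, 9L, 9L),
    n_runs = 10L,
    sentinel = "none",
    dep = FALSE
  )
  x <- structure(list(table = base, control = "ctl", experimental = "exp",
                      log_scale = TRUE, var_equal = FALSE, thresholds = NULL),
                 class = "dep_analysis")
  out <- tidy(call_deps(x))
  # FC 1.0 never a DEP; FC 1.25/adj .05/6 of 10 is; adj .2 and 4/10 are not;
  # FC 0.5 passes two-sided; FC 1.15 fails the |1.2| rule
  expect_equal(out$dep, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("planted DEPs are recovered exactly in a noiseless toy", {
  planted <- tibble::tibble(protein = 1:3, group = "pte",
                            log2fc = c(1, -1, 0.5))
  sim <- simulate_abundance(20, planted = planted, noise_sd = 0, seed = 6)
  de <- call_deps(differential_expression(sim$abundance, sim$design,
                                          "sham", "pte"))
  called <- tidy(de)$protein[tidy(de)$dep]
  expect_setequal(called, sprintf("P%04d", 1:3))
})

test_that("sentinel proteins are DEP-flagged iff they pass presence", {
  design <- two_group_design(n_bio = 2, n_tech = 2)
  tab <- dplyr::bind_rows(
    tibble::tibble(feature = "p_full",
                   sample = design$sample[design$group == "exp"],
                   intensity = c(1, 2, 3, 4)),
    tibble::tibble(feature = "p_rare",
                   sample = design$sample[design$group == "exp"][1],
                   intensity = 5),
    tibble::tibble(feature = "p_anchor", sample = design$sample,
                   intensity = rep(1, 8))
  )
  de <- call_deps(differential_expression(tab, design, "ctl", "exp"))
  out <- tidy(de)
  expect_true(out$dep[out$protein == "p_full"])    # 4 of 4 runs
  expect_false(out$dep[out$protein == "p_rare"])   # 1 of 4 runs
})

test_that("hypergeometric ORA matches exact combinatorics", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5], cold = universe[6:10])
  res <- ora_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$overlap[res$set == "hit"], 5L)

  # exhaustive selection makes every set's p-value 1
  res_all <- ora_enrichment(universe, sets, universe)
  expect_equal(res_all$p_value, c(1, 1))
})

test_that("ORA agrees with a brute-force tail summation on random cases", {
  set.seed(7)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    universe <- sprintf("u%02d", seq_len(N))
    m <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    members <- sample(universe, m)
    selected <- sample(universe, k)
    res <- ora_enrichment(selected, list(s = members), universe)
    x <- length(intersect(selected, members))
    expect_equal(res$p_value, oracle_hyper_tail(x, m, N, k), tolerance = 1e-12)
  }
  expect_error(ora_enrichment(character(), list(a = "x"), character()),
               "non-empty")
})
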