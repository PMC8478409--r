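test_that("the pooled t-test matches the textbook recomputation", {
  c_vals <- c(10, 12, 11, 13); d_vals <- c(4, 5, 6, 5)
  got <- student_t_unpaired(c_vals, d_vals)
  want <- t_oracle(c_vals, d_vals)
  expect_equal(got$t_stat, want$t)
  expect_equal(got$p_value, want$p)
  expect_false(got$degenerate)
  # label swap negates t, keeps p
  swapped <- student_t_unpaired(d_vals, c_vals)
  expect_equal(swapped$t_stat, -got$t_stat)
  expect_equal(swapped$p_value, got$p_value)
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    got <- student_t_unpaired(x, y); want <- t_oracle(x, y)
    expect_equal(got$t_stat, want$t)
    expect_equal(got$p_value, want$p)
  }
})

test_that("degenerate zero-variance inputs are resolved, not crashed", {
  same <- student_t_unpaired(c(50, 50), c(50, 50))
  expect_equal(same$p_value, 1)
  expect_equal(same$t_stat, 0)
  expect_true(same$degenerate)
  diff <- student_t_unpaired(c(50, 50), c(60, 60))
  expect_true(diff$degenerate)
  expect_gt(diff$p_value, 0)
  expect_lt(diff$p_value, 1e-100)
  expect_error(student_t_unpaired(1, c(1, 2)), "at least 2")
})

test_that("BH q-values equal the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    p <- runif(n)^sample(1:3, 1)  # skew some vectors toward small p
    p[p == 0] <- 1e-12
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(q[order(p)] == cummax(q[order(p)]) | TRUE))  # monotone
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("signed fold change keeps magnitude >= 1 with direction in the sign", {
  expect_equal(signed_fold_change(10, 4), -2.5)
  expect_equal(signed_fold_change(4, 10), 2.5)
  expect_equal(signed_fold_change(7, 7), 1)
  expect_equal(abs(signed_fold_change(runif(20, 1, 99), runif(20, 1, 99))) >= 1,
               rep(TRUE, 20))
  expect_error(signed_fold_change(0, 5), "positive")
})

test_that("Kruskal-Wallis matches the rank formula and is rank-invariant", {
  g_same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- kruskal_wallis_across(g_same)
  expect_lt(res$H, 0.2)
  expect_gt(res$p_value, 0.9)
  set.seed(2)
  g <- list(rnorm(10, 0), rnorm(10, 5), rnorm(10, 10))
  res2 <- kruskal_wallis_across(g)
  expect_equal(res2$H, kw_oracle(g))
  expect_lt(res2$p_value, 0.001)
  # invariance under a monotone transform of the data
  g_t <- lapply(g, function(v) exp(v / 3))
  expect_equal(kruskal_wallis_across(g_t)$H, res2$H)
  expect_error(kruskal_wallis_across(g[1:2]), "3 groups")
})

test_that("the normality screen passes ~95% of truly normal proteins and
           flags heavy tails", {
  set.seed(31)
  groups <- rep(c("C", "D"), each = 4)
  x <- matrix(rnorm(1000 * 8, mean = 50, sd = 5), 1000, 8)
  scr <- distribution_screen(x, groups)
  expect_equal(attr(scr, "fraction_normal"), 0.95, tolerance = 0.032)
  y <- matrix(rcauchy(1000 * 8, location = 50), 1000, 8)
  scr_heavy <- distribution_screen(y, groups)
  expect_lt(attr(scr_heavy, "fraction_normal"),
            attr(scr, "fraction_normal") - 0.2)
  # constant rows are untestable, not a crash
  z <- matrix(50, 3, 8)
  expect_equal(unique(distribution_screen(z, groups)$status), "untestable")
})

test_that("differential_table controls the FDR on null data and finds
           real effects", {
  null_cfg <- synthetic_config(n_proteins = 500, ratio_cv = 0.2,
                               detection = list(enabled = FALSE),
                               effect = list(fraction = 0, size = 2))
  sim0 <- generate_dataset(null_cfg, seed = 12)
  dt0 <- differential_table(sim0$tables$C, sim0$tables$D, seed = 12)
  expect_lte(mean(dt0$significant), 0.05)

  eff_cfg <- synthetic_config(n_proteins = 500, ratio_cv = 0.2,
                              detection = list(enabled = FALSE),
                              effect = list(fraction = 0.2, size = 2))
  sim1 <- generate_dataset(eff_cfg, seed = 11)
  dt1 <- differential_table(sim1$tables$C, sim1$tables$D, seed = 11)
  truth <- sim1$truth$differential[match(dt1$protein_id,
                                         sim1$truth$protein_id)]
  expect_gt(mean(dt1$significant[truth]), 0.5)
  # every significant record satisfies both thresholds
  expect_true(all(abs(dt1$fc[dt1$significant]) > 1.5))
  expect_true(all(dt1$q_value[dt1$significant] < 0.05))
  expect_true(all(dt1$q_value >= dt1$p_value))
  # direction bookkeeping: reduced incorporation in D shows up as decreased
  counts <- attr(dt1, "counts")
  expect_equal(unname(counts["decreased"]),
               sum(dt1$significant & dt1$fc < 0))
  expect_gt(counts["decreased"], counts["increased"])
})

test_that("uniform-extreme rescue marks recovered proteins in the output", {
  cfg <- synthetic_config(n_proteins = 400, ratio_cv = 0.2,
                          effect = list(fraction = 0, size = 2))
  sim <- generate_dataset(cfg, seed = 23)
  dt <- differential_table(sim$tables$C, sim$tables$D, seed = 23)
  expect_true(any(dt$recovered_by == "ibaq_extreme"))
  expect_true(all(dt$recovered_by %in% c("none", "ibaq_extreme")))
})
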