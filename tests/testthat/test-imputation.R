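# Pulse-group table: protein 4 has iBAQ L missing in 3 of 4 samples (censored
# fully-labelled pattern); observed H/L in column A1 is {0.5, 2, 4}.
censored_fixture <- function(lysine4 = TRUE) {
  ratio <- rbind(c(0.5, 1, 1, 1),
                 c(2.0, 1, 1, 1),
                 c(4.0, 1, 1, 1),
                 c(NA,  NA, NA, 2))
  ibl <- matrix(1e6, 4, 4)
  ibl[4, 1:3] <- NA
  make_qt(ratio, ibl = ibl, lysine = c(TRUE, TRUE, TRUE, lysine4))
}

# Chase-group table: protein 4 lost its heavy channel in 3 of 4 samples.
chase_fixture <- function(colmin = 0.5) {
  ratio <- rbind(c(colmin, 1, 1, 1),
                 c(2.0, 1, 1, 1),
                 c(4.0, 1, 1, 1),
                 c(NA,  NA, NA, 2))
  ibh <- matrix(1e6, 4, 4)
  ibh[4, 1:3] <- NA
  make_qt(ratio, ibh = ibh, group = "B")
}

test_that("censored-extreme imputation lands on column max + 0.1 and
           column min - 0.01", {
  out <- impute_censored_pulse(censored_fixture(), chase_fixture())
  # group A, missing iBAQ L -> column maximum + 0.1
  expect_equal(out$table_a$ratio_hl[4, 1], 4.1)
  # group B, missing iBAQ H -> column minimum - 0.01
  expect_equal(out$table_b$ratio_hl[4, 1], 0.49)
  # imputed values sit strictly beyond every observed value in the column
  expect_gt(out$table_a$ratio_hl[4, 1], max(censored_fixture()$ratio_hl[, 1],
                                            na.rm = TRUE))
  expect_lt(out$table_b$ratio_hl[4, 1], min(chase_fixture()$ratio_hl[, 1],
                                            na.rm = TRUE))
  # audit: one record per imputed cell, with the basis recorded
  expect_equal(nrow(out$audit), 6L)  # 3 cells per table
  expect_setequal(unique(out$audit$scheme), c("censored_max", "censored_min"))
  expect_match(out$audit$basis[1], "column max 4")
})

test_that("imputation is gated on lysine evidence and floors the minimum", {
  # no lysine peptides -> untouched
  out <- impute_censored_pulse(censored_fixture(lysine4 = FALSE),
                               chase_fixture())
  expect_true(is.na(out$table_a$ratio_hl[4, 1]))
  expect_true(all(out$audit$scheme == "censored_min"))
  # tiny column minimum would go negative -> floored at epsilon
  out2 <- impute_censored_pulse(censored_fixture(),
                                chase_fixture(colmin = 0.005))
  expect_equal(out2$table_b$ratio_hl[4, 1], 1e-4)
  expect_gt(out2$table_b$ratio_hl[4, 1], 0)
})

test_that("observed cells are bit-identical across every imputation scheme", {
  a0 <- censored_fixture(); b0 <- chase_fixture()
  out <- impute_censored_pulse(a0, b0)
  obs <- !is.na(a0$ratio_hl)
  expect_identical(out$table_a$ratio_hl[obs], a0$ratio_hl[obs])
  obs_b <- !is.na(b0$ratio_hl)
  expect_identical(out$table_b$ratio_hl[obs_b], b0$ratio_hl[obs_b])

  set.seed(1)
  x <- matrix(runif(40, 10, 90), 10, 4)
  x[sample(40, 8)] <- NA
  done <- impute_knn(x, k = 2)
  expect_identical(done[!is.na(x)], x[!is.na(x)])
})

test_that("a column with no observed ratios is a hard error naming it", {
  a <- censored_fixture()
  a$ratio_hl[, 2] <- NA
  expect_error(impute_censored_pulse(a, chase_fixture()), "A2")
})

test_that("KNN with identical rows or k = 1 behaves like a copy", {
  x <- matrix(rep(c(10, 20, 30, 40), each = 5), 5, 4)
  x[2, 3] <- NA
  expect_equal(impute_knn(x, k = 3)[2, 3], 30)
  # unique nearest row is copied under k = 1
  y <- rbind(c(10, 10, 10, NA),
             c(10, 10, 10, 55),
             c(90, 90, 90, 99),
             c(80, 80, 80, 88))
  expect_equal(impute_knn(y, k = 1)[1, 4], 55)
})

test_that("KNN equals the brute-force all-pairs oracle on random matrices", {
  set.seed(7)
  for (rep in 1:20) {
    nr <- sample(6:50, 1); nc <- sample(4:8, 1)
    x <- matrix(runif(nr * nc, 0, 100), nr, nc)
    n_miss <- sample.int(floor(nr * nc / 4), 1)
    x[sample(nr * nc, n_miss)] <- NA
    # keep every row imputable for a clean comparison
    bad <- rowSums(!is.na(x)) < 2
    x[bad, 1:2] <- 50
    k <- sample(1:4, 1)
    expect_equal(impute_knn(x, k), knn_oracle(x, k), ignore_attr = TRUE)
  }
})

test_that("KNN rejects under-observed rows and impossible k", {
  x <- matrix(runif(20, 0, 100), 5, 4)
  x[1, 1:3] <- NA  # single observed value: excluded, left untouched
  out <- impute_knn(x, k = 2)
  expect_true(all(is.na(out[1, 1:3])))
  expect_equal(attr(out, "excluded_rows"), 1L)
  expect_error(impute_knn(x, k = 4), "smaller than")
})

# C/D pair in which protein 2 has no ratios in C but heavy iBAQ evidence,
# and protein 3 has no ratios in C with light-only evidence.
uniform_fixture <- function() {
  ratio_c <- rbind(c(1, 2, 4, 10), c(NA, NA, NA, NA), c(NA, NA, NA, NA))
  ibh_c <- rbind(rep(1e6, 4), c(1e6, 1e6, 1e6, NA), rep(NA_real_, 4))
  ibl_c <- rbind(rep(1e6, 4), rep(NA_real_, 4), c(1e6, 1e6, NA, NA))
  ratio_d <- rbind(c(1, 2, 4, 0.05), c(1, 1, 1, 1), c(2, 2, 2, 2))
  list(c = make_qt(ratio_c, ibh_c, ibl_c, group = "C"),
       d = make_qt(ratio_d, group = "D"))
}

test_that("uniform-extreme draws respect their bounds and the seed", {
  fx <- uniform_fixture()
  obs <- c(fx$c$ratio_hl, fx$d$ratio_hl)
  obs <- obs[!is.na(obs)]
  hi <- max(obs); lo <- min(obs); s <- sd(obs)
  out <- impute_extreme_uniform(fx$c, fx$d, seed = 99)
  # heavy evidence: fully labelled, draws near the dataset maximum
  d_max <- out$table_c$ratio_hl[2, ]
  expect_true(all(d_max > hi & d_max < hi + s))
  # light-only evidence: unlabelled, draws near the minimum
  d_min <- out$table_c$ratio_hl[3, ]
  expect_true(all(d_min > 0 & d_min < lo))
  # audited with bounds and seed; deterministic under the same seed
  expect_equal(nrow(out$audit), 8L)
  expect_match(out$audit$basis[1], "seed 99")
  out2 <- impute_extreme_uniform(fx$c, fx$d, seed = 99)
  expect_identical(out$table_c$ratio_hl, out2$table_c$ratio_hl)
  out3 <- impute_extreme_uniform(fx$c, fx$d, seed = 100)
  expect_false(identical(out$table_c$ratio_hl, out3$table_c$ratio_hl))
})

test_that("proteins without iBAQ evidence stay missing and are logged", {
  fx <- uniform_fixture()
  fx$c$ibaq_h[2, ] <- NA  # strip the heavy evidence
  fx$c$ibaq_l[2, ] <- NA
  out <- impute_extreme_uniform(fx$c, fx$d, seed = 1)
  expect_true(all(is.na(out$table_c$ratio_hl[2, ])))
  expect_equal(out$unresolved$protein_id, "P002")
  expect_error(impute_extreme_uniform(fx$c, fx$d), "seed")
})
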