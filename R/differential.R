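#' Unpaired Student's t-test with degenerate-input handling
#'
#' Two-sided pooled-variance (Student's) t-test by default; Welch's unequal
#' variance form behind `welch = TRUE`. The pooled form is the primary choice
#' because variance homogeneity is screened separately (see
#' [distribution_screen()]) rather than folded into the test. Degenerate
#' inputs that break the textbook formula are resolved explicitly: zero
#' pooled variance with equal means gives `t = 0, p = 1` (no evidence of an
#' effect); zero pooled variance with different means is flagged degenerate
#' and given the smallest representable positive p so it survives
#' multiple-testing correction on the (0, 1] scale.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param welch use Welch's t instead of the pooled form.
#' @return list with `t_stat` (sign follows `mean(x) - mean(y)`), `p_value`
#'   in (0, 1], and `degenerate` (logical).
#' @export
student_t_unpaired <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t_stat = 0, p_value = 1, degenerate = TRUE))
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf,
                p_value = .Machine$double.xmin, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t_stat = unname(tt$statistic),
       p_value = max(tt$p.value, .Machine$double.xmin),
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p p-values in (0, 1].
#' @return q-values (BH-adjusted p), same order as input; monotone in `p`,
#'   ties share a q, and `q >= p` pairwise.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change between two positive means
#'
#' The convention keeps the magnitude at least 1 and encodes direction in the
#' sign: `fc = mean_d / mean_c` when the older-adult mean is the larger
#' (increase, positive), `-mean_c / mean_d` otherwise (decrease, negative).
#' Equal means give +1.
#'
#' @param mean_c,mean_d positive group means (vectorised).
#' @return Signed fold change with `|fc| >= 1`.
#' @export
signed_fold_change <- function(mean_c, mean_d) {
  if (any(mean_c <= 0 | mean_d <= 0, na.rm = TRUE))
    stop("means must be positive")
  ifelse(mean_d >= mean_c, mean_d / mean_c, -mean_c / mean_d)
}

#' Kruskal-Wallis comparison of three or more groups
#'
#' Rank-based H statistic with tie correction and the chi-square reference
#' distribution, for comparing incorporation distributions across tissues or
#' age groups where normality is not assumed.
#'
#' @param groups list of >= 3 numeric vectors, each with >= 2 values.
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis_across <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need at least 3 groups (use the t-test path for 2)")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Per-protein normality and variance-homogeneity screen
#'
#' Advisory screen mirroring standard practice before t-testing: per protein,
#' Shapiro-Wilk normality on the within-group-centred replicate values and
#' Levene's test (via `car::leveneTest`) for variance homogeneity across
#' groups, both at the given alpha. Proteins with fewer than 3 non-missing
#' values in any group, or with constant values (Shapiro is undefined), are
#' marked untestable. The screen does not gate the t-tests; it only reports
#' the overall fraction of testable proteins that look normal.
#'
#' @param x proteins x samples numeric matrix.
#' @param groups factor or character vector, one group label per column.
#' @param alpha screening level (default 0.05).
#' @return data.frame with per-protein `normal`, `homogeneous` and `status`
#'   ("tested"/"untestable"); the overall fraction of testable proteins
#'   passing normality is in `attr(, "fraction_normal")`.
#' @export
distribution_screen <- function(x, groups, alpha = 0.05) {
  stopifnot(is.matrix(x), ncol(x) == length(groups))
  groups <- factor(groups)
  normal <- homogeneous <- rep(NA, nrow(x))
  status <- rep("untestable", nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    ok <- !is.na(v)
    if (any(tapply(ok, groups, sum) < 3)) next
    centred <- v[ok] - stats::ave(v[ok], groups[ok])
    if (diff(range(centred)) == 0) next
    sw <- tryCatch(stats::shapiro.test(centred), error = function(e) NULL)
    if (is.null(sw)) next
    lv <- tryCatch(
      car::leveneTest(v[ok] ~ groups[ok], center = stats::median),
      error = function(e) NULL)
    status[i] <- "tested"
    normal[i] <- sw$p.value >= alpha
    homogeneous[i] <- if (is.null(lv) || is.na(lv[["Pr(>F)"]][1])) NA else
      lv[["Pr(>F)"]][1] >= alpha
  }
  out <- data.frame(normal = normal, homogeneous = homogeneous,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "fraction_normal") <-
    if (any(status == "tested")) mean(normal[status == "tested"]) else NA_real_
  out
}

#' Differential incorporation between young (C) and older (D) adults
#'
#' Runs the full young-versus-older comparison for one tissue, in the order
#' the imputation schemes are meant to compose:
#'
#' 1. Seeded uniform-near-extreme rescue of proteins with ratios in one group
#'    only, based on iBAQ evidence ([impute_extreme_uniform()]); rescued
#'    proteins are marked `recovered_by = "ibaq_extreme"`.
#' 2. Conversion of all ratios to percent incorporation.
#' 3. Eligibility filter: proteins need at least `min_valid` observed values
#'    across the combined C and D replicates; others are excluded.
#' 4. K-nearest-neighbour completion of the combined percent matrix
#'    ([impute_knn()]).
#' 5. Per-protein unpaired Student's t-test on percent values, signed fold
#'    change of group means, Benjamini-Hochberg correction across proteins,
#'    and the significance call `q < alpha & |fc| > fc_threshold`.
#'
#' @param table_c,table_d [quant_table]s for groups C and D (post
#'   [filter_quantifiable()]).
#' @param seed integer seed for the uniform draws.
#' @param k neighbours for KNN (default 3).
#' @param alpha FDR threshold (default 0.05).
#' @param fc_threshold fold-change magnitude threshold (default 1.5).
#' @param welch use Welch's t instead of pooled Student's t.
#' @param min_valid minimum observed values across C and D for eligibility
#'   (default 2).
#' @param on_log_ratio run the tests on log2(H/L) instead of percent
#'   incorporation (sensitivity analysis; fold changes are still computed on
#'   percent means).
#' @return data.frame with one row per eligible protein: `protein_id`,
#'   `gene_name`, `mean_C`, `mean_D`, `fc`, `t_stat`, `p_value`, `q_value`,
#'   `significant`, `recovered_by`, and the volcano columns `log2_fc`
#'   (signed) and `neg_log10_q`. Attributes: `excluded` (ineligible
#'   proteins), `audit` (imputation audit), `counts` (significant up/down).
#' @export
differential_table <- function(table_c, table_d, seed, k = 3, alpha = 0.05,
                               fc_threshold = 1.5, welch = FALSE,
                               min_valid = 2, on_log_ratio = FALSE) {
  stopifnot(identical(table_c$proteins$protein_id,
                      table_d$proteins$protein_id))
  imp <- impute_extreme_uniform(table_c, table_d, seed = seed)
  tc <- imp$table_c; td <- imp$table_d
  rescued <- unique(imp$audit$protein_id)

  pc <- incorporation_percent(tc$ratio_hl)
  pd <- incorporation_percent(td$ratio_hl)
  comb <- cbind(pc, pd)
  eligible <- rowSums(!is.na(comb)) >= min_valid
  excluded <- data.frame(protein_id = tc$proteins$protein_id[!eligible],
                         reason = rep(sprintf("fewer than %d valid values",
                                              min_valid), sum(!eligible)),
                         stringsAsFactors = FALSE)
  comb <- comb[eligible, , drop = FALSE]
  ids <- tc$proteins$protein_id[eligible]
  genes <- tc$proteins$gene_name[eligible]
  comb <- impute_knn(comb, k = k)

  nc <- ncol(pc)
  mc <- comb[, seq_len(nc), drop = FALSE]
  md <- comb[, nc + seq_len(ncol(pd)), drop = FALSE]
  test_c <- mc; test_d <- md
  if (on_log_ratio) {
    test_c <- log2(ratio_from_percent(mc))
    test_d <- log2(ratio_from_percent(md))
  }
  tests <- lapply(seq_len(nrow(comb)), function(i)
    student_t_unpaired(test_c[i, ], test_d[i, ], welch = welch))
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  tstat <- vapply(tests, `[[`, numeric(1), "t_stat")
  q <- benjamini_hochberg(p)
  mean_c <- rowMeans(mc); mean_d <- rowMeans(md)
  fc <- signed_fold_change(mean_c, mean_d)
  significant <- q < alpha & abs(fc) > fc_threshold

  out <- data.frame(protein_id = ids, gene_name = genes,
                    mean_C = mean_c, mean_D = mean_d, fc = fc,
                    t_stat = tstat, p_value = p, q_value = q,
                    significant = significant,
                    recovered_by = ifelse(ids %in% rescued,
                                          "ibaq_extreme", "none"),
                    log2_fc = sign(fc) * log2(abs(fc)),
                    neg_log10_q = -log10(q),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "audit") <- imp$audit
  attr(out, "counts") <- c(increased = sum(significant & fc > 0),
                           decreased = sum(significant & fc < 0),
                           total = nrow(out))
  out
}
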