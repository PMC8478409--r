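# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately restate each definition from first principles so
# the implementation is checked against something it does not share code with.

# Brute-force KNN imputation: exhaustive all-pairs distance enumeration.
knn_oracle <- function(x, k) {
  out <- x
  n_obs <- rowSums(!is.na(x))
  for (i in seq_len(nrow(x))) {
    if (n_obs[i] < 2) next
    for (j in which(is.na(x[i, ]))) {
      rows <- integer(0); dists <- numeric(0)
      for (h in seq_len(nrow(x))) {
        if (h == i || n_obs[h] < 2 || is.na(x[h, j])) next
        shared <- which(!is.na(x[i, ]) & !is.na(x[h, ]))
        if (!length(shared)) next
        rows <- c(rows, h)
        dists <- c(dists, sqrt(sum((x[i, shared] - x[h, shared])^2)))
      }
      nn <- rows[order(dists)][seq_len(min(k, length(rows)))]
      out[i, j] <- mean(x[nn, j])
    }
  }
  out
}

# Brute-force BH step-up: q_i = min over {j : p_j >= p_i} of p_j * n / rank_j,
# rank_j = #{p <= p_j}, clipped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  r <- vapply(p, function(pj) sum(p <= pj), numeric(1))
  v <- p * n / r
  q <- vapply(p, function(pi) min(1, min(v[p >= pi])), numeric(1))
  q
}

# Textbook pooled-variance two-sided t-test.
t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Kruskal-Wallis H from the rank formula (no ties assumed).
kw_oracle <- function(groups) {
  v <- unlist(groups)
  N <- length(v)
  rk <- rank(v)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(rk, idx, mean)
  12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
}

# A small quant_table built directly in code. `ratio`, `ibh`, `ibl` are
# matrices (proteins x samples); NA marks missing.
make_qt <- function(ratio, ibh = NULL, ibl = NULL, group = "A",
                    tissue = "testis", lysine = TRUE,
                    reverse = FALSE, contaminant = FALSE, site_only = FALSE) {
  n <- nrow(ratio); s <- ncol(ratio)
  if (is.null(ibh)) ibh <- matrix(1e6, n, s)
  if (is.null(ibl)) ibl <- matrix(1e6, n, s)
  quant_table(
    proteins = data.frame(
      protein_id = sprintf("P%03d", seq_len(n)),
      gene_name = sprintf("Gene%03d", seq_len(n)),
      has_lysine_peptides = rep_len(lysine, n),
      reverse_flag = rep_len(reverse, n),
      contaminant_flag = rep_len(contaminant, n),
      site_only_flag = rep_len(site_only, n),
      stringsAsFactors = FALSE),
    ratio_hl = ratio, ibaq_h = ibh, ibaq_l = ibl,
    samples = sample_spec(paste0(group, seq_len(s)), group, tissue))
}

# Write a 3-protein, 2-sample proteinGroups-dialect TSV fixture; `tweak`
# can edit the cell grid before writing.
write_pg_fixture <- function(path, tweak = identity) {
  header <- c("Protein IDs", "Gene names",
              "Ratio H/L s1", "Ratio H/L s2",
              "iBAQ H s1", "iBAQ H s2", "iBAQ L s1", "iBAQ L s2",
              "Lysine peptides", "Reverse", "Potential contaminant",
              "Only identified by site")
  rows <- list(
    c("P1;P1b", "Acan", "1", "2", "1000", "2000", "3000", "4000", "5", "", "", ""),
    c("P2", "Col2a1", "0.5", "0.25", "500", "600", "700", "800", "3", "", "", ""),
    c("P3", "Prg4", "4", "3", "100", "200", "300", "400", "2", "", "", ""))
  rows <- tweak(rows)
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

fixture_spec <- function() sample_spec(c("s1", "s2"), "A", "cartilage")
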