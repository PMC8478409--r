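#' Censoring-aware imputation of H/L ratios in the pulse-chase design
#'
#' In the pulse-chase comparison a missing iBAQ light channel in most
#' replicates of the pulse group is read as evidence of a fully labelled
#' protein (the light signal fell below detection), and a missing iBAQ heavy
#' channel in most replicates of the chase group as complete turnover (no
#' heavy signal left). Affected missing H/L ratios are imputed at the column
#' extremes: the observed column maximum + 0.1 for the fully-labelled case,
#' the observed column minimum - 0.01 (floored at a small positive epsilon,
#' since ratios must stay positive for the percentage transform) for the
#' fully-turned-over case. Only proteins with lysine-containing peptides are
#' imputed — only lysine carries the heavy label, so other proteins carry no
#' labelling information. Observed cells are never altered.
#'
#' @param table_a pulse-group [quant_table].
#' @param table_b chase-group [quant_table].
#' @param min_missing minimum number of replicates with the missing channel
#'   for the censoring interpretation to apply (default 3, i.e. strictly more
#'   than 2 of 4).
#' @param floor_ratio positive floor applied to the minimum-side imputation
#'   (default 1e-4).
#' @return list with `table_a`, `table_b` (imputed) and `audit`, a data.frame
#'   with one row per imputed cell (`protein_id`, `sample`, `scheme`,
#'   `imputed_value`, `basis`).
#' @export
impute_censored_pulse <- function(table_a, table_b, min_missing = 3,
                                  floor_ratio = 1e-4) {
  stopifnot(inherits(table_a, "quant_table"), inherits(table_b, "quant_table"))
  for (tb in list(table_a, table_b)) {
    empty <- colSums(!is.na(tb$ratio_hl)) == 0
    if (any(empty))
      stop("no observed H/L values in column ",
           dQuote(tb$samples$sample[which(empty)[1]]))
  }

  impute_one <- function(tb, channel, scheme) {
    miss_ch <- is.na(tb[[channel]])
    eligible <- tb$proteins$has_lysine_peptides &
      rowSums(miss_ch) >= min_missing
    audit <- list()
    for (j in seq_len(ncol(tb$ratio_hl))) {
      obs <- tb$ratio_hl[, j]
      target <- eligible & miss_ch[, j] & is.na(obs)
      if (!any(target)) next
      if (scheme == "censored_max") {
        value <- max(obs, na.rm = TRUE) + 0.1
        basis <- sprintf("column max %.6g + 0.1", max(obs, na.rm = TRUE))
      } else {
        value <- max(min(obs, na.rm = TRUE) - 0.01, floor_ratio)
        basis <- sprintf("column min %.6g - 0.01", min(obs, na.rm = TRUE))
      }
      tb$ratio_hl[target, j] <- value
      audit[[length(audit) + 1]] <- data.frame(
        protein_id = tb$proteins$protein_id[target],
        sample = tb$samples$sample[j], scheme = scheme,
        imputed_value = value, basis = basis, stringsAsFactors = FALSE)
    }
    list(table = tb, audit = do.call(rbind, c(audit, list(empty_audit()))))
  }

  a <- impute_one(table_a, "ibaq_l", "censored_max")
  b <- impute_one(table_b, "ibaq_h", "censored_min")
  list(table_a = a$table, table_b = b$table,
       audit = rbind(a$audit, b$audit))
}

empty_audit <- function() {
  data.frame(protein_id = character(), sample = character(),
             scheme = character(), imputed_value = numeric(),
             basis = character(), stringsAsFactors = FALSE)
}

#' K-nearest-neighbour imputation of an incorporation matrix
#'
#' Completes a proteins x samples matrix of percent incorporation. Each
#' missing cell is replaced by the mean of the target column's values over
#' the `k` rows nearest to the incomplete row, where distance is plain
#' Euclidean distance over the columns observed in both rows (all columns
#' share percent units, so no rescaling is applied) and candidate neighbours
#' must themselves carry a value in the target column. Distance ties are
#' broken by row order. Rows with fewer than 2 observed values carry too
#' little profile information and are rejected before imputation: they are
#' returned untouched and listed in the `"excluded_rows"` attribute.
#'
#' @param x numeric matrix with `NA` for missing cells.
#' @param k number of neighbours (default 3); must be at least 1 and smaller
#'   than the number of eligible rows. If fewer than `k` candidate neighbours
#'   exist for a particular cell, all candidates are used.
#' @return The completed matrix; observed cells are bit-identical to the
#'   input. Attributes: `excluded_rows` (indices left untouched).
#' @export
impute_knn <- function(x, k = 3) {
  stopifnot(is.matrix(x), is.numeric(x), k >= 1)
  n_obs <- rowSums(!is.na(x))
  eligible <- which(n_obs >= 2)
  if (k >= length(eligible))
    stop("k must be smaller than the number of rows with >= 2 observed values")
  out <- x
  for (i in eligible) {
    miss <- which(is.na(x[i, ]))
    if (!length(miss)) next
    obs_i <- !is.na(x[i, ])
    for (j in miss) {
      cand <- setdiff(eligible[!is.na(x[eligible, j])], i)
      if (!length(cand))
        stop("no eligible neighbour for row ", i, ", column ", j)
      d <- vapply(cand, function(h) {
        shared <- obs_i & !is.na(x[h, ])
        if (!any(shared)) return(Inf)
        sqrt(sum((x[i, shared] - x[h, shared])^2))
      }, numeric(1))
      cand <- cand[is.finite(d)]
      d <- d[is.finite(d)]
      if (!length(cand))
        stop("no eligible neighbour for row ", i, ", column ", j)
      nn <- cand[order(d)][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(x[nn, j])
    }
  }
  attr(out, "excluded_rows") <- setdiff(seq_len(nrow(x)), eligible)
  out
}

#' Seeded uniform-near-extreme imputation for one-group-absent proteins
#'
#' In the young (C) versus older adult (D) comparison, a protein whose H/L
#' ratio is reported in one group but in none of the replicates of the other
#' is interpreted through its iBAQ evidence in the ratio-less group: heavy
#' iBAQ present in at least `min_evidence` replicates means the protein is
#' essentially fully labelled there, so its missing ratios are drawn from
#' Uniform(max, max + sd); light iBAQ present (without the heavy evidence)
#' means no new incorporation, drawn from Uniform(0, min). `max`, `min` and
#' `sd` are taken over all observed H/L values of the combined C and D
#' tables ("of the dataset", in contrast to the per-column extremes of the
#' censored scheme). Draw bounds are open in practice (a continuous draw hits
#' an endpoint with probability 0). Draws are seeded and fully audited;
#' proteins qualifying for neither evidence rule stay missing and are logged.
#'
#' @param table_c,table_d [quant_table]s for groups C and D.
#' @param seed integer seed for the draws.
#' @param min_evidence minimum replicates with iBAQ evidence (default 2).
#' @return list with `table_c`, `table_d`, `audit` (one row per imputed cell,
#'   with the draw bounds and seed), and `unresolved` (protein/group pairs
#'   left missing).
#' @export
impute_extreme_uniform <- function(table_c, table_d, seed, min_evidence = 2) {
  stopifnot(inherits(table_c, "quant_table"), inherits(table_d, "quant_table"))
  if (missing(seed)) stop("seed is required for the uniform draws")
  all_obs <- c(table_c$ratio_hl, table_d$ratio_hl)
  all_obs <- all_obs[!is.na(all_obs)]
  if (length(all_obs) < 2)
    stop("cannot compute dataset max/min/sd: fewer than 2 observed H/L values")
  hi <- max(all_obs); lo <- min(all_obs); s <- stats::sd(all_obs)

  set.seed(seed)
  tabs <- list(table_c, table_d)
  audit <- list()
  unresolved <- list()
  for (idx in 1:2) {
    this <- tabs[[idx]]; other <- tabs[[3 - idx]]
    none_here <- rowSums(!is.na(this$ratio_hl)) == 0
    some_there <- rowSums(!is.na(other$ratio_hl)) > 0
    candidates <- which(none_here & some_there)
    for (i in candidates) {
      n_h <- sum(!is.na(this$ibaq_h[i, ]))
      n_l <- sum(!is.na(this$ibaq_l[i, ]))
      if (n_h >= min_evidence) {
        lwr <- hi; upr <- hi + s; scheme <- "uniform_max"
      } else if (n_l >= min_evidence) {
        lwr <- 0; upr <- lo; scheme <- "uniform_min"
      } else {
        unresolved[[length(unresolved) + 1]] <- data.frame(
          protein_id = this$proteins$protein_id[i],
          group = this$samples$group[1],
          reason = "insufficient iBAQ evidence", stringsAsFactors = FALSE)
        next
      }
      nrep <- ncol(this$ratio_hl)
      draws <- stats::runif(nrep, min = lwr, max = upr)
      this$ratio_hl[i, ] <- draws
      audit[[length(audit) + 1]] <- data.frame(
        protein_id = this$proteins$protein_id[i],
        sample = this$samples$sample, scheme = scheme,
        imputed_value = draws,
        basis = sprintf("Uniform(%.6g, %.6g), seed %d", lwr, upr, seed),
        stringsAsFactors = FALSE)
      tabs[[idx]] <- this
    }
  }
  list(table_c = tabs[[1]], table_d = tabs[[2]],
       audit = do.call(rbind, c(audit, list(empty_audit()))),
       unresolved = do.call(rbind, c(unresolved, list(
         data.frame(protein_id = character(), group = character(),
                    reason = character(), stringsAsFactors = FALSE)))))
}
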