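#' Convert a heavy/light ratio to percent label incorporation
#'
#' The fraction of a protein pool synthesised during the pulse is estimated
#' from the heavy/light ratio as `100 * (H/L) / ((H/L) + 1)`, a strictly
#' increasing bijection from `[0, Inf)` onto `[0, 100)`. `NA` inputs pass
#' through as `NA` (missing stays missing); negative or non-finite values are
#' rejected.
#'
#' @param ratio_hl heavy/light ratio(s), dimensionless, >= 0.
#' @return Percent incorporation in `[0, 100)`.
#' @seealso [ratio_from_percent()] for the inverse.
#' @export
incorporation_percent <- function(ratio_hl) {
  bad <- !is.na(ratio_hl) & (!is.finite(ratio_hl) | ratio_hl < 0)
  if (any(bad))
    stop("ratio_hl must be finite and non-negative; offending value: ",
         ratio_hl[which(bad)[1]])
  100 * ratio_hl / (ratio_hl + 1)
}

#' Invert percent incorporation back to a heavy/light ratio
#'
#' @param percent percent incorporation in `[0, 100)`; `NA` passes through.
#' @return Ratio `percent / (100 - percent)`.
#' @export
ratio_from_percent <- function(percent) {
  bad <- !is.na(percent) & (!is.finite(percent) | percent < 0 | percent >= 100)
  if (any(bad))
    stop("percent must lie in [0, 100); offending value: ",
         percent[which(bad)[1]])
  percent / (100 - percent)
}

#' Per-protein incorporation summary for one experimental group
#'
#' Aggregates replicate-level H/L ratios of one group into a per-protein mean
#' and standard deviation of percent incorporation (the mean of per-replicate
#' percentages, not the percentage of the mean ratio), and assigns a
#' quantification status:
#'
#' * `OK` — at least 2 replicates quantified; mean and SD reported.
#' * `ND` — not detected: no ratio and no iBAQ signal in any replicate.
#' * `NL` — not labelled: only the light isotope quantified (no H/L ratio and
#'   no iBAQ H anywhere, but iBAQ L present).
#' * `NQ` — not quantified: detected, but fewer than 2 replicates carry a
#'   ratio; no mean is reported.
#'
#' @param table a [quant_table].
#' @param group group label; the group must contribute at least 2 samples.
#' @return data.frame with columns `protein_id`, `group`, `tissue`,
#'   `percent_mean`, `percent_sd`, `n_quantified`, `status`.
#' @export
summarize_group <- function(table, group) {
  stopifnot(inherits(table, "quant_table"))
  cols <- which(table$samples$group == group)
  if (length(cols) < 2)
    stop("group ", dQuote(group), " has fewer than 2 samples")
  tissue <- table$samples$tissue[cols[1]]

  ratio <- table$ratio_hl[, cols, drop = FALSE]
  ibh <- table$ibaq_h[, cols, drop = FALSE]
  ibl <- table$ibaq_l[, cols, drop = FALSE]
  pct <- incorporation_percent(ratio)

  n_quant <- rowSums(!is.na(ratio))
  any_h <- rowSums(!is.na(ibh)) > 0
  any_l <- rowSums(!is.na(ibl)) > 0
  any_r <- n_quant > 0

  status <- rep("NQ", nrow(ratio))
  status[!any_r & !any_h & !any_l] <- "ND"
  status[!any_r & !any_h & any_l] <- "NL"
  status[n_quant >= 2] <- "OK"

  percent_mean <- ifelse(n_quant >= 2, rowMeans(pct, na.rm = TRUE), NA_real_)
  percent_sd <- ifelse(n_quant >= 2,
                       apply(pct, 1, stats::sd, na.rm = TRUE), NA_real_)

  data.frame(protein_id = table$proteins$protein_id,
             group = group, tissue = tissue,
             percent_mean = percent_mean, percent_sd = percent_sd,
             n_quantified = as.integer(n_quant), status = status,
             stringsAsFactors = FALSE)
}

#' Pulse-vs-chase retention profile
#'
#' Joins the pulse (group A) and chase (group B) incorporation summaries and
#' computes per-protein label retention `r = percentB / percentA`. Only
#' proteins with `OK` status in both groups enter the profile; exclusions
#' (non-OK status in either group, or a zero pulse percentage for which
#' retention is undefined) are recorded with a reason in the `"excluded"`
#' attribute.
#'
#' @param summary_a,summary_b data.frames from [summarize_group()] for the
#'   pulse and chase groups.
#' @return data.frame with columns `protein_id`, `percent_A`, `percent_B`,
#'   `retention`; excluded proteins in `attr(, "excluded")`.
#' @export
retention_profile <- function(summary_a, summary_b) {
  m <- merge(summary_a[, c("protein_id", "percent_mean", "status")],
             summary_b[, c("protein_id", "percent_mean", "status")],
             by = "protein_id", suffixes = c("_A", "_B"), all = TRUE,
             sort = FALSE)
  reason <- rep(NA_character_, nrow(m))
  reason[is.na(m$status_A) | m$status_A != "OK"] <- "not OK in pulse group"
  reason[is.na(m$status_B) | m$status_B != "OK"] <- "not OK in chase group"
  ok <- is.na(reason)
  reason[ok & m$percent_mean_A == 0] <- "zero pulse percentage"
  ok <- is.na(reason)

  out <- data.frame(protein_id = m$protein_id[ok],
                    percent_A = m$percent_mean_A[ok],
                    percent_B = m$percent_mean_B[ok],
                    retention = m$percent_mean_B[ok] / m$percent_mean_A[ok],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- data.frame(protein_id = m$protein_id[!ok],
                                      reason = reason[!ok],
                                      stringsAsFactors = FALSE)
  out
}
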