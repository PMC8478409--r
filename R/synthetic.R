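#' Configuration for the synthetic pulsed-SILAC generator
#'
#' Bundles every knob of the simulated experiment: a four-group design
#' (A: 3-week heavy pulse during skeletal growth; B: same pulse followed by a
#' 3-week light-diet chase; C: 3-week pulse in young adults; D: 3-week pulse
#' in older adults), first-order label incorporation with growth dilution,
#' 97% precursor enrichment, multiplicative replicate noise on the observed
#' H/L ratio, and intensity-dependent (missing-not-at-random) dropout of the
#' per-channel iBAQ intensities.
#'
#' @param n_proteins number of protein groups to simulate.
#' @param n_replicates replicates per group (>= 2; the emulated design uses 4).
#' @param pulse_days heavy-diet duration in days (default 21 = 3 weeks).
#' @param chase_days light-diet chase duration for group B, days (default 21).
#' @param enrichment precursor heavy-lysine enrichment p in (0, 1]; the
#'   labelled fraction plateaus at p (default 0.97, i.e. 97 atom % 13C diet).
#' @param k_mixture per-protein turnover rate model: a list with `weights`
#'   (fast/intermediate/slow mixture weights summing to 1), `meanlog` and
#'   `sdlog` (log-normal parameters of k, per day, one per component).
#'   Defaults put ~40% of proteins in a fast component (k ~ 0.2/day), ~40%
#'   intermediate (k ~ 0.03/day) and ~20% slow (k ~ 0.002/day), roughly the
#'   class proportions seen across the emulated tissues.
#' @param growth_rate named per-group growth-dilution rate g (per day).
#'   Groups A/B are growing animals (default 0.005/day, illustrative);
#'   C/D are skeletally mature (default 0).
#' @param ratio_cv multiplicative coefficient of variation of the observed
#'   H/L ratio across replicates (log-normal noise; default 0.2).
#' @param abundance_meanlog10,abundance_sdlog10 log10-normal protein
#'   abundance distribution feeding the iBAQ channels.
#' @param detection list controlling MNAR dropout: `enabled`, and the logistic
#'   of log10 channel intensity — `midpoint_log10` (intensity at 50% dropout)
#'   and `width_log10` (logistic scale). Low-intensity channels drop out, so
#'   near-fully-labelled proteins preferentially lose iBAQ L and
#'   near-unlabelled proteins lose iBAQ H; a missing channel also removes the
#'   H/L ratio for that replicate.
#' @param effect list with `fraction` (share of proteins whose turnover rate
#'   differs between groups C and D) and `size` (multiplicative drop of k in
#'   group D, emulating reduced incorporation with age; default 2-fold).
#' @param tissue tissue label stamped on the generated tables.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 500,
                             n_replicates = 4,
                             pulse_days = 21,
                             chase_days = 21,
                             enrichment = 0.97,
                             k_mixture = list(
                               weights = c(fast = 0.40, intermediate = 0.40,
                                           slow = 0.20),
                               meanlog = log(c(0.2, 0.03, 0.002)),
                               sdlog = c(0.3, 0.3, 0.3)),
                             growth_rate = c(A = 0.005, B = 0.005,
                                             C = 0, D = 0),
                             ratio_cv = 0.2,
                             abundance_meanlog10 = 7,
                             abundance_sdlog10 = 1,
                             detection = list(enabled = TRUE,
                                              midpoint_log10 = 5.5,
                                              width_log10 = 0.4),
                             effect = list(fraction = 0, size = 2),
                             tissue = "synthetic") {
  cfg <- list(n_proteins = n_proteins, n_replicates = n_replicates,
              pulse_days = pulse_days, chase_days = chase_days,
              enrichment = enrichment, k_mixture = k_mixture,
              growth_rate = growth_rate, ratio_cv = ratio_cv,
              abundance_meanlog10 = abundance_meanlog10,
              abundance_sdlog10 = abundance_sdlog10,
              detection = detection, effect = effect, tissue = tissue)
  stopifnot(n_proteins >= 1, n_replicates >= 2,
            pulse_days >= 0, chase_days >= 0,
            enrichment > 0, enrichment <= 1,
            ratio_cv >= 0,
            all(growth_rate >= 0),
            all(c("A", "B", "C", "D") %in% names(growth_rate)),
            length(k_mixture$weights) == length(k_mixture$meanlog),
            length(k_mixture$weights) == length(k_mixture$sdlog),
            all(k_mixture$weights >= 0),
            effect$fraction >= 0, effect$fraction <= 1, effect$size > 0)
  if (abs(sum(k_mixture$weights) - 1) > 1e-8)
    stop("k_mixture weights must sum to 1")
  class(cfg) <- "synthetic_config"
  cfg
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(args[[nm]] < 0, na.rm = TRUE))
      stop(nm, " must be non-negative")
  invisible(NULL)
}

#' Expected labelled fraction after a heavy pulse
#'
#' One-compartment first-order kinetics: a protein pool turning over at rate
#' `k` (per day) in a tissue expanding at rate `g` (per day) replaces its
#' unlabelled molecules at effective rate `k + g`, so after `t` days on a diet
#' with precursor enrichment `p` the labelled fraction is
#' `f = p * (1 - exp(-(k + g) * t))`, monotone in each argument and bounded by
#' the enrichment plateau `p`.
#'
#' @param k turnover rate constant, per day (>= 0).
#' @param g growth-dilution rate, per day (>= 0).
#' @param t pulse duration in days (>= 0).
#' @param p precursor enrichment in (0, 1].
#' @return Labelled fraction in `[0, p)`. Vectorised over `k`, `g`, `t`.
#' @export
expected_label_fraction <- function(k, g, t, p) {
  check_nonneg(k = k, g = g, t = t)
  stopifnot(all(p > 0), all(p <= 1))
  p * (1 - exp(-(k + g) * t))
}

#' Labelled fraction remaining after a light-diet chase
#'
#' During the chase no new label enters, and labelled molecules are lost by
#' the same effective rate, so `f_chase = f_pulse * exp(-(k + g) * t_chase)`.
#'
#' @param f_pulse labelled fraction at the end of the pulse, in `[0, 1)`.
#' @param k,g rates per day (>= 0).
#' @param t_chase chase duration in days (>= 0).
#' @return Labelled fraction, `0 <= f_chase <= f_pulse`.
#' @export
chase_retention <- function(f_pulse, k, g, t_chase) {
  check_nonneg(f_pulse = f_pulse, k = k, g = g, t_chase = t_chase)
  stopifnot(all(f_pulse < 1))
  f_pulse * exp(-(k + g) * t_chase)
}

#' Recover the effective turnover rate from percent incorporation
#'
#' Inverts the pulse kinetics: `k_eff = -log(1 - f / p) / t` with
#' `f = percent / 100`. The recovered rate is the effective rate `k + g`
#' (turnover plus growth dilution); the two are not separable from a single
#' pulse.
#'
#' @param percent percent heavy-label incorporation, with `percent/100 < p`.
#' @param t pulse duration in days (> 0).
#' @param p precursor enrichment in (0, 1].
#' @return Effective rate per day. Vectorised over `percent`.
#' @export
recover_rate <- function(percent, t, p) {
  check_nonneg(percent = percent)
  stopifnot(all(t > 0), all(p > 0), all(p <= 1))
  f <- percent / 100
  if (any(f >= p))
    stop("percent/100 >= enrichment: label saturated, rate unidentifiable")
  -log(1 - f / p) / t
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic four-group pulsed-SILAC dataset
#'
#' Draws per-protein turnover rates from the configured mixture, computes the
#' noiseless labelled fraction per group from the pulse/chase kinetics,
#' then emits one [quant_table] per group with replicate-level observations:
#' `H/L = f/(1-f) * eps` with log-normal `eps` (CV = `ratio_cv`),
#' `iBAQ H = abundance * f`, `iBAQ L = abundance * (1 - f)` (each with the
#' same replicate noise), and per-channel logistic dropout of low intensities.
#' A replicate whose iBAQ H or iBAQ L channel dropped out also loses its H/L
#' ratio, reproducing the censoring structure in which missing iBAQ L marks
#' near-complete labelling and missing iBAQ H marks near-complete turnover.
#'
#' The returned ground truth carries each protein's rate, its noiseless
#' fractions per group, its turnover class (the pulse-chase classifier applied
#' to the noiseless group A/B percentages), and its C-vs-D differential flag.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical seed and config give identical output.
#' @return list with `tables` (named list of [quant_table] for groups
#'   A, B, C, D), `truth` (data.frame), and `config`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_proteins
  nr <- config$n_replicates
  p <- config$enrichment

  comp <- sample(seq_along(config$k_mixture$weights), n, replace = TRUE,
                 prob = config$k_mixture$weights)
  k <- stats::rlnorm(n, meanlog = config$k_mixture$meanlog[comp],
                     sdlog = config$k_mixture$sdlog[comp])
  abundance <- 10^stats::rnorm(n, config$abundance_meanlog10,
                               config$abundance_sdlog10)
  differential <- stats::runif(n) < config$effect$fraction
  k_D <- ifelse(differential, k / config$effect$size, k)

  g <- config$growth_rate
  f <- list(
    A = expected_label_fraction(k, g[["A"]], config$pulse_days, p),
    B = chase_retention(
      expected_label_fraction(k, g[["B"]], config$pulse_days, p),
      k, g[["B"]], config$chase_days),
    C = expected_label_fraction(k, g[["C"]], config$pulse_days, p),
    D = expected_label_fraction(k_D, g[["D"]], config$pulse_days, p))

  protein_id <- sprintf("SYN%05d", seq_len(n))
  proteins <- data.frame(protein_id = protein_id,
                         gene_name = sprintf("Gene%05d", seq_len(n)),
                         has_lysine_peptides = TRUE,
                         reverse_flag = FALSE, contaminant_flag = FALSE,
                         site_only_flag = FALSE, stringsAsFactors = FALSE)

  make_group <- function(grp) {
    fg <- f[[grp]]
    spec <- sample_spec(paste0(grp, seq_len(nr)), grp, config$tissue)
    ratio <- ibh <- ibl <- matrix(NA_real_, n, nr)
    for (j in seq_len(nr)) {
      eps <- rlnorm_cv(n, config$ratio_cv)
      ratio[, j] <- fg / (1 - fg) * eps
      ch_noise <- rlnorm_cv(n, config$ratio_cv)
      ibh[, j] <- abundance * fg * ch_noise
      ibl[, j] <- abundance * (1 - fg) * ch_noise
      if (isTRUE(config$detection$enabled)) {
        drop_prob <- function(x) {
          stats::plogis((config$detection$midpoint_log10 - log10(pmax(x, 1e-12))) /
                          config$detection$width_log10)
        }
        drop_h <- stats::runif(n) < drop_prob(ibh[, j])
        drop_l <- stats::runif(n) < drop_prob(ibl[, j])
        ibh[drop_h, j] <- NA_real_
        ibl[drop_l, j] <- NA_real_
        ratio[drop_h | drop_l, j] <- NA_real_
      }
    }
    ratio[!is.na(ratio) & ratio <= 0] <- NA_real_
    quant_table(proteins, ratio, ibh, ibl, spec)
  }
  tables <- list(A = make_group("A"), B = make_group("B"),
                 C = make_group("C"), D = make_group("D"))

  true_class <- as.character(classify_turnover(100 * f$A, 100 * f$B)$class)
  truth <- data.frame(protein_id = protein_id, k = k, k_D = k_D,
                      component = names(config$k_mixture$weights)[comp],
                      abundance = abundance,
                      f_A = f$A, f_B = f$B, f_C = f$C, f_D = f$D,
                      true_class = true_class,
                      differential = differential,
                      stringsAsFactors = FALSE)
  list(tables = tables, truth = truth, config = config)
}
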