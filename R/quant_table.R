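#' Per-protein, per-sample quantification container
#'
#' A `quant_table` holds one tissue-and-group slice of a pulsed-SILAC
#' protein-group quantification: per-protein heavy/light ratios and per-channel
#' iBAQ intensities across replicate samples, together with row-level flags
#' (decoy, contaminant, identified-only-by-site, lysine-peptide evidence) and a
#' sample-to-group/tissue map.
#'
#' @param proteins data.frame with columns `protein_id`, `gene_name`,
#'   `has_lysine_peptides`, `reverse_flag`, `contaminant_flag`,
#'   `site_only_flag`. `protein_id` must be unique.
#' @param ratio_hl,ibaq_h,ibaq_l numeric matrices, proteins x samples. `NA`
#'   marks a missing cell. Ratios must be positive where present; iBAQ
#'   intensities non-negative.
#' @param samples data.frame with columns `sample`, `group`, `tissue`; one row
#'   per sample column of the matrices, `sample` unique.
#'
#' @return An object of class `quant_table`: a list with elements `proteins`,
#'   `ratio_hl`, `ibaq_h`, `ibaq_l`, `samples`.
#' @export
quant_table <- function(proteins, ratio_hl, ibaq_h, ibaq_l, samples) {
  stopifnot(is.data.frame(proteins), is.data.frame(samples))
  req <- c("protein_id", "gene_name", "has_lysine_peptides",
           "reverse_flag", "contaminant_flag", "site_only_flag")
  missing_cols <- setdiff(req, names(proteins))
  if (length(missing_cols))
    stop("proteins is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  missing_cols <- setdiff(c("sample", "group", "tissue"), names(samples))
  if (length(missing_cols))
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample))
    stop("duplicate sample id: ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "))

  n <- nrow(proteins)
  s <- nrow(samples)
  for (nm in c("ratio_hl", "ibaq_h", "ibaq_l")) {
    m <- get(nm)
    if (!is.matrix(m) || !is.numeric(m) || nrow(m) != n || ncol(m) != s)
      stop(nm, " must be a numeric ", n, " x ", s, " matrix")
  }
  if (any(ratio_hl <= 0, na.rm = TRUE))
    stop("ratio_hl must be strictly positive where present")
  if (any(!is.finite(ratio_hl) & !is.na(ratio_hl)))
    stop("ratio_hl must be finite where present")
  if (any(ibaq_h < 0, na.rm = TRUE) || any(ibaq_l < 0, na.rm = TRUE))
    stop("iBAQ intensities must be non-negative")

  dimnames(ratio_hl) <- dimnames(ibaq_h) <- dimnames(ibaq_l) <-
    list(proteins$protein_id, samples$sample)
  rownames(proteins) <- NULL
  rownames(samples) <- NULL
  structure(
    list(proteins = proteins, ratio_hl = ratio_hl,
         ibaq_h = ibaq_h, ibaq_l = ibaq_l, samples = samples),
    class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table: ", nrow(x$proteins), " protein groups x ",
      nrow(x$samples), " samples\n", sep = "")
  grp <- unique(paste0(x$samples$group, " (", x$samples$tissue, ")"))
  cat("  groups: ", paste(grp, collapse = ", "), "\n", sep = "")
  n_missing <- sum(is.na(x$ratio_hl))
  cat("  missing H/L cells: ", n_missing, " / ", length(x$ratio_hl), "\n",
      sep = "")
  flagged <- with(x$proteins, reverse_flag | contaminant_flag | site_only_flag)
  cat("  flagged rows (reverse/contaminant/site-only): ", sum(flagged), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) c(nrow(x$proteins), nrow(x$samples))

# Row subset preserving all slots; i may be logical or integer.
subset_quant <- function(x, i) {
  quant_table(x$proteins[i, , drop = FALSE],
              x$ratio_hl[i, , drop = FALSE],
              x$ibaq_h[i, , drop = FALSE],
              x$ibaq_l[i, , drop = FALSE],
              x$samples)
}
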