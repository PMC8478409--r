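#' Declare the sample layout of a proteinGroups table
#'
#' Maps the per-sample suffix of the MaxQuant quantification columns
#' ("Ratio H/L <sample>", "iBAQ H <sample>", "iBAQ L <sample>") to an
#' experimental group and a tissue.
#'
#' @param sample character vector of sample column suffixes (unique).
#' @param group experimental group label per sample (e.g. "A", "B", "C", "D").
#' @param tissue tissue label per sample.
#' @return data.frame with columns `sample`, `group`, `tissue`.
#' @export
sample_spec <- function(sample, group, tissue) {
  if (anyDuplicated(sample))
    stop("duplicate sample id: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  data.frame(sample = as.character(sample),
             group = as.character(rep_len(group, length(sample))),
             tissue = as.character(rep_len(tissue, length(sample))),
             stringsAsFactors = FALSE)
}

# Default column-name aliases for the proteinGroups dialect. MaxQuant column
# spellings drift across versions, so each logical field accepts several
# candidates, first match wins; override via the `aliases` argument.
mq_default_aliases <- function() {
  list(
    protein_ids  = c("Protein IDs", "Majority protein IDs"),
    gene_names   = c("Gene names", "Gene Names"),
    reverse      = c("Reverse"),
    contaminant  = c("Potential contaminant", "Contaminant"),
    site_only    = c("Only identified by site"),
    lysine_count = c("Lysine peptides", "Razor + unique peptides (K)",
                     "Unique peptides (K)", "Peptide counts (K)")
  )
}

find_alias <- function(header, candidates) {
  hit <- candidates[candidates %in% header]
  if (length(hit)) hit[[1]] else NA_character_
}

parse_numeric_col <- function(raw, col, zero_as_missing = FALSE) {
  raw <- trimws(raw)
  miss <- raw == "" | toupper(raw) %in% c("NA", "NAN")
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !miss)
  if (length(bad))
    stop("non-numeric value ", dQuote(raw[bad[1]]), " at row ", bad[1],
         ", column ", dQuote(col))
  out[miss] <- NA_real_
  if (zero_as_missing) out[!is.na(out) & out == 0] <- NA_real_
  out
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantification file in the MaxQuant
#' `proteinGroups` dialect into a [quant_table]. For every declared sample
#' `s` the columns `"Ratio H/L s"`, `"iBAQ H s"` and `"iBAQ L s"` must exist.
#'
#' Missing-value conventions are normalised on read: empty cells, `NA` and
#' `NaN` are missing in all numeric columns; iBAQ cells equal to exactly 0 are
#' also treated as missing (MaxQuant prints 0 for "no intensity"). A ratio of
#' 0 is invalid and rejected by the container. Protein groups are keyed by the
#' first accession of the semicolon-separated `"Protein IDs"` entry; row order
#' is preserved.
#'
#' Lysine-peptide evidence (`has_lysine_peptides`) is derived from a count
#' column when one is present (default aliases include `"Lysine peptides"` and
#' `"Razor + unique peptides (K)"`: count > 0 means evidence). When no such
#' column exists, every row defaults to `TRUE` with a warning, because
#' downstream imputation is gated on this flag.
#'
#' @param path path to the TSV file.
#' @param sample_spec data.frame from [sample_spec()] declaring the samples.
#' @param aliases optional named list overriding entries of the default
#'   column-alias table (fields: `protein_ids`, `gene_names`, `reverse`,
#'   `contaminant`, `site_only`, `lysine_count`).
#' @return A [quant_table].
#' @export
read_protein_groups <- function(path, sample_spec, aliases = list()) {
  stopifnot(is.data.frame(sample_spec),
            all(c("sample", "group", "tissue") %in% names(sample_spec)))
  al <- utils::modifyList(mq_default_aliases(), aliases)

  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  header <- names(raw)

  id_col <- find_alias(header, al$protein_ids)
  if (is.na(id_col))
    stop("missing required column ", dQuote(al$protein_ids[[1]]))
  needed <- as.vector(outer(c("Ratio H/L ", "iBAQ H ", "iBAQ L "),
                            sample_spec$sample, paste0))
  absent <- setdiff(needed, header)
  if (length(absent))
    stop("missing required column(s): ",
         paste(dQuote(absent), collapse = ", "))

  first_accession <- function(x) sub(";.*$", "", trimws(x))
  protein_id <- first_accession(raw[[id_col]])
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))

  gene_col <- find_alias(header, al$gene_names)
  gene_name <- if (is.na(gene_col)) rep("", nrow(raw)) else
    first_accession(raw[[gene_col]])

  flag_col <- function(field) {
    col <- find_alias(header, al[[field]])
    if (is.na(col)) rep(FALSE, nrow(raw)) else trimws(raw[[col]]) == "+"
  }
  reverse_flag <- flag_col("reverse")
  contaminant_flag <- flag_col("contaminant")
  site_only_flag <- flag_col("site_only")

  lys_col <- find_alias(header, al$lysine_count)
  if (is.na(lys_col)) {
    warning("no lysine-peptide count column found; assuming all protein ",
            "groups have lysine-containing peptides")
    has_lysine_peptides <- rep(TRUE, nrow(raw))
  } else {
    cnt <- parse_numeric_col(raw[[lys_col]], lys_col)
    has_lysine_peptides <- !is.na(cnt) & cnt > 0
  }

  grab <- function(prefix, zero_as_missing) {
    m <- vapply(sample_spec$sample, function(s) {
      parse_numeric_col(raw[[paste0(prefix, s)]], paste0(prefix, s),
                        zero_as_missing = zero_as_missing)
    }, numeric(nrow(raw)))
    matrix(m, nrow = nrow(raw), ncol = nrow(sample_spec))
  }
  ratio_hl <- grab("Ratio H/L ", zero_as_missing = FALSE)
  ibaq_h <- grab("iBAQ H ", zero_as_missing = TRUE)
  ibaq_l <- grab("iBAQ L ", zero_as_missing = TRUE)

  quant_table(
    proteins = data.frame(protein_id = protein_id, gene_name = gene_name,
                          has_lysine_peptides = has_lysine_peptides,
                          reverse_flag = reverse_flag,
                          contaminant_flag = contaminant_flag,
                          site_only_flag = site_only_flag,
                          stringsAsFactors = FALSE),
    ratio_hl = ratio_hl, ibaq_h = ibaq_h, ibaq_l = ibaq_l,
    samples = sample_spec[, c("sample", "group", "tissue")])
}

#' Remove decoy/contaminant rows and annotate imputability
#'
#' Drops rows flagged as reverse (decoy), potential contaminant, or identified
#' only by site. Rows lacking lysine-peptide evidence are retained but carry
#' `has_lysine_peptides = FALSE`, which downstream imputation honours (only
#' proteins with lysine-containing peptides are ever imputed, since only
#' lysine carries the heavy label). Numeric cells are never altered.
#'
#' @param table a [quant_table].
#' @return A [quant_table] with flagged rows removed.
#' @export
filter_quantifiable <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  keep <- !(table$proteins$reverse_flag | table$proteins$contaminant_flag |
              table$proteins$site_only_flag)
  subset_quant(table, keep)
}

#' Write a quant_table or result data.frame as TSV
#'
#' `quant_table` objects are serialised back to the proteinGroups dialect
#' (one row per protein; columns `Protein IDs`, `Gene names`,
#' `Ratio H/L <s>` / `iBAQ H <s>` / `iBAQ L <s>` per sample, `Lysine
#' peptides`, `Reverse`, `Potential contaminant`, `Only identified by site`),
#' so that `read_protein_groups(write_table(x), spec)` round-trips on the
#' value level. Plain data.frames are written as-is. Missing values are
#' serialised as `"NA"`; encoding is UTF-8.
#'
#' @param x a [quant_table] or data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "quant_table")) {
    df <- data.frame(`Protein IDs` = x$proteins$protein_id,
                     `Gene names` = x$proteins$gene_name,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (s in x$samples$sample) {
      df[[paste0("Ratio H/L ", s)]] <- x$ratio_hl[, s]
      df[[paste0("iBAQ H ", s)]] <- x$ibaq_h[, s]
      df[[paste0("iBAQ L ", s)]] <- x$ibaq_l[, s]
    }
    df[["Lysine peptides"]] <- as.integer(x$proteins$has_lysine_peptides)
    df[["Reverse"]] <- ifelse(x$proteins$reverse_flag, "+", "")
    df[["Potential contaminant"]] <- ifelse(x$proteins$contaminant_flag, "+", "")
    df[["Only identified by site"]] <- ifelse(x$proteins$site_only_flag, "+", "")
    x <- df
  }
  stopifnot(is.data.frame(x))
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
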