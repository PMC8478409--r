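#' Read a matrisome annotation table
#'
#' The matrisome — collagens, proteoglycans, glycoproteins and ECM-associated
#' proteins — is annotated from a user-supplied two- or three-column TSV:
#' `key` (gene symbol or accession), `category`, and optionally `subfamily`
#' (e.g. fibrillar / FACIT / network / beaded-filament for collagens).
#' Keys must be unique (case-insensitively).
#'
#' @param path TSV file path.
#' @return data.frame with columns `key`, `category`, `subfamily`.
#' @export
read_matrisome_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2)
    stop("annotation file must have at least 2 columns (key, category)")
  out <- data.frame(key = as.character(df[[1]]),
                    category = as.character(df[[2]]),
                    subfamily = if (ncol(df) >= 3) as.character(df[[3]]) else
                      NA_character_,
                    stringsAsFactors = FALSE)
  dup <- duplicated(tolower(out$key))
  if (any(dup))
    stop("duplicate annotation key: ",
         paste(unique(out$key[dup]), collapse = ", "))
  out
}

#' Annotate proteins with matrisome categories
#'
#' Case-insensitive lookup by gene symbol with an optional accession
#' fallback; anything unmatched defaults to category `"other"`. Match
#' statistics (matched by gene, by fallback, unmatched) are stored in
#' `attr(, "match_stats")`.
#'
#' @param keys primary lookup keys (gene symbols).
#' @param annotation data.frame from [read_matrisome_annotation()] (or of the
#'   same shape).
#' @param fallback_keys optional secondary keys (accessions) tried where the
#'   primary key does not match.
#' @return data.frame with columns `key`, `category`, `subfamily`.
#' @export
annotate_matrisome <- function(keys, annotation, fallback_keys = NULL) {
  stopifnot(all(c("key", "category") %in% names(annotation)))
  if (anyDuplicated(tolower(annotation$key)))
    stop("duplicate annotation key: ",
         paste(unique(annotation$key[duplicated(tolower(annotation$key))]),
               collapse = ", "))
  lut <- tolower(annotation$key)
  idx <- match(tolower(keys), lut)
  n_gene <- sum(!is.na(idx))
  if (!is.null(fallback_keys)) {
    fb <- match(tolower(fallback_keys), lut)
    idx[is.na(idx)] <- fb[is.na(idx)]
  }
  subfam <- if ("subfamily" %in% names(annotation)) annotation$subfamily else
    rep(NA_character_, nrow(annotation))
  out <- data.frame(key = keys,
                    category = ifelse(is.na(idx), "other",
                                      annotation$category[idx]),
                    subfamily = subfam[idx],
                    stringsAsFactors = FALSE)
  attr(out, "match_stats") <- c(matched_gene = n_gene,
                                matched_fallback = sum(!is.na(idx)) - n_gene,
                                unmatched = sum(is.na(idx)))
  out
}

#' Display-style percentage of a count pair
#'
#' Computes `100 * n / total` exactly and alongside it the two-significant-
#' figure display value used in reporting (e.g. 142/171 -> 83, 6/171 -> 3.5,
#' 115/634 -> 18). Full precision is always retained in the `percent` field;
#' rounding is display-only.
#'
#' @param n count in the class (vectorised).
#' @param total total count (> 0).
#' @return list with `percent` (exact) and `display` (two significant
#'   figures).
#' @export
class_fraction <- function(n, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(n < 0 | n > total)) stop("n must lie in [0, total]")
  pct <- 100 * n / total
  list(percent = pct, display = signif(pct, 2))
}

#' Matrisome category summaries of turnover and incorporation
#'
#' For each matrisome category: counts per turnover class (with the matrisome
#' share of each class), mean/SD percent incorporation per experimental group
#' where incorporation summaries are supplied, and the top 3 most-retained
#' members (highest retention ratio r) per category.
#'
#' @param calls data.frame with `protein_id`, `retention`, `class` (e.g. a
#'   classified [retention_profile()]).
#' @param annotations data.frame from [annotate_matrisome()] aligned to
#'   `calls` rows (same order), or carrying a `protein_id` column to merge on.
#' @param summaries optional stacked output of [summarize_group()] across
#'   groups, used for per-category group statistics.
#' @param n_top how many top-retained members to report per category.
#' @return list with `class_by_category` (category x class counts),
#'   `top_retained`, and (if `summaries` given) `group_stats`.
#' @export
category_summary <- function(calls, annotations, summaries = NULL,
                             n_top = 3) {
  stopifnot(nrow(annotations) == nrow(calls))
  df <- cbind(calls, category = annotations$category,
              stringsAsFactors = FALSE)

  tab <- as.data.frame(table(category = df$category, class = df$class),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  cls_tot <- stats::aggregate(n ~ class, tab, sum)
  tab$class_total <- cls_tot$n[match(tab$class, cls_tot$class)]

  ord <- df[order(-df$retention), ]
  top <- do.call(rbind, lapply(split(ord, ord$category), function(g)
    utils::head(g[, c("category", "protein_id", "retention")], n_top)))
  rownames(top) <- NULL

  out <- list(class_by_category = tab, top_retained = top)
  if (!is.null(summaries)) {
    s <- merge(summaries[summaries$status == "OK", ],
               df[, c("protein_id", "category")], by = "protein_id")
    gs <- stats::aggregate(percent_mean ~ category + group, s,
                           function(v) c(mean = mean(v), sd = stats::sd(v),
                                         n = length(v)))
    gs <- cbind(gs[c("category", "group")], as.data.frame(gs$percent_mean))
    out$group_stats <- gs
  }
  out
}
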