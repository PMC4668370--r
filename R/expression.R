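#' Classify genes as up-, down-regulated or unchanged
#'
#' Applies effect-size and FDR thresholds to a differential-expression
#' table: `up` when `log2fc >= min_abs_log2fc` and `q_value <= q_max`,
#' `down` for the mirrored condition, otherwise `unchanged`. The defaults
#' (q <= 0.05, |log2fc| >= 1) are the package's own convention and are
#' configurable.
#'
#' @param de_table `data.frame` with one row per gene and columns
#'   `gene_id`, `log2fc`, `q_value` (additional columns such as per-
#'   condition FPKM are carried through).
#' @param q_max FDR ceiling for a differential call.
#' @param min_abs_log2fc Minimum absolute log2 fold change.
#' @return `de_table` with an added factor column `de_class` with levels
#'   `up`, `down`, `unchanged`.
#' @export
classify_expression <- function(de_table, q_max = 0.05, min_abs_log2fc = 1.0) {
  req <- c("gene_id", "log2fc", "q_value")
  miss <- setdiff(req, names(de_table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(de_table$gene_id)) stop("duplicate gene ids")
  if (any(de_table$q_value < 0 | de_table$q_value > 1, na.rm = TRUE))
    stop("q_value outside [0, 1]")
  cls <- ifelse(de_table$q_value <= q_max & de_table$log2fc >= min_abs_log2fc, "up",
         ifelse(de_table$q_value <= q_max & de_table$log2fc <= -min_abs_log2fc, "down",
                "unchanged"))
  de_table$de_class <- factor(cls, levels = c("up", "down", "unchanged"))
  de_table
}

## Inner join of binned 5-hmC records with expression rows; drops (and
## counts) genes present on only one side.
join_hmc_expression <- function(records, expr) {
  if (is.null(records$bin)) stop("records must be binned; see bin_by_percentile()")
  j <- merge(records, expr, by = "gene_id")
  if (nrow(j) == 0) stop("no genes shared between 5-hmC records and expression table")
  attr(j, "n_hmc_only") <- sum(!records$gene_id %in% expr$gene_id)
  attr(j, "n_expr_only") <- sum(!expr$gene_id %in% records$gene_id)
  j
}

#' Expression summarized by 5-hmC density bin
#'
#' Joins gene-level 5-hmC records with an expression table and reports,
#' per density bin, the number of genes and the median and quartiles of
#' expression. Bins with no genes after the join are kept with `n = 0`.
#'
#' @param records Binned output of [bin_by_percentile()].
#' @param expr Expression `data.frame` with `gene_id` and the column named
#'   by `value_col`.
#' @param value_col Expression column to summarize (default `"fpkm"`).
#' @return A `data.frame` with columns `bin`, `n`, `q1`, `median`, `q3`,
#'   ordered from the lowest to the highest density bin, with attributes
#'   `n_hmc_only` / `n_expr_only` counting genes dropped by the join.
#' @export
expression_by_hmc_bin <- function(records, expr, value_col = "fpkm") {
  if (!value_col %in% names(expr)) stop("expression table lacks column ", value_col)
  j <- join_hmc_expression(records, expr)
  lev <- levels(records$bin)
  out <- do.call(rbind, lapply(lev, function(b) {
    v <- j[[value_col]][j$bin == b]
    if (length(v) == 0)
      data.frame(bin = b, n = 0L, q1 = NA_real_, median = NA_real_, q3 = NA_real_)
    else
      data.frame(bin = b, n = length(v),
                 q1 = unname(stats::quantile(v, 0.25)),
                 median = stats::median(v),
                 q3 = unname(stats::quantile(v, 0.75)))
  }))
  out$bin <- factor(out$bin, levels = lev, ordered = TRUE)
  attr(out, "n_hmc_only") <- attr(j, "n_hmc_only")
  attr(out, "n_expr_only") <- attr(j, "n_expr_only")
  out
}

#' Association between 5-hmC bin and differential-expression class
#'
#' Builds the bins-by-class contingency table over the joined gene set and
#' tests independence with Pearson's chi-squared (no continuity
#' correction). Rows or columns that are entirely zero are dropped with a
#' warning and the degrees of freedom adjusted.
#'
#' @param records Binned output of [bin_by_percentile()].
#' @param expr Expression table carrying a `de_class` column (see
#'   [classify_expression()]).
#' @return A list with `table` (observed counts), `expected` (expected
#'   counts under independence), `chi2`, `df`, `p_value`.
#' @export
bin_class_association <- function(records, expr) {
  if (is.null(expr$de_class)) stop("expression table lacks de_class; see classify_expression()")
  j <- join_hmc_expression(records, expr)
  tab <- table(bin = j$bin, class = j$de_class)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s) from contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table degenerate after dropping empty margins")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, expected = ct$expected,
       chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Median log2 fold change per 5-hmC bin
#'
#' @param records Binned output of [bin_by_percentile()].
#' @param expr Expression table with a `log2fc` column.
#' @return A `data.frame` with columns `bin`, `n`, `median_log2fc`.
#' @export
median_fold_change_by_bin <- function(records, expr) {
  j <- join_hmc_expression(records, expr)
  lev <- levels(records$bin)
  out <- do.call(rbind, lapply(lev, function(b) {
    v <- j$log2fc[j$bin == b]
    data.frame(bin = b, n = length(v),
               median_log2fc = if (length(v)) stats::median(v) else NA_real_)
  }))
  out$bin <- factor(out$bin, levels = lev, ordered = TRUE)
  out
}

#' Read a differential-expression table
#'
#' Tab-separated with header; requires columns `gene_id`, `log2fc`,
#' `q_value`; per-condition FPKM columns (e.g. `fpkm_a`, `fpkm_b` or
#' `fpkm`) are carried through.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "log2fc", "q_value"), names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tab
}
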