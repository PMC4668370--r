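#' Call genes gaining or losing 5-hmC between tumor and normal
#'
#' Presence/absence rule on consensus peak coverage: a gene loses 5-hmC
#' when its body is hit by the normal consensus but not the tumor
#' consensus; it gains when hit by tumor only. Genes hit by both or
#' neither are uncalled. An alternative density-ratio criterion
#' (`|log2(tumor density / normal density)| >= lfc_min` over gene-body tag
#' densities) is available via `mode = "density"`.
#'
#' @param genes A `GeneModels` object (or gene-body `GRanges`).
#' @param normal_consensus,tumor_consensus Merged consensus `GRanges`
#'   (see [consensus()]).
#' @param mode `"presence"` (default) or `"density"`.
#' @param normal_density,tumor_density Named per-gene density vectors,
#'   required for `mode = "density"`.
#' @param lfc_min Density-mode threshold on |log2 ratio| (default 1).
#' @return A `data.frame` with columns `gene_id` and `direction`
#'   (`"gain"` or `"loss"`); zero rows when nothing is called.
#' @export
call_hmc_change <- function(genes, normal_consensus, tumor_consensus,
                            mode = c("presence", "density"),
                            normal_density = NULL, tumor_density = NULL,
                            lfc_min = 1) {
  mode <- match.arg(mode)
  ids <- gene_ids(genes)
  if (mode == "presence") {
    bodies <- get_bodies(genes)
    in_n <- countOverlaps(bodies, normal_consensus, ignore.strand = TRUE) > 0
    in_t <- countOverlaps(bodies, tumor_consensus, ignore.strand = TRUE) > 0
    loss <- in_n & !in_t
    gain <- in_t & !in_n
  } else {
    if (is.null(normal_density) || is.null(tumor_density))
      stop("density mode requires normal_density and tumor_density")
    dn <- normal_density[ids]; dt <- tumor_density[ids]
    dn[is.na(dn)] <- 0; dt[is.na(dt)] <- 0
    lr <- log2((dt + 1e-9) / (dn + 1e-9))
    loss <- lr <= -lfc_min
    gain <- lr >= lfc_min
  }
  data.frame(gene_id = c(ids[loss], ids[gain]),
             direction = rep(c("loss", "gain"), c(sum(loss), sum(gain))),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test reporting the rank sum of `x` and a two-sided
#' p-value: exact by enumeration when the combined sample size is at most
#' 12 and there are no ties, otherwise the normal approximation with tie
#' and continuity corrections (via [stats::wilcox.test()]). Two identical
#' samples give p = 1.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_max Combined sample size up to which the exact null
#'   distribution is used (when tie-free).
#' @return A list with `rank_sum` (of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  rank_sum <- sum(r[seq_len(m)])
  if (length(unique(c(x, y))) == 1)
    return(list(rank_sum = rank_sum, p_value = 1))
  ties <- any(duplicated(c(x, y)))
  use_exact <- (m + n) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(rank_sum = rank_sum, p_value = wt$p.value)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` where `m` is the number of tests (family size).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  pmin(1, m * p)
}

#' Concordance between 5-hmC change and expression change
#'
#' For every gene called as gaining or losing 5-hmC, tests tumor-vs-normal
#' expression with the Wilcoxon rank-sum test, adjusts the p-values by
#' Bonferroni across the genes actually tested, and counts concordant
#' changes: a loss gene "lost expression" when the adjusted p is at most
#' `alpha` and the tumor median is below the normal median; a gain gene
#' "gained expression" analogously.
#'
#' @param calls `data.frame` from [call_hmc_change()].
#' @param expr Numeric matrix of expression values, genes in rows (row
#'   names are gene ids), samples in columns.
#' @param groups Character vector (one per column of `expr`) with values
#'   `"tumor"` or `"normal"`.
#' @param alpha Significance level on the adjusted p-value.
#' @return A list with the four concordance counts `n_loss_total`,
#'   `n_loss_expr_down`, `n_gain_total`, `n_gain_expr_up`, the number of
#'   called genes lacking expression data (`n_missing_expr`), and a
#'   per-gene `detail` data frame (`gene_id`, `direction`, `p_value`,
#'   `p_adjusted`, `median_tumor`, `median_normal`, `concordant`).
#' @export
concordance_counts <- function(calls, expr, groups, alpha = 0.05) {
  stopifnot(ncol(expr) == length(groups))
  if (!all(groups %in% c("tumor", "normal")))
    stop("groups must be 'tumor' or 'normal'")
  have <- calls$gene_id %in% rownames(expr)
  tested <- calls[have, , drop = FALSE]
  tum <- groups == "tumor"
  if (nrow(tested) > 0) {
    res <- lapply(tested$gene_id, function(g) {
      v <- expr[g, ]
      w <- wilcoxon_rank_sum(v[tum], v[!tum])
      c(p = w$p_value, mt = stats::median(v[tum]), mn = stats::median(v[!tum]))
    })
    res <- do.call(rbind, res)
    p_adj <- bonferroni(res[, "p"])
    sig <- p_adj <= alpha
    down <- sig & res[, "mt"] < res[, "mn"]
    up <- sig & res[, "mt"] > res[, "mn"]
    concord <- ifelse(tested$direction == "loss", down, up)
    detail <- data.frame(gene_id = tested$gene_id, direction = tested$direction,
                         p_value = res[, "p"], p_adjusted = p_adj,
                         median_tumor = res[, "mt"], median_normal = res[, "mn"],
                         concordant = concord, stringsAsFactors = FALSE,
                         row.names = NULL)
  } else {
    detail <- data.frame(gene_id = character(), direction = character(),
                         p_value = numeric(), p_adjusted = numeric(),
                         median_tumor = numeric(), median_normal = numeric(),
                         concordant = logical(), stringsAsFactors = FALSE)
  }
  list(n_loss_total = sum(calls$direction == "loss"),
       n_loss_expr_down = sum(detail$concordant[detail$direction == "loss"]),
       n_gain_total = sum(calls$direction == "gain"),
       n_gain_expr_up = sum(detail$concordant[detail$direction == "gain"]),
       n_missing_expr = sum(!have),
       detail = detail)
}

#' Read a genes-by-samples expression matrix with a group-label row
#'
#' Tab-separated: first column gene ids, remaining columns samples; a
#' first data row labelled `group` gives each sample's `tumor`/`normal`
#' label.
#'
#' @param path Path to the TSV file.
#' @return A list with `expr` (numeric matrix) and `groups` (character).
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"group" %in% rownames(tab)) stop("expression matrix lacks a 'group' row")
  groups <- as.character(unlist(tab["group", ]))
  expr <- as.matrix(tab[rownames(tab) != "group", , drop = FALSE])
  mode(expr) <- "numeric"
  list(expr = expr, groups = groups)
}

#' Write an expression matrix with group labels
#'
#' @param expr Numeric matrix (genes x samples).
#' @param groups Character vector of sample group labels.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, groups, path) {
  body <- rbind(group = groups, expr)
  out <- data.frame(gene_id = rownames(body), body, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
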