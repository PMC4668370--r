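#' Three-state cytosine quantification from bisulfite / TAB-seq clone counts
#'
#' Standard bisulfite sequencing protects both 5-mC and 5-hmC from
#' conversion (both read C), whereas TET-assisted bisulfite (TAB)
#' treatment protects only 5-hmC. Per CpG and condition, with clone
#' counts `bs_c`/`bs_t` (reads C / T after bisulfite) and `tab_c`/`tab_t`
#' (after TAB):
#' \deqn{pct5hmC = 100 f_{tab}, \quad
#'       pct5mC = 100 \max(0, f_{bs} - f_{tab}), \quad
#'       pctC = 100 - pct5hmC - pct5mC}
#' where `f_bs = bs_c/(bs_c+bs_t)` and `f_tab = tab_c/(tab_c+tab_t)`.
#' When sampling noise makes `f_tab > f_bs` the 5-mC estimate is clamped
#' at 0 (flagged in the output) and unmodified cytosine absorbs the
#' remainder, keeping the three percentages on the simplex.
#'
#' @param sites `data.frame` with columns `chrom`, `pos`, `condition`,
#'   `bs_c`, `bs_t`, `tab_c`, `tab_t` (one row per CpG and condition).
#' @param min_clones Minimum clones per treatment for a site to be
#'   quantified (default 16); sites below the floor are flagged
#'   `low_coverage` and excluded from downstream tests.
#' @return `sites` with added columns `pct_5hmC`, `pct_5mC`, `pct_C`
#'   (NA for low-coverage sites), `clamped` (TRUE where the 5-mC clamp
#'   fired) and `low_coverage`.
#' @export
site_modification <- function(sites, min_clones = 16) {
  req <- c("chrom", "pos", "condition", "bs_c", "bs_t", "tab_c", "tab_t")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cnt <- sites[, c("bs_c", "bs_t", "tab_c", "tab_t")]
  if (any(cnt < 0)) stop("clone counts must be non-negative")
  bs_n <- sites$bs_c + sites$bs_t
  tab_n <- sites$tab_c + sites$tab_t
  low <- bs_n < min_clones | tab_n < min_clones
  f_bs <- ifelse(bs_n > 0, sites$bs_c / bs_n, NA_real_)
  f_tab <- ifelse(tab_n > 0, sites$tab_c / tab_n, NA_real_)
  clamped <- !is.na(f_bs) & !is.na(f_tab) & f_tab > f_bs
  if (any(clamped & !low))
    warning(sum(clamped & !low),
            " site(s) with f_tab > f_bs; 5-mC clamped to 0 (sampling noise)")
  pct_5hmC <- 100 * f_tab
  pct_5mC <- 100 * pmax(0, f_bs - f_tab)
  pct_C <- 100 - pct_5hmC - pct_5mC
  pct_5hmC[low] <- pct_5mC[low] <- pct_C[low] <- NA_real_
  sites$pct_5hmC <- pct_5hmC
  sites$pct_5mC <- pct_5mC
  sites$pct_C <- pct_C
  sites$clamped <- clamped & !low
  sites$low_coverage <- low
  sites
}

#' Chi-squared comparison of two conditions over a region
#'
#' Pools clone counts across the region's quantified CpGs into a 2x2
#' table of (C, T) calls per condition in the chosen channel and applies
#' Pearson's chi-squared test with one degree of freedom. The `"tab"`
#' channel compares 5-hmC; `"bs"` compares total modification
#' (5-mC + 5-hmC). Per-site tables (`pool = FALSE`) are also available,
#' though individual CpGs at typical clone depth are underpowered.
#'
#' @param sites Output of [site_modification()] (low-coverage sites are
#'   excluded).
#' @param condition_a,condition_b Condition labels to compare.
#' @param channel `"tab"` (default) or `"bs"`.
#' @param pool Pool counts across CpGs (default) or test each site.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return For pooled mode, a list with `table`, `chi2`, `df`, `p_value`;
#'   a zero margin gives `p_value = 1` with a warning. For per-site mode,
#'   a `data.frame` with one test per CpG.
#' @export
compare_conditions <- function(sites, condition_a, condition_b,
                               channel = c("tab", "bs"), pool = TRUE,
                               correct = FALSE) {
  channel <- match.arg(channel)
  if (is.null(sites$low_coverage)) sites <- site_modification(sites)
  ok <- !sites$low_coverage
  a <- sites[ok & sites$condition == condition_a, , drop = FALSE]
  b <- sites[ok & sites$condition == condition_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("need at least one quantified site in each condition")
  cc <- paste0(channel, "_c"); ct <- paste0(channel, "_t")
  if (pool) {
    tab <- rbind(c(sum(a[[cc]]), sum(a[[ct]])),
                 c(sum(b[[cc]]), sum(b[[ct]])))
    dimnames(tab) <- list(condition = c(condition_a, condition_b),
                          call = c("C", "T"))
    chi2_2x2(tab, correct)
  } else {
    key_a <- paste(a$chrom, a$pos)
    key_b <- paste(b$chrom, b$pos)
    shared <- intersect(key_a, key_b)
    do.call(rbind, lapply(shared, function(k) {
      ra <- a[key_a == k, ][1, ]; rb <- b[key_b == k, ][1, ]
      tab <- rbind(c(ra[[cc]], ra[[ct]]), c(rb[[cc]], rb[[ct]]))
      res <- chi2_2x2(tab, correct)
      data.frame(chrom = ra$chrom, pos = ra$pos, chi2 = res$chi2,
                 df = res$df, p_value = res$p_value)
    }))
  }
}

chi2_2x2 <- function(tab, correct = FALSE) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p = 1")
    return(list(table = tab, chi2 = 0, df = 1L, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, chi2 = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}

#' Read a TAB-seq clone-count table
#'
#' Tab-separated with header and columns `chrom`, `pos`, `condition`,
#' `treatment` (`bs` or `tab`), `n_C`, `n_T`; the long layout is widened
#' to one row per CpG and condition.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `chrom`, `pos`, `condition`,
#'   `bs_c`, `bs_t`, `tab_c`, `tab_t`.
#' @export
read_tabseq <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "condition", "treatment", "n_C", "n_T")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(tab$treatment %in% c("bs", "tab")))
    stop("treatment must be 'bs' or 'tab'")
  key <- unique(tab[, c("chrom", "pos", "condition")])
  wide <- key
  for (tr in c("bs", "tab")) {
    sub <- tab[tab$treatment == tr, ]
    idx <- match(paste(key$chrom, key$pos, key$condition),
                 paste(sub$chrom, sub$pos, sub$condition))
    wide[[paste0(tr, "_c")]] <- ifelse(is.na(idx), 0L, sub$n_C[idx])
    wide[[paste0(tr, "_t")]] <- ifelse(is.na(idx), 0L, sub$n_T[idx])
  }
  wide
}

#' Write a TAB-seq clone-count table (long layout)
#'
#' @param sites Wide `data.frame` as returned by [read_tabseq()].
#' @param path Output path.
#' @export
write_tabseq <- function(sites, path) {
  long <- rbind(
    data.frame(chrom = sites$chrom, pos = sites$pos,
               condition = sites$condition, treatment = "bs",
               n_C = sites$bs_c, n_T = sites$bs_t),
    data.frame(chrom = sites$chrom, pos = sites$pos,
               condition = sites$condition, treatment = "tab",
               n_C = sites$tab_c, n_T = sites$tab_t))
  long <- long[order(long$chrom, long$pos, long$condition, long$treatment), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
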