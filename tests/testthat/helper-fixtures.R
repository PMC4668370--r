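suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## BED-style (0-based half-open) interval constructor for readable tests.
gi <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start + 1L, end), strand = strand)
}

## Independent per-base accumulation oracle for the tag-overlap statistic:
## each annotation base receives the density of every peak covering it.
brute_observed_tags <- function(pk, annotation, genome_len,
                                chroms = names(genome_len)) {
  total <- 0
  for (ch in chroms) {
    dens <- numeric(genome_len[[ch]])
    sel <- as.character(seqnames(pk)) == ch
    for (i in which(sel)) {
      idx <- start(pk)[i]:end(pk)[i]
      dens[idx] <- dens[idx] + mcols(pk)$density[i]
    }
    asel <- as.character(seqnames(annotation)) == ch
    for (j in which(asel))
      total <- total + sum(dens[start(annotation)[j]:end(annotation)[j]])
  }
  total
}

## Per-base union oracle for coverage.
brute_coverage_bases <- function(gr, genome_len) {
  total <- 0
  for (ch in names(genome_len)) {
    covered <- logical(genome_len[[ch]])
    sel <- as.character(seqnames(gr)) == ch
    for (i in which(sel)) covered[start(gr)[i]:end(gr)[i]] <- TRUE
    total <- total + sum(covered)
  }
  total
}

## Textbook Pearson chi-squared on a contingency table.
chi2_formula <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

## Exhaustive-enumeration oracle for the two-sided exact Wilcoxon rank-sum
## p-value (tie-free samples): enumerate every assignment of ranks to x.
wilcox_enum <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  u_all <- apply(sets, 2, function(s) sum(s) - m * (m + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(rank_sum = sum(r[seq_len(m)]),
       p = min(1, 2 * min(p_le, p_ge)))
}

## Small random peak set on the given Seqinfo.
random_peaks <- function(n, sizes, max_width = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slen <- GenomeInfoDb::seqlengths(sizes)
  ch <- sample(names(slen), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  st <- vapply(seq_len(n),
               function(i) sample.int(slen[[ch[i]]] - w[i], 1), integer(1))
  peaks(ch, st, st + w, tags = sample.int(100, n, replace = TRUE),
        sizes = sizes)
}
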