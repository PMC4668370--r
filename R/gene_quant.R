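#' Genes with peaks within a flank of their body
#'
#' The gene-list rule used for pathway analysis: a gene qualifies when at
#' least one peak overlaps its body extended by `flank` bases on each side
#' (default 2 kb) by at least one base.
#'
#' @param genes A `GeneModels` object (or gene-body `GRanges`).
#' @param pk Peak `GRanges`.
#' @param sizes A `Seqinfo`.
#' @param flank Extension in bases (default 2000).
#' @return Character vector of qualifying gene ids.
#' @export
genes_with_peaks <- function(genes, pk, sizes, flank = 2000) {
  ext <- extend_genes(genes, sizes, flank = flank)
  hit <- countOverlaps(ext, pk, ignore.strand = TRUE) > 0
  gene_ids(genes)[hit]
}

#' Gene-level 5-hmC tag counting and density
#'
#' For genes with at least one peak overlapping their (unextended) body,
#' sums the aligned sequencing tags over the body and divides by gene
#' length to give tags-per-base density. A tag counts toward a gene if it
#' overlaps the body by at least one base; tags overlapping more than one
#' counted gene are ambiguous and discarded (union-mode counting). Genes
#' without a peak are omitted entirely.
#'
#' @param tags `GRanges` of aligned tag intervals.
#' @param genes A `GeneModels` object (or gene-body `GRanges`).
#' @param pk Peak `GRanges` used as the inclusion filter.
#' @return A `data.frame` with columns `gene_id`, `tag_count`,
#'   `gene_length`, `density` (and no `bin` column until
#'   [bin_by_percentile()] is applied).
#' @export
count_tags_per_gene <- function(tags, genes, pk) {
  bodies <- get_bodies(genes)
  ids <- gene_ids(genes)
  keep <- countOverlaps(bodies, pk, ignore.strand = TRUE) > 0
  bodies <- bodies[keep]
  ids <- ids[keep]
  n <- length(bodies)
  counts <- integer(n)
  if (n > 0 && length(tags) > 0) {
    hits <- findOverlaps(tags, bodies, ignore.strand = TRUE)
    ngenes_per_tag <- countOverlaps(tags, bodies, ignore.strand = TRUE)
    unambig <- hits[ngenes_per_tag[queryHits(hits)] == 1L]
    tab <- tabulate(subjectHits(unambig), nbins = n)
    counts <- tab
  }
  data.frame(gene_id = ids,
             tag_count = counts,
             gene_length = width(bodies),
             density = counts / width(bodies),
             stringsAsFactors = FALSE)
}

#' Percentile binning of gene 5-hmC densities
#'
#' Genes are ranked by density and cut at the given percentiles (default
#' 25/75/98, giving the four bins 0-25, 25-75, 75-98 and 98-100). A gene
#' with rank r out of n falls in the first bin whose upper percentile
#' bound is >= 100 * r / n. Ties in density are broken by gene id, so the
#' assignment is deterministic.
#'
#' @param records Output of [count_tags_per_gene()] (needs `gene_id` and
#'   `density` columns); at least 4 rows.
#' @param cuts Increasing percentile cut points strictly between 0 and 100.
#' @return `records` with an added ordered factor column `bin` with levels
#'   `P0_25`, `P25_75`, `P75_98`, `P98_100` (for the default cuts).
#' @export
bin_by_percentile <- function(records, cuts = c(25, 75, 98)) {
  if (nrow(records) < 4) stop("need at least 4 records to bin")
  if (is.unsorted(cuts, strictly = TRUE) || any(cuts <= 0) || any(cuts >= 100))
    stop("cuts must be strictly increasing and inside (0, 100)")
  n <- nrow(records)
  ord <- order(records$density, records$gene_id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  pct <- 100 * rank / n
  edges <- c(cuts, 100)
  lab <- paste0("P", c(0, cuts), "_", edges)
  idx <- vapply(pct, function(p) which(edges >= p)[1], integer(1))
  records$bin <- factor(lab[idx], levels = lab, ordered = TRUE)
  records
}

#' Metagene coverage profile around features
#'
#' Average per-base tag coverage over a set of features, with feature
#' bodies rescaled to a common axis of `body_bins` bins and flanks of
#' `flank` bases split into `flank_bins` fixed-width bins on each side.
#' Minus-strand features are reversed so bin 1 is always the 5' flank.
#' Coverage is normalized to tags per million tags per base, so the
#' profile is invariant to sequencing depth.
#'
#' @param tags `GRanges` of aligned tag intervals.
#' @param features Stranded `GRanges` of features (gene bodies, binding
#'   sites, ...).
#' @param body_bins Number of bins the feature body is rescaled to.
#' @param flank Flank width in bases on each side.
#' @param flank_bins Number of fixed-width bins per flank.
#' @return A `data.frame` with columns `bin` (index), `region` (one of
#'   `"upstream"`, `"body"`, `"downstream"`) and `signal` (tags per
#'   million per bp, averaged over features).
#' @export
metagene_profile <- function(tags, features, body_bins = 100, flank = 2000,
                             flank_bins = 20) {
  if (length(features) == 0) stop("no features supplied")
  total_tags <- length(tags)
  cov <- coverage(tags)
  nb <- flank_bins + body_bins + flank_bins
  acc <- matrix(NA_real_, nrow = length(features), ncol = nb)
  fw <- if (flank_bins > 0) flank / flank_bins else 0
  for (i in seq_along(features)) {
    f <- features[i]
    chr <- as.character(seqnames(f))
    covc <- if (chr %in% names(cov)) cov[[chr]] else S4Vectors::Rle(0L, end(f) + flank)
    lo <- start(f) - flank
    hi <- end(f) + flank
    v <- numeric(hi - lo + 1)
    a <- max(lo, 1L); b <- min(hi, length(covc))
    if (b >= a)
      v[(a - lo + 1):(b - lo + 1)] <- as.numeric(S4Vectors::window(covc, a, b))
    up <- v[seq_len(flank)]
    body <- v[(flank + 1):(flank + width(f))]
    down <- v[(flank + width(f) + 1):length(v)]
    prof <- c(bin_means(up, flank_bins), bin_means(body, body_bins),
              bin_means(down, flank_bins))
    ## reverse the binned profile (not the base-level vector) on minus
    ## strand so strand-flipping a feature reverses its profile exactly
    if (as.logical(strand(f) == "-")) prof <- rev(prof)
    acc[i, ] <- prof
  }
  sig <- colMeans(acc, na.rm = TRUE)
  if (total_tags > 0) sig <- sig / (total_tags / 1e6)
  data.frame(
    bin = seq_len(nb),
    region = rep(c("upstream", "body", "downstream"),
                 c(flank_bins, body_bins, flank_bins)),
    signal = sig)
}

## Mean of v over nbins contiguous chunks (proportional boundaries).
## Chunks that receive no base (len(v) < nbins) are NA.
bin_means <- function(v, nbins) {
  if (nbins == 0) return(numeric(0))
  n <- length(v)
  if (n == 0) return(rep(NA_real_, nbins))
  idx <- floor((seq_len(n) - 1) * nbins / n) + 1L
  out <- rep(NA_real_, nbins)
  sums <- tapply(v, idx, sum)
  cnts <- tabulate(idx, nbins)
  got <- as.integer(names(sums))
  out[got] <- as.numeric(sums) / cnts[got]
  out
}
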