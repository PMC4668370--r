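#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqnames keepSeqlevels
#' @importFrom methods is
NULL

## Internal RNG scoping: run `expr` under `seed` without disturbing the
## caller's RNG stream. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a vector of independent sub-seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Construct a chromosome-size table
#'
#' Chromosome sizes anchor all coordinate clamping and genome-wide peak
#' shuffling. They are represented as a [GenomeInfoDb::Seqinfo] so that
#' bounds travel with every `GRanges` built against them.
#'
#' @param lengths Named numeric/integer vector of chromosome lengths in
#'   bases; names are chromosome names and must be unique, lengths positive.
#' @return A `Seqinfo` object.
#' @examples
#' chrom_sizes(c(chr1 = 1e6, chr2 = 5e5))
#' @export
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome names must be present and unique")
  if (any(lengths <= 0) || any(!is.finite(lengths)))
    stop("all chromosome lengths must be positive finite numbers")
  Seqinfo(seqnames = names(lengths), seqlengths = as.integer(lengths))
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab- or space-separated file with columns
#'   `chrom`, `length`.
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(tab$length, tab$chrom))
}

#' Build a peak set
#'
#' A peak is a genomic interval annotated with the number of sequencing tags
#' the peak caller assigned to it. Tag density (tags per base) is derived on
#' construction and used by the tag-weighted enrichment statistic.
#'
#' @param chrom,start,end Interval coordinates, 0-based half-open (BED
#'   convention, as emitted by peak callers); converted internally to the
#'   1-based closed `GRanges` convention.
#' @param tags Non-negative tag counts, one per peak.
#' @param sizes Optional `Seqinfo`; when given, peaks are checked against
#'   chromosome bounds.
#' @return A `GRanges` with metadata columns `tags` and `density`.
#' @examples
#' sz <- chrom_sizes(c(chr1 = 1e5))
#' peaks(c("chr1", "chr1"), c(100, 5000), c(600, 5400), tags = c(50, 12), sizes = sz)
#' @export
peaks <- function(chrom, start, end, tags, sizes = NULL) {
  if (any(tags < 0)) stop("tag counts must be non-negative")
  if (any(end <= start)) stop("intervals must satisfy start < end")
  gr <- GRanges(chrom, IRanges(start = start + 1L, end = end))
  if (!is.null(sizes)) {
    check_bounds(gr, sizes)
    gr <- gr_on_sizes(gr, sizes)
  }
  mcols(gr)$tags <- as.numeric(tags)
  mcols(gr)$density <- as.numeric(tags) / width(gr)
  gr
}

## Attach a Seqinfo to a GRanges (expanding seqlevels as needed).
gr_on_sizes <- function(gr, sizes) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(sizes)
  GenomeInfoDb::seqinfo(gr) <- sizes
  gr
}

check_bounds <- function(gr, sizes) {
  unknown <- setdiff(unique(as.character(seqnames(gr))), seqlevels(sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  len <- seqlengths(sizes)[as.character(seqnames(gr))]
  if (any(end(gr) > len) || any(start(gr) < 1))
    stop("interval(s) out of chromosome bounds")
  invisible(gr)
}

#' Length of the intersection between two intervals
#'
#' Pairwise intersection length in bases; zero when the chromosomes differ
#' or the intervals are disjoint. Vectorized over pairs (the shorter
#' argument is recycled).
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return Integer vector of intersection lengths in bases.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(161, 300))
#' intersect_length(a, b)  # 40
#' @export
intersect_length <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  pmax(ov, 0L)
}

#' Merge intervals into a disjoint sorted set
#'
#' Thin wrapper over [GenomicRanges::reduce()]: the result is sorted,
#' pairwise disjoint, strand-agnostic, and covers exactly the union of the
#' input bases. Used so that annotation bases are never double-counted.
#'
#' @param gr A `GRanges`.
#' @return A merged `GRanges` (metadata columns dropped).
#' @export
merge_intervals <- function(gr) {
  reduce(sort(gr), ignore.strand = TRUE)
}

#' Extend an interval on both sides, clamped to chromosome bounds
#'
#' The genomic analog of `bedtools slop`: grow each interval by `left`
#' bases upstream (lower coordinates) and `right` bases downstream, never
#' past position 0 or the chromosome end.
#'
#' @param gr A `GRanges`.
#' @param left,right Non-negative extensions in bases.
#' @param sizes A `Seqinfo` supplying chromosome lengths.
#' @return The extended `GRanges`.
#' @export
slop <- function(gr, left, right, sizes) {
  if (left < 0 || right < 0) stop("extensions must be non-negative")
  unknown <- setdiff(unique(as.character(seqnames(gr))), seqlevels(sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  gr <- gr_on_sizes(gr, sizes)
  start(gr) <- pmax(1L, start(gr) - as.integer(left))
  end(gr) <- pmin(seqlengths(sizes)[as.character(seqnames(gr))],
                  end(gr) + as.integer(right))
  gr
}

#' Shuffle peaks uniformly across the genome
#'
#' Implements the genome-wide scrambling that defines the permutation null
#' of the enrichment test. Each peak keeps its length and tag count; it is
#' placed on a chromosome drawn with probability proportional to chromosome
#' length among chromosomes long enough to contain it, with a uniform start
#' such that the peak fits entirely. Placed peaks may overlap each other;
#' each stays on a single chromosome.
#'
#' @param pk Peak `GRanges` (as from [peaks()]).
#' @param sizes A `Seqinfo`.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A `GRanges` with the same metadata columns, repositioned.
#' @export
shuffle_peaks <- function(pk, sizes, seed = NULL) {
  slen <- seqlengths(sizes)
  w <- width(pk)
  with_seed(seed, {
    pos <- shuffle_positions(w, slen)
    out <- GRanges(names(slen)[pos$chrom], IRanges(start = pos$start, width = w))
    out <- gr_on_sizes(out, sizes)
    mcols(out) <- mcols(pk)
    out
  })
}

## Uniform genome placement shared by shuffle_peaks() and the fast null
## loop in expected_tags(): chromosome ~ length among chromosomes that can
## hold the peak, start uniform over valid positions. Consumes the current
## RNG stream; returns 1-based chromosome indices and starts.
shuffle_positions <- function(w, slen) {
  n <- length(w)
  if (n == 0) return(list(chrom = integer(0), start = integer(0)))
  if (any(w > max(slen)))
    stop("peak longer than every chromosome; cannot place")
  ci <- integer(n)
  st <- numeric(n)
  if (all(w <= min(slen))) {
    prob <- as.numeric(slen) / sum(as.numeric(slen))
    ci <- sample.int(length(slen), n, replace = TRUE, prob = prob)
    st <- 1 + floor(stats::runif(n) * (slen[ci] - w + 1))
  } else {
    key <- vapply(w, function(wi) paste(which(slen >= wi), collapse = ","), "")
    for (k in unique(key)) {
      idx <- which(key == k)
      ok <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
      prob <- as.numeric(slen[ok]) / sum(as.numeric(slen[ok]))
      ch <- ok[sample.int(length(ok), length(idx), replace = TRUE, prob = prob)]
      ci[idx] <- ch
      st[idx] <- 1 + floor(stats::runif(length(idx)) * (slen[ch] - w[idx] + 1))
    }
  }
  list(chrom = ci, start = as.integer(st))
}

#' Number of bases covered by a set of intervals
#'
#' The size of the union of the intervals, in bases (each base counted
#' once regardless of how many peaks cover it).
#'
#' @param gr A `GRanges`.
#' @return A single numeric base count.
#' @export
coverage_bases <- function(gr) {
  if (length(gr) == 0) return(0)
  sum(as.numeric(width(reduce(gr, ignore.strand = TRUE))))
}
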