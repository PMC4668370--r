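#' Replicate-consensus peak coverage
#'
#' The consensus of a sample group is the set of bases with a called peak
#' in every member replicate: the base-level intersection across
#' replicates, merged. With a single replicate the consensus is its merged
#' coverage. For more than two replicates a relaxed >= k-of-n mode is
#' available; the strict all-replicates intersection is the default.
#'
#' @param replicates A list of peak `GRanges` (or plain interval
#'   `GRanges`), one per replicate.
#' @param min_replicates Minimum number of replicates a base must be
#'   covered in (default: all of them).
#' @param name Label for the consensus set.
#' @return A merged `GRanges` with `metadata(x)$name` set.
#' @export
consensus <- function(replicates, min_replicates = length(replicates),
                      name = "consensus") {
  if (length(replicates) == 0) stop("no replicates supplied")
  if (min_replicates < 1 || min_replicates > length(replicates))
    stop("min_replicates must be between 1 and the number of replicates")
  covs <- lapply(replicates, function(r) reduce(granges(r), ignore.strand = TRUE))
  if (min_replicates == length(replicates)) {
    out <- Reduce(function(a, b) GenomicRanges::intersect(a, b, ignore.strand = TRUE),
                  covs)
  } else {
    ## each replicate's coverage is already reduced, so the coverage of the
    ## concatenation counts how many replicates cover each base
    combined <- suppressWarnings(do.call(c, covs))
    hit <- methods::as(coverage(combined) >= min_replicates, "GRanges")
    out <- hit[mcols(hit)$score]
    mcols(out) <- NULL
  }
  annotation_set(out, name)
}

#' Base-level overlap between two consensus peak sets
#'
#' Overlap measured in number of bases covered in both sets, with the
#' fraction of each set's covered bases that the overlap represents.
#'
#' @param a,b Merged `GRanges` (e.g. from [consensus()]).
#' @return A list with `overlap_bases`, `fraction_a`, `fraction_b`
#'   (fractions are `NA` with a warning when the respective set is empty).
#' @export
base_overlap <- function(a, b) {
  ov <- coverage_bases(GenomicRanges::intersect(reduce(granges(a), ignore.strand = TRUE),
                                                reduce(granges(b), ignore.strand = TRUE),
                                                ignore.strand = TRUE))
  ca <- coverage_bases(a); cb <- coverage_bases(b)
  if (ca == 0 || cb == 0)
    warning("empty consensus set; containment fraction undefined")
  list(overlap_bases = ov,
       fraction_a = if (ca > 0) ov / ca else NA_real_,
       fraction_b = if (cb > 0) ov / cb else NA_real_)
}

#' Gene-level overlap between two consensus peak sets
#'
#' A gene is hydroxymethylated in a set when the consensus coverage
#' intersects its (unextended) gene body by at least one base. Returns the
#' three-way partition of genes hit in only one set, the other, or both.
#'
#' @param genes A `GeneModels` object (or gene-body `GRanges`).
#' @param a,b Merged consensus `GRanges`.
#' @return A list with counts `only_a`, `only_b`, `both` and the
#'   corresponding gene-id character vectors `genes_only_a`,
#'   `genes_only_b`, `genes_both`.
#' @export
gene_overlap <- function(genes, a, b) {
  bodies <- get_bodies(genes)
  ids <- gene_ids(genes)
  in_a <- countOverlaps(bodies, a, ignore.strand = TRUE) > 0
  in_b <- countOverlaps(bodies, b, ignore.strand = TRUE) > 0
  list(only_a = sum(in_a & !in_b),
       only_b = sum(!in_a & in_b),
       both = sum(in_a & in_b),
       genes_only_a = ids[in_a & !in_b],
       genes_only_b = ids[!in_a & in_b],
       genes_both = ids[in_a & in_b])
}
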