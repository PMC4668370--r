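#' Named, merged annotation set
#'
#' An annotation set is the strand-agnostic merged union of a feature
#' class's intervals (CpG islands, shores, promoters, gene bodies,
#' transcription-factor binding sites, ...). Merging on construction
#' guarantees each genomic base belongs to the annotation at most once,
#' which the tag-weighted enrichment statistic relies on.
#'
#' @param gr A `GRanges` of raw feature intervals.
#' @param name Label for the annotation (stored in `metadata`).
#' @return A merged, sorted `GRanges` with `metadata(x)$name` set.
#' @export
annotation_set <- function(gr, name = "annotation") {
  out <- merge_intervals(gr)
  S4Vectors::metadata(out)$name <- name
  out
}

annotation_name <- function(x) {
  nm <- S4Vectors::metadata(x)$name
  if (is.null(nm)) "annotation" else nm
}

#' Load a BED file as an annotation set
#'
#' @param path Path to a BED file of feature intervals.
#' @param name Annotation label.
#' @param sizes Optional `Seqinfo`.
#' @return A merged annotation `GRanges`.
#' @export
load_bed_annotation <- function(path, name = basename(path), sizes = NULL) {
  annotation_set(read_bed(path, sizes = sizes), name = name)
}

#' Build promoter annotations around transcription start sites
#'
#' Promoters are defined as the window from `up` bases upstream of each
#' TSS to `down` bases downstream (default 500 bp upstream to 2 kb
#' downstream), strand-aware, clamped to chromosome bounds, one window per
#' distinct transcript TSS, merged. A strand-ignorant mode treats every
#' TSS as if on the plus strand.
#'
#' @param genes A `GeneModels` object (or gene-body `GRanges`).
#' @param sizes A `Seqinfo`.
#' @param down Bases downstream of the TSS (in transcription direction).
#' @param up Bases upstream of the TSS.
#' @param stranded If `FALSE`, ignore strand when orienting the window.
#' @return A merged annotation `GRanges` named `"promoters"`.
#' @export
build_promoters <- function(genes, sizes, down = 2000, up = 500,
                            stranded = TRUE) {
  if (down < 0 || up < 0) stop("window extents must be non-negative")
  tss <- get_tss(genes)
  if (length(tss) == 0) return(annotation_set(gr_on_sizes(GRanges(), sizes), "promoters"))
  if (!stranded) strand(tss) <- "+"
  minus <- as.logical(strand(tss) == "-")
  s1 <- ifelse(minus, start(tss) - down, start(tss) - up)
  e1 <- ifelse(minus, start(tss) + up - 1L, start(tss) + down - 1L)
  win <- GRanges(seqnames(tss), IRanges(pmax(1, s1), pmax(1, e1)))
  win <- gr_on_sizes(win, sizes)
  win <- trim(win)
  annotation_set(win, "promoters")
}

#' Build CpG shore annotations
#'
#' Shores are the `width`-base flanks adjacent to each CpG island, clamped
#' to chromosome bounds, with all island bases subtracted so no base is
#' simultaneously island and shore, then merged across neighboring islands.
#'
#' @param islands Annotation `GRanges` of CpG islands.
#' @param sizes A `Seqinfo`.
#' @param width Shore width in bases (default 2000).
#' @return A merged annotation `GRanges` named `"CpG shores"`.
#' @export
build_shores <- function(islands, sizes, width = 2000) {
  if (width <= 0) stop("shore width must be positive")
  isl <- merge_intervals(islands)
  if (length(isl) == 0) return(annotation_set(gr_on_sizes(GRanges(), sizes), "CpG shores"))
  isl <- gr_on_sizes(isl, sizes)
  flanked <- slop(isl, left = width, right = width, sizes)
  shores <- setdiff(flanked, isl, ignore.strand = TRUE)
  annotation_set(shores, "CpG shores")
}

#' Extend gene bodies by a fixed flank
#'
#' Each gene body grown by `flank` bases on both sides, clamped to
#' chromosome bounds. Genes are retained individually (per-gene variant)
#' so gene-list intersections remain possible; use [annotation_set()] on
#' the result for the merged variant.
#'
#' @param genes A `GeneModels` object (or gene-body `GRanges`).
#' @param sizes A `Seqinfo`.
#' @param flank Extension in bases (default 2000).
#' @return A `GRanges` with one (extended) interval per gene, `gene_id`
#'   metadata preserved.
#' @export
extend_genes <- function(genes, sizes, flank = 2000) {
  if (flank < 0) stop("flank must be non-negative")
  b <- get_bodies(genes)
  slop(b, left = flank, right = flank, sizes)
}
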