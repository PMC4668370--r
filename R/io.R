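#' Read a MACS-style peak table
#'
#' Peak callers in the MACS family emit BED-like tables whose fourth column
#' carries the number of sequencing tags assigned to each peak. This reader
#' accepts that layout (tab-separated `chrom start end tags`, 0-based
#' half-open coordinates, optional further columns ignored) and returns a
#' peak `GRanges` with derived per-base tag density.
#'
#' @param path Path to the peak table.
#' @param tags_col Column index holding the tag count (default 4).
#' @param sizes Optional `Seqinfo` for bounds checking.
#' @return A peak `GRanges` (see [peaks()]).
#' @export
read_peaks <- function(path, tags_col = 4, sizes = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < tags_col)
    stop("peak table has ", ncol(tab), " columns; tags_col = ", tags_col)
  peaks(tab[[1]], tab[[2]], tab[[3]], tags = tab[[tags_col]], sizes = sizes)
}

#' Write a peak set as a MACS-style table
#'
#' @param pk Peak `GRanges`.
#' @param path Output path; written as `chrom start end tags` (0-based
#'   half-open), tab-separated, no header.
#' @export
write_peaks <- function(pk, path) {
  utils::write.table(
    data.frame(chrom = as.character(seqnames(pk)), start = start(pk) - 1L,
               end = end(pk), tags = mcols(pk)$tags),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BED file of plain intervals
#'
#' Thin wrapper over [rtracklayer::import.bed()]; BED's 0-based half-open
#' coordinates are converted to the 1-based closed `GRanges` convention.
#'
#' @param path Path to a BED3/BED6 file.
#' @param sizes Optional `Seqinfo` attached to the result.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr) <- NULL
  if (!is.null(sizes)) {
    check_bounds(gr, sizes)
    gr <- gr_on_sizes(gr, sizes)
  }
  gr
}

#' Write intervals as BED
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
}

#' Gene models from a GTF file
#'
#' Reads gene annotation in GTF (Ensembl dialect, 1-based closed
#' coordinates) through [rtracklayer::import()] and collapses it to one
#' model per `gene_id`: the gene body is the union span of the gene's
#' transcripts on its strand, and every distinct transcript start site is
#' retained for promoter construction.
#'
#' @param path Path to a GTF file.
#' @param sizes Optional `Seqinfo` attached to the result.
#' @return An object of class `GeneModels`: a list with
#'   \describe{
#'     \item{genes}{`GRanges` of gene bodies, named by `gene_id`, stranded.}
#'     \item{tss}{width-1 `GRanges` of distinct transcript start sites with
#'       a `gene_id` metadata column.}
#'   }
#' @export
read_gene_models <- function(path, sizes = NULL) {
  gr <- rtracklayer::import(path, format = "GTF")
  keep <- mcols(gr)$type %in% c("transcript", "gene", "exon")
  gr <- gr[keep]
  if (length(gr) == 0) return(gene_models_empty(sizes))
  ## prefer transcript records for TSS resolution; genes alone also work
  tx <- gr[mcols(gr)$type == "transcript"]
  if (length(tx) == 0) tx <- gr[mcols(gr)$type == "gene"]
  if (length(tx) == 0) tx <- gr
  gene_models_from_tx(tx, sizes)
}

gene_models_empty <- function(sizes = NULL) {
  g <- GRanges()
  if (!is.null(sizes)) g <- gr_on_sizes(g, sizes)
  structure(list(genes = g, tss = g), class = "GeneModels")
}

gene_models_from_tx <- function(tx, sizes = NULL) {
  ids <- as.character(mcols(tx)$gene_id)
  if (anyNA(ids)) stop("GTF records without gene_id")
  spl <- split(tx, ids)
  bodies <- unlist(range(spl, ignore.strand = FALSE))
  names(bodies) <- names(spl)
  mcols(bodies)$gene_id <- names(spl)
  tss <- resize(tx, width = 1L, fix = "start")
  mcols(tss) <- DataFrame(gene_id = ids)
  tss <- unique(tss)
  if (!is.null(sizes)) {
    bodies <- gr_on_sizes(bodies, sizes)
    tss <- gr_on_sizes(tss, sizes)
  }
  structure(list(genes = sort(bodies), tss = sort(tss)), class = "GeneModels")
}

#' Construct gene models directly from coordinates
#'
#' Programmatic counterpart of [read_gene_models()], used by the simulator
#' and in tests. One transcript per gene; the TSS is the 5' end of the body.
#'
#' @param chrom,start,end 0-based half-open body coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @param gene_id Unique identifiers.
#' @param sizes Optional `Seqinfo`.
#' @return A `GeneModels` object.
#' @export
gene_models <- function(chrom, start, end, strand, gene_id, sizes = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  g <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  names(g) <- gene_id
  mcols(g)$gene_id <- gene_id
  if (!is.null(sizes)) g <- gr_on_sizes(g, sizes)
  tss <- resize(g, width = 1L, fix = "start")
  mcols(tss) <- DataFrame(gene_id = gene_id)
  structure(list(genes = sort(g), tss = sort(tss)), class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", length(x$genes), "genes,", length(x$tss), "TSS sites\n")
  invisible(x)
}

#' Write gene models as GTF
#'
#' Emits one `gene` and one `transcript` record per gene so the file
#' round-trips through [read_gene_models()].
#'
#' @param gm A `GeneModels` object.
#' @param path Output path.
#' @export
write_gene_models_gtf <- function(gm, path) {
  g <- gm$genes
  rec <- rep(g, each = 2)
  mcols(rec) <- DataFrame(
    source = "hmcdiff",
    type = rep(c("gene", "transcript"), length(g)),
    gene_id = rep(mcols(g)$gene_id, each = 2),
    transcript_id = ifelse(rep(c(FALSE, TRUE), length(g)),
                           paste0(rep(mcols(g)$gene_id, each = 2), ".t1"), NA))
  names(rec) <- NULL
  rtracklayer::export(rec, path, format = "GTF")
}

## Accept either a GeneModels list or a bare GRanges of gene bodies.
get_bodies <- function(x) {
  if (inherits(x, "GeneModels")) x$genes
  else if (is(x, "GRanges")) x
  else stop("expected GeneModels or GRanges")
}

get_tss <- function(x) {
  if (inherits(x, "GeneModels")) x$tss
  else if (is(x, "GRanges")) {
    t <- resize(x, width = 1L, fix = "start")
    if (is.null(mcols(t)$gene_id))
      mcols(t)$gene_id <- if (!is.null(names(x))) names(x)
        else as.character(seq_along(x))
    t
  } else stop("expected GeneModels or GRanges")
}

gene_ids <- function(x) {
  b <- get_bodies(x)
  ids <- mcols(b)$gene_id
  if (is.null(ids)) ids <- names(b)
  if (is.null(ids)) ids <- as.character(seq_along(b))
  as.character(ids)
}
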