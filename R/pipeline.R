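#' Run the 5-hmC analysis pipeline end to end
#'
#' Orchestrates the stages (simulate or load inputs, build annotations,
#' permutation enrichment, gene-level quantification, expression
#' integration, replicate overlap, tumor/normal differential calls,
#' TAB-seq quantification) in dependency order, communicating exclusively
#' through files in standard formats so any stage can be rerun
#' standalone. Every output table starts with comment lines echoing the
#' package version, seed and stage parameters. Referenced input files are
#' validated before any computation starts; a failing stage stops its
#' dependents.
#'
#' @param config A named list (or path to a YAML file with the same
#'   structure) with elements:
#'   \describe{
#'     \item{seed}{Master seed (default 1).}
#'     \item{stages}{Character vector among `"simulate"`, `"annotate"`,
#'       `"enrich"`, `"gene_quant"`, `"integrate"`, `"cancer"`,
#'       `"tabseq"`; defaults to all. The `"cancer"` stage runs the
#'       planted tumor/normal cohort demonstration (generator plus
#'       consensus calls and concordance); for real cohorts call
#'       [consensus()], [call_hmc_change()] and [concordance_counts()]
#'       directly.}
#'     \item{inputs}{When not simulating: named paths `chrom_sizes`,
#'       `peaks`, `tags`, `genes_gtf`, `islands_bed`, and optionally
#'       `expression`, `tabseq`.}
#'     \item{params}{Stage parameters: `n_shuffles` (default 200),
#'       `flank`, `q_max`, `min_abs_log2fc`, `alpha`, plus any
#'       [sim_config()] overrides under `sim`.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data frame of stage/file
#'   rows) and in-memory `results` per stage.
#' @export
run_pipeline <- function(config = list(), out_dir = "hmcdiff_out") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  stages <- config$stages %||%
    c("simulate", "annotate", "enrich", "gene_quant", "integrate",
      "cancer", "tabseq")
  params <- config$params %||% list()
  n_shuffles <- params$n_shuffles %||% 200L
  flank <- params$flank %||% 2000L

  ## pre-flight: all referenced inputs must exist before anything runs
  if (!"simulate" %in% stages) {
    need <- c("chrom_sizes", "peaks", "tags", "genes_gtf", "islands_bed")
    paths <- unlist(config$inputs[c(need,
                                    intersect(c("expression", "tabseq"),
                                              names(config$inputs)))])
    missing_keys <- setdiff(need, names(config$inputs))
    if (length(missing_keys))
      stop("config$inputs lacks: ", paste(missing_keys, collapse = ", "))
    gone <- paths[!file.exists(paths)]
    if (length(gone))
      stop("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- data.frame(stage = character(), file = character())
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file))
  }
  hdr <- function(stage, extra = "") {
    paste0("# hmcdiff ", as.character(utils::packageVersion("hmcdiff")),
           " | stage=", stage, " | seed=", seed,
           if (nzchar(extra)) paste0(" | ", extra) else "")
  }
  write_tsv_with_header <- function(df, path, stage, extra = "") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr(stage, extra), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results <- list()

  if ("simulate" %in% stages) {
    sim_over <- params$sim %||% list()
    cfg <- do.call(sim_config, utils::modifyList(list(seed = seed), sim_over))
    gen <- simulate_genome(cfg)
    sim_dir <- file.path(out_dir, "sim")
    dir.create(sim_dir, showWarnings = FALSE)
    pt <- simulate_peaks_and_tags(cfg, gen$islands, gen$sizes)
    sizes_path <- file.path(sim_dir, "genome.sizes")
    utils::write.table(
      data.frame(names(seqlengths(gen$sizes)), seqlengths(gen$sizes)),
      sizes_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    write_gene_models_gtf(gen$genes, file.path(sim_dir, "genes.gtf"))
    write_bed(gen$islands, file.path(sim_dir, "islands.bed"))
    write_peaks(pt$peaks, file.path(sim_dir, "peaks.bed"))
    write_bed(pt$tags, file.path(sim_dir, "tags.bed"))
    for (f in c("genome.sizes", "genes.gtf", "islands.bed", "peaks.bed",
                "tags.bed"))
      emit("simulate", file.path(sim_dir, f))
    config$inputs <- list(chrom_sizes = sizes_path,
                          peaks = file.path(sim_dir, "peaks.bed"),
                          tags = file.path(sim_dir, "tags.bed"),
                          genes_gtf = file.path(sim_dir, "genes.gtf"),
                          islands_bed = file.path(sim_dir, "islands.bed"))
    results$simulate <- list(config = cfg,
                             realized_fraction = pt$realized_fraction)
  }

  sizes <- read_chrom_sizes(config$inputs$chrom_sizes)
  pk <- read_peaks(config$inputs$peaks, sizes = sizes)
  tags <- read_bed(config$inputs$tags, sizes = sizes)
  genes <- read_gene_models(config$inputs$genes_gtf, sizes = sizes)
  islands <- load_bed_annotation(config$inputs$islands_bed, "CpG islands",
                                 sizes = sizes)

  annots <- NULL
  if ("annotate" %in% stages) {
    annots <- list(
      `CpG islands` = islands,
      `CpG shores` = build_shores(islands, sizes),
      promoters = build_promoters(genes, sizes),
      `gene bodies` = annotation_set(get_bodies(genes), "gene bodies"))
    for (nm in names(annots)) {
      f <- file.path(out_dir, paste0(gsub(" ", "_", nm), ".bed"))
      write_bed(annots[[nm]], f)
      emit("annotate", f)
    }
    results$annotate <- annots
  }

  if ("enrich" %in% stages) {
    if (is.null(annots)) stop("stage 'enrich' requires stage 'annotate'")
    er <- lapply(names(annots), function(nm) {
      a <- annots[[nm]]
      S4Vectors::metadata(a)$name <- nm
      enrichment_test(pk, a, sizes, n_shuffles = n_shuffles, seed = seed)
    })
    tab <- enrichment_table(er)
    f <- file.path(out_dir, "enrichment.tsv")
    write_tsv_with_header(tab, f, "enrich",
                          paste0("n_shuffles=", n_shuffles))
    emit("enrich", f)
    results$enrich <- tab
  }

  records <- NULL
  if ("gene_quant" %in% stages) {
    records <- count_tags_per_gene(tags, genes, pk)
    if (nrow(records) >= 4) records <- bin_by_percentile(records)
    f <- file.path(out_dir, "gene_hmc.tsv")
    write_tsv_with_header(records, f, "gene_quant")
    emit("gene_quant", f)
    results$gene_quant <- records
  }

  if ("integrate" %in% stages) {
    if (is.null(records) || is.null(records$bin))
      stop("stage 'integrate' requires binned gene_quant records")
    expr <- if (!is.null(config$inputs$expression)) {
      read_expression_table(config$inputs$expression)
    } else {
      simulate_expression(records,
                          do.call(sim_config,
                                  utils::modifyList(list(seed = seed),
                                                    params$sim %||% list())))
    }
    expr <- classify_expression(expr, q_max = params$q_max %||% 0.05,
                                min_abs_log2fc = params$min_abs_log2fc %||% 1)
    by_bin <- expression_by_hmc_bin(records, expr)
    assoc <- bin_class_association(records, expr)
    mfc <- median_fold_change_by_bin(records, expr)
    f1 <- file.path(out_dir, "expression_by_bin.tsv")
    write_tsv_with_header(by_bin, f1, "integrate")
    f2 <- file.path(out_dir, "median_log2fc_by_bin.tsv")
    write_tsv_with_header(mfc, f2, "integrate")
    emit("integrate", f1); emit("integrate", f2)
    results$integrate <- list(by_bin = by_bin, association = assoc,
                              median_fc = mfc)
  }

  if ("cancer" %in% stages) {
    co <- simulate_cancer_cohort(seed = seed)
    ncons <- consensus(co$normal_peaks, name = "normal consensus")
    tcons <- consensus(co$tumor_peaks, name = "tumor consensus")
    calls <- call_hmc_change(co$genes, ncons, tcons)
    conc <- concordance_counts(calls, co$expr, co$groups)
    ov <- base_overlap(ncons, tcons)
    f <- file.path(out_dir, "cancer_concordance.tsv")
    write_tsv_with_header(conc$detail, f, "cancer")
    emit("cancer", f)
    results$cancer <- list(calls = calls, concordance = conc,
                           base_overlap = ov)
  }

  if ("tabseq" %in% stages) {
    ts <- if (!is.null(config$inputs$tabseq)) {
      read_tabseq(config$inputs$tabseq)
    } else {
      simulate_tabseq(sim_config(seed = seed))
    }
    est <- site_modification(ts)
    conds <- unique(est$condition)
    cmp <- if (length(conds) >= 2)
      compare_conditions(est, conds[1], conds[2]) else NULL
    f <- file.path(out_dir, "tabseq_estimates.tsv")
    write_tsv_with_header(est, f, "tabseq")
    emit("tabseq", f)
    results$tabseq <- list(estimates = est, comparison = cmp)
  }

  f <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
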