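#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators with defaults
#' sized for a desk-scale genome: a handful of megabase chromosomes,
#' log-normally sized genes and CpG islands, peaks with negative-binomial
#' (over-dispersed) tag counts, a configurable fraction of tag mass
#' planted inside a target annotation, a monotone density-to-expression
#' link, planted gain/loss gene sets and binomial TAB-seq clone counts.
#'
#' @param seed Master seed.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_genes Number of genes.
#' @param gene_meanlog,gene_sdlog Log-normal gene-length parameters (bases).
#' @param n_islands Number of CpG islands.
#' @param island_meanlog,island_sdlog Log-normal island-width parameters.
#' @param n_peaks Number of peaks.
#' @param peak_meanlog,peak_sdlog Log-normal peak-length parameters.
#' @param tag_mu,tag_size Negative-binomial mean and dispersion of
#'   per-peak tag counts.
#' @param tag_length Length of an aligned tag interval (bases).
#' @param annotation_fraction_q Target fraction of total tag mass inside
#'   the designated annotation.
#' @param link_slope,link_noise_sd Monotone density-to-FPKM link: slope on
#'   the standardized log-density and log-scale noise sd.
#' @param induction_link Strength of the density effect on the
#'   probability of a gene being up-regulated (0 = independent).
#' @param clones_per_site TAB-seq clones per CpG and treatment.
#' @param tabseq_truth Named list, one `c(pct_C, pct_5mC, pct_5hmC)`
#'   triple per condition (each summing to 100).
#' @return A list of class `hmc_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
                       n_genes = 300, gene_meanlog = log(8000), gene_sdlog = 0.5,
                       n_islands = 150, island_meanlog = log(1000), island_sdlog = 0.4,
                       n_peaks = 200, peak_meanlog = log(500), peak_sdlog = 0.3,
                       tag_mu = 50, tag_size = 5, tag_length = 50,
                       annotation_fraction_q = 0.5,
                       link_slope = 1, link_noise_sd = 0.5, induction_link = 1,
                       clones_per_site = 20,
                       tabseq_truth = list(day0 = c(60, 35, 5),
                                           day15 = c(15, 60, 25))) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$chrom_lengths > 0),
            cfg$annotation_fraction_q >= 0, cfg$annotation_fraction_q <= 1,
            cfg$tag_mu > 0, cfg$tag_size > 0)
  for (tt in cfg$tabseq_truth)
    if (abs(sum(tt) - 100) > 1e-8 || any(tt < 0))
      stop("each tabseq_truth triple must be non-negative and sum to 100")
  class(cfg) <- "hmc_sim_config"
  cfg
}

## Pack feature widths onto chromosomes without overlap: each feature goes
## to a chromosome drawn by remaining free capacity; per chromosome the
## inter-feature gaps are drawn uniformly (stick-breaking).
pack_features <- function(widths, sizes) {
  slen <- seqlengths(sizes)
  if (sum(as.numeric(widths)) > sum(as.numeric(slen)))
    stop("requested feature mass exceeds genome length; packing infeasible")
  free <- as.numeric(slen)
  names(free) <- names(slen)
  chrom <- character(length(widths))
  for (i in order(widths, decreasing = TRUE)) {
    ok <- free >= widths[i]
    if (!any(ok))
      stop("requested feature mass exceeds genome length; packing infeasible")
    ch <- if (sum(ok) == 1) names(free)[ok]
          else sample(names(free)[ok], 1, prob = free[ok])
    chrom[i] <- ch
    free[ch] <- free[ch] - widths[i]
  }
  starts <- integer(length(widths))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- sample(idx)  # random left-to-right order
    w <- widths[idx]
    slack <- slen[ch] - sum(w)
    gaps <- diff(c(0, sort(stats::runif(length(w), 0, 1)), 1)) * slack
    pos <- 1 + cumsum(gaps[seq_along(w)]) + c(0, cumsum(w[-length(w)]))
    starts[idx] <- as.integer(floor(pos))
  }
  GRanges(chrom, IRanges(start = starts, width = widths))
}

#' Simulate a genome: chromosome sizes, gene models and CpG islands
#'
#' Gene bodies and islands are placed without mutual overlap, uniformly
#' across chromosomes, with random strands for genes. Deterministic under
#' the config seed.
#'
#' @param config An [sim_config()] object.
#' @return A list with `sizes` (`Seqinfo`), `genes` (`GeneModels`) and
#'   `islands` (merged annotation `GRanges`).
#' @export
simulate_genome <- function(config = sim_config()) {
  sizes <- chrom_sizes(config$chrom_lengths)
  with_seed(config$seed, {
    gw <- pmax(200L, as.integer(stats::rlnorm(config$n_genes,
                                              config$gene_meanlog,
                                              config$gene_sdlog)))
    iw <- pmax(200L, as.integer(stats::rlnorm(config$n_islands,
                                              config$island_meanlog,
                                              config$island_sdlog)))
    all_feat <- pack_features(c(gw, iw), sizes)
    gidx <- seq_len(config$n_genes)
    gbod <- all_feat[gidx]
    isl <- if (config$n_genes > 0) all_feat[-gidx] else all_feat
    gm <- if (config$n_genes > 0) {
      gene_models(as.character(seqnames(gbod)), start(gbod) - 1L, end(gbod),
                  strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                  gene_id = sprintf("gene%04d", gidx), sizes = sizes)
    } else gene_models_empty(sizes)
    list(sizes = sizes, genes = gm,
         islands = annotation_set(gr_on_sizes(isl, sizes), "CpG islands"))
  })
}

## Place intervals of the given widths fully inside a merged region set;
## intervals are drawn by interval capacity (#valid starts).
place_within <- function(widths, regions) {
  if (length(regions) == 0) stop("cannot place features: empty region set")
  starts <- integer(length(widths))
  chrom <- character(length(widths))
  rl <- width(regions)
  for (i in seq_along(widths)) {
    cap <- pmax(0, rl - widths[i] + 1)
    if (sum(cap) == 0)
      stop("no region can contain a feature of width ", widths[i])
    j <- if (length(cap) == 1) 1 else sample(seq_along(cap), 1, prob = cap)
    starts[i] <- start(regions)[j] + sample.int(cap[j], 1) - 1L
    chrom[i] <- as.character(seqnames(regions))[j]
  }
  GRanges(chrom, IRanges(start = starts, width = widths))
}

#' Simulate peaks and tag alignments with planted annotation enrichment
#'
#' Draws peak lengths (log-normal) and per-peak tag counts (negative
#' binomial), and places each peak fully inside the target annotation
#' with probability `q` (the target tag-mass fraction) or fully inside
#' its complement otherwise, so the expected fraction of tag mass inside
#' the annotation is `q`. Per-peak tag alignments are placed uniformly
#' within their peak.
#'
#' @param config An [sim_config()] object (`annotation_fraction_q`, peak
#'   and tag parameters).
#' @param annotation Merged target annotation `GRanges`.
#' @param sizes A `Seqinfo`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `peaks` (peak `GRanges`), `tags` (tag `GRanges`)
#'   and `realized_fraction` (achieved tag-mass fraction inside the
#'   annotation).
#' @export
simulate_peaks_and_tags <- function(config, annotation, sizes,
                                    seed = config$seed) {
  q <- config$annotation_fraction_q
  ann <- merge_intervals(gr_on_sizes(annotation, sizes))
  compl <- gaps(ann)
  compl <- compl[strand(compl) == "*"]
  with_seed(seed, {
    n <- config$n_peaks
    w <- pmax(50L, as.integer(stats::rlnorm(n, config$peak_meanlog,
                                            config$peak_sdlog)))
    tags <- stats::rnbinom(n, mu = config$tag_mu, size = config$tag_size) + 1L
    inside <- stats::runif(n) < q
    pk <- GRanges()
    if (any(inside)) pk <- c(pk, place_within(w[inside], ann))
    if (any(!inside)) pk <- c(pk, place_within(w[!inside], compl))
    tags <- c(tags[inside], tags[!inside])
    pk <- gr_on_sizes(pk, sizes)
    mcols(pk)$tags <- as.numeric(tags)
    mcols(pk)$density <- as.numeric(tags) / width(pk)
    ## one aligned tag interval per sequencing tag, uniform within peak
    tot <- sum(tags)
    tchr <- rep(as.character(seqnames(pk)), tags)
    tw <- pmin(config$tag_length, rep(width(pk), tags))
    maxoff <- rep(width(pk), tags) - tw
    toff <- floor(stats::runif(tot) * (maxoff + 1))
    tg <- GRanges(tchr, IRanges(start = rep(start(pk), tags) + as.integer(toff),
                                width = tw))
    tg <- gr_on_sizes(tg, sizes)
    realized <- observed_tags(pk, ann) / sum(as.numeric(tags))
    list(peaks = pk, tags = sort(tg), realized_fraction = realized)
  })
}

#' Simulate a differential-expression table linked to 5-hmC density
#'
#' FPKM follows a log-linear link on the standardized log 5-hmC density
#' (`link_slope` = 0 gives independence); the probability that a gene is
#' up-regulated over the time course increases with density at strength
#' `induction_link`. Up/down genes receive large fold changes and small
#' q-values so they are recovered by [classify_expression()] defaults;
#' unchanged genes receive near-zero fold changes and large q-values.
#'
#' @param records `data.frame` with `gene_id` and `density` columns (e.g.
#'   from [count_tags_per_gene()]).
#' @param config An [sim_config()] object.
#' @param base_up,base_down Baseline up/down probabilities at average
#'   density.
#' @param seed Optional seed overriding `config$seed`.
#' @return A `data.frame` with columns `gene_id`, `fpkm_a`, `fpkm`
#'   (condition B, the differentiated state), `log2fc`, `q_value` and the
#'   planted `true_class`.
#' @export
simulate_expression <- function(records, config = sim_config(),
                                base_up = 0.15, base_down = 0.15,
                                seed = config$seed) {
  n <- nrow(records)
  d <- log(records$density + 1e-12)
  z <- if (stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else rep(0, n)
  with_seed(seed, {
    fpkm <- 10 * exp(config$link_slope * z +
                     stats::rnorm(n, 0, config$link_noise_sd))
    p_up <- stats::plogis(stats::qlogis(base_up) + config$induction_link * z)
    p_down <- stats::plogis(stats::qlogis(base_down) - config$induction_link * z)
    u <- stats::runif(n)
    cls <- ifelse(u < p_up, "up",
           ifelse(u < p_up + pmin(p_down, 1 - p_up), "down", "unchanged"))
    log2fc <- ifelse(cls == "up", stats::rnorm(n, 2, 0.25),
              ifelse(cls == "down", stats::rnorm(n, -2, 0.25),
                     stats::rnorm(n, 0, 0.25)))
    q <- ifelse(cls == "unchanged", stats::runif(n, 0.2, 1),
                stats::runif(n, 0, 0.01))
    data.frame(gene_id = records$gene_id,
               fpkm_a = fpkm / 2^log2fc,
               fpkm = fpkm,
               log2fc = log2fc,
               q_value = q,
               true_class = cls,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a matched tumor/normal cohort with planted 5-hmC changes
#'
#' Builds a genome, plants disjoint loss and gain gene sets (loss genes
#' carry gene-body peaks in both normal samples only; gain genes in both
#' tumor samples only; a background stratum carries peaks in all four or
#' none), and generates a genes-by-samples expression matrix in which a
#' configurable subset of each planted list receives a true fold change
#' in the concordant direction.
#'
#' @param n_loss,n_loss_shifted Planted loss genes and how many of them
#'   truly lose expression.
#' @param n_gain,n_gain_shifted Planted gain genes and how many truly
#'   gain expression.
#' @param n_genes Total genes (must exceed `n_loss + n_gain`).
#' @param n_per_group Tumor and normal sample count in the expression
#'   matrix.
#' @param fold Expression fold change for shifted genes.
#' @param sd_log Log-scale biological noise sd of expression.
#' @param seed Master seed.
#' @return A list with `sizes`, `genes`, `normal_peaks` / `tumor_peaks`
#'   (lists of two peak `GRanges` each), `expr` (matrix), `groups`, and
#'   `truth` (planted id lists).
#' @export
simulate_cancer_cohort <- function(n_loss = 222, n_loss_shifted = 163,
                                   n_gain = 175, n_gain_shifted = 96,
                                   n_genes = 600, n_per_group = 12,
                                   fold = 8, sd_log = 0.2, seed = 1) {
  stopifnot(n_loss_shifted <= n_loss, n_gain_shifted <= n_gain,
            n_loss + n_gain <= n_genes)
  cfg <- sim_config(seed = seed,
                    chrom_lengths = c(chr1 = 5e6, chr2 = 4e6),
                    n_genes = n_genes, gene_meanlog = log(5000),
                    gene_sdlog = 0.3, n_islands = 0)
  gen <- simulate_genome(cfg)
  ids <- gene_ids(gen$genes)
  with_seed(seed + 1L, {
    pick <- sample(ids, n_loss + n_gain)
    loss <- pick[seq_len(n_loss)]
    gain <- pick[n_loss + seq_len(n_gain)]
    rest <- setdiff(ids, pick)
    background <- sample(rest, length(rest) %/% 2)  # peaks in all samples
    loss_shift <- sample(loss, n_loss_shifted)
    gain_shift <- sample(gain, n_gain_shifted)

    bodies <- get_bodies(gen$genes)
    body_of <- function(g) bodies[match(g, ids)]
    mk_peaks <- function(present_ids, samp_seed) with_seed(samp_seed, {
      b <- body_of(present_ids)
      ## peak = central subinterval of the gene body
      w <- pmax(100L, as.integer(width(b) * 0.5))
      st <- start(b) + (width(b) - w) %/% 2L
      pk <- GRanges(seqnames(b), IRanges(st, width = w))
      pk <- gr_on_sizes(pk, gen$sizes)
      mcols(pk)$tags <- as.numeric(stats::rnbinom(length(pk), mu = 50, size = 5) + 1L)
      mcols(pk)$density <- mcols(pk)$tags / width(pk)
      sort(pk)
    })
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 4)
    normal_peaks <- lapply(1:2, function(i)
      mk_peaks(c(loss, background), sub_seeds[i]))
    tumor_peaks <- lapply(1:2, function(i)
      mk_peaks(c(gain, background), sub_seeds[2 + i]))

    ns <- 2 * n_per_group
    groups <- rep(c("normal", "tumor"), each = n_per_group)
    base <- stats::rlnorm(n_genes, log(100), 0.5)
    expr <- matrix(stats::rlnorm(n_genes * ns, 0, sd_log), n_genes, ns) * base
    rownames(expr) <- ids
    colnames(expr) <- paste0(rep(c("N", "T"), each = n_per_group),
                             seq_len(n_per_group))
    tum <- groups == "tumor"
    expr[loss_shift, tum] <- expr[loss_shift, tum] / fold
    expr[gain_shift, tum] <- expr[gain_shift, tum] * fold

    list(sizes = gen$sizes, genes = gen$genes,
         normal_peaks = normal_peaks, tumor_peaks = tumor_peaks,
         expr = expr, groups = groups,
         truth = list(loss = loss, gain = gain,
                      loss_shifted = loss_shift, gain_shifted = gain_shift,
                      background = background))
  })
}

#' Simulate TAB-seq clone-count tables
#'
#' For each CpG and condition, bisulfite clone counts are binomial with
#' success probability `(pct_5mC + pct_5hmC)/100` (both states protected
#' from conversion) and TAB clone counts binomial with probability
#' `pct_5hmC/100` (only 5-hmC protected), independently per site.
#'
#' @param config An [sim_config()] object (`tabseq_truth`,
#'   `clones_per_site`).
#' @param n_sites CpGs per condition.
#' @param chrom,start Region placement of the simulated CpGs.
#' @param seed Optional seed overriding `config$seed`.
#' @return A wide `data.frame` as returned by [read_tabseq()].
#' @export
simulate_tabseq <- function(config = sim_config(), n_sites = 10,
                            chrom = "chr1", start = 10000,
                            seed = config$seed) {
  with_seed(seed, {
    out <- lapply(names(config$tabseq_truth), function(cond) {
      tt <- config$tabseq_truth[[cond]]
      p_bs <- (tt[2] + tt[3]) / 100
      p_tab <- tt[3] / 100
      nc <- config$clones_per_site
      data.frame(chrom = chrom,
                 pos = start + 25L * seq_len(n_sites),
                 condition = cond,
                 bs_c = stats::rbinom(n_sites, nc, p_bs),
                 bs_t = NA_integer_, tab_c = stats::rbinom(n_sites, nc, p_tab),
                 tab_t = NA_integer_, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$bs_t <- config$clones_per_site - out$bs_c
    out$tab_t <- config$clones_per_site - out$tab_c
    out
  })
}
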