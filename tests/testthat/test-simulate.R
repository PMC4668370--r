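test_that("genome simulation is deterministic and packs features disjointly", {
  cfg <- sim_config(seed = 42)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.data.frame(g1$genes$genes), as.data.frame(g2$genes$genes))
  expect_identical(as.data.frame(g1$islands), as.data.frame(g2$islands))
  ## gene bodies and islands never overlap
  feats <- c(granges(get_bodies(g1$genes)), granges(g1$islands))
  strand(feats) <- "*"
  expect_equal(coverage_bases(feats), sum(as.numeric(width(feats))))
  ## all within bounds
  slen <- GenomeInfoDb::seqlengths(g1$sizes)
  expect_true(all(end(feats) <= slen[as.character(seqnames(feats))]))
})

test_that("degenerate genome configs behave as specified", {
  empty <- simulate_genome(sim_config(seed = 1, n_genes = 0, n_islands = 5))
  expect_equal(length(empty$genes$genes), 0L)
  ## infeasible packing errors
  tiny <- sim_config(seed = 1, chrom_lengths = c(chr1 = 10000),
                     n_genes = 50, gene_meanlog = log(5000), gene_sdlog = 0.1,
                     n_islands = 0)
  expect_error(simulate_genome(tiny), "infeasible")
})

test_that("simulated files round-trip through the package's own readers", {
  cfg <- sim_config(seed = 99, n_genes = 40, n_islands = 20, n_peaks = 50)
  g <- simulate_genome(cfg)
  pt <- simulate_peaks_and_tags(cfg, g$islands, g$sizes)
  d <- tempfile(); dir.create(d)
  szf <- file.path(d, "genome.sizes")
  utils::write.table(data.frame(GenomeInfoDb::seqnames(g$sizes),
                                GenomeInfoDb::seqlengths(g$sizes)),
                     szf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gene_models_gtf(g$genes, file.path(d, "genes.gtf"))
  write_bed(g$islands, file.path(d, "islands.bed"))
  write_peaks(pt$peaks, file.path(d, "peaks.bed"))
  write_bed(pt$tags, file.path(d, "tags.bed"))

  sz <- read_chrom_sizes(szf)
  expect_identical(GenomeInfoDb::seqlengths(sz),
                   GenomeInfoDb::seqlengths(g$sizes))
  gm <- read_gene_models(file.path(d, "genes.gtf"), sizes = sz)
  expect_identical(as.data.frame(granges(gm$genes)),
                   as.data.frame(granges(g$genes$genes)))
  isl <- load_bed_annotation(file.path(d, "islands.bed"), sizes = sz)
  expect_identical(ranges(isl), ranges(g$islands))
  pk <- read_peaks(file.path(d, "peaks.bed"), sizes = sz)
  expect_identical(ranges(sort(pk)), ranges(sort(pt$peaks)))
  expect_equal(sum(mcols(pk)$tags), sum(mcols(pt$peaks)$tags))
  tg <- read_bed(file.path(d, "tags.bed"), sizes = sz)
  expect_equal(length(tg), length(pt$tags))
})

test_that("planted tag-mass fraction is achieved in expectation", {
  cfg <- sim_config(seed = 5, annotation_fraction_q = 0.5, n_peaks = 150)
  g <- simulate_genome(cfg)
  fr <- vapply(1:30, function(i)
    simulate_peaks_and_tags(cfg, g$islands, g$sizes,
                            seed = 700 + i)$realized_fraction, 0)
  ## binomial placement: mean near q, sd ~ 0.5/sqrt(150) ~ 0.04
  expect_lt(abs(mean(fr) - 0.5), 2 * stats::sd(fr) / sqrt(30) + 0.02)
  ## degenerate q = 1: every peak fully inside
  cfg1 <- sim_config(seed = 5, annotation_fraction_q = 1, n_peaks = 60)
  pt1 <- simulate_peaks_and_tags(cfg1, g$islands, g$sizes)
  expect_equal(pt1$realized_fraction, 1, tolerance = 1e-12)
  ## q equal to the annotation's genomic fraction ~ null construction
  f_ann <- coverage_bases(g$islands) /
    sum(as.numeric(GenomeInfoDb::seqlengths(g$sizes)))
  cfg0 <- sim_config(seed = 6, annotation_fraction_q = f_ann, n_peaks = 2000)
  pt0 <- simulate_peaks_and_tags(cfg0, g$islands, g$sizes)
  r <- enrichment_test(pt0$peaks, g$islands, g$sizes, n_shuffles = 100,
                       seed = 3)
  expect_gt(r$enrichment, 0.6)
  expect_lt(r$enrichment, 1.5)
})

test_that("tag intervals lie within their peaks' coverage", {
  cfg <- sim_config(seed = 8, n_peaks = 80)
  g <- simulate_genome(cfg)
  pt <- simulate_peaks_and_tags(cfg, g$islands, g$sizes)
  expect_equal(length(pt$tags), sum(mcols(pt$peaks)$tags))
  within <- countOverlaps(pt$tags, pt$peaks, type = "within",
                          ignore.strand = TRUE)
  expect_true(all(within >= 1))
})

test_that("expression link strength controls the density-FPKM correlation", {
  set.seed(50)
  rec <- data.frame(gene_id = sprintf("g%04d", 1:2000),
                    density = rlnorm(2000, log(0.01), 0.8))
  none <- simulate_expression(rec, sim_config(seed = 1, link_slope = 0,
                                              induction_link = 0))
  expect_lt(abs(cor(rec$density, none$fpkm, method = "spearman")), 0.1)
  strong <- simulate_expression(rec, sim_config(seed = 2, link_slope = 1,
                                                link_noise_sd = 0.1))
  expect_gt(cor(rec$density, strong$fpkm, method = "spearman"), 0.8)
  ## planted up-genes are recovered by the default classifier
  cl <- classify_expression(strong)
  expect_true(all(cl$de_class[cl$true_class == "up"] == "up"))
  expect_true(all(cl$de_class[cl$true_class == "unchanged"] == "unchanged"))
})

test_that("cancer cohort generator validates and plants disjoint sets", {
  co <- simulate_cancer_cohort(n_loss = 10, n_loss_shifted = 5, n_gain = 8,
                               n_gain_shifted = 4, n_genes = 60, seed = 2)
  expect_equal(length(intersect(co$truth$loss, co$truth$gain)), 0L)
  expect_equal(length(co$normal_peaks), 2L)
  expect_equal(dim(co$expr), c(60L, 24L))
  ## no planted genes -> no calls
  co0 <- simulate_cancer_cohort(n_loss = 0, n_loss_shifted = 0, n_gain = 0,
                                n_gain_shifted = 0, n_genes = 40, seed = 3)
  calls0 <- call_hmc_change(co0$genes, consensus(co0$normal_peaks),
                            consensus(co0$tumor_peaks))
  expect_equal(nrow(calls0), 0L)
  expect_error(simulate_cancer_cohort(n_loss = 50, n_loss_shifted = 60,
                                      n_genes = 100), "n_loss_shifted")
})

test_that("TAB-seq generator respects degenerate truths and determinism", {
  pure_hmc <- sim_config(seed = 4, tabseq_truth = list(x = c(0, 0, 100)))
  ts <- simulate_tabseq(pure_hmc, n_sites = 8)
  expect_true(all(ts$tab_c == 20))  # all TAB clones read C
  pure_c <- sim_config(seed = 4, tabseq_truth = list(x = c(100, 0, 0)))
  ts2 <- simulate_tabseq(pure_c, n_sites = 8)
  expect_true(all(ts2$bs_c == 0))   # all bisulfite clones read T
  cfg <- sim_config(seed = 31)
  expect_identical(simulate_tabseq(cfg), simulate_tabseq(cfg))
  expect_error(sim_config(tabseq_truth = list(x = c(50, 20, 20))), "sum to 100")
})
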