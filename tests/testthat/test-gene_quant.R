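szg <- chrom_sizes(c(chr1 = 200000))

test_that("genes_with_peaks applies the flank rule with half-open adjacency", {
  g <- gene_models("chr1", 10000, 20000, "+", "g1", szg)
  near <- peaks("chr1", 21000, 21500, tags = 5, sizes = szg)  # 1000 bp past end
  far <- peaks("chr1", 22500, 23000, tags = 5, sizes = szg)   # 2500 bp past end
  expect_equal(genes_with_peaks(g, near, szg, flank = 2000), "g1")
  expect_equal(genes_with_peaks(g, far, szg, flank = 2000), character(0))
  abut <- peaks("chr1", 20000, 20500, tags = 5, sizes = szg)  # starts at gene end
  expect_equal(genes_with_peaks(g, abut, szg, flank = 0), character(0))
  expect_equal(genes_with_peaks(g, abut, szg, flank = 1), "g1")
})

test_that("count_tags_per_gene: peak filter, unambiguous counting, density", {
  g <- gene_models("chr1", c(1000, 10000, 30000), c(2000, 11000, 31000),
                   c("+", "+", "-"), c("gA", "gB", "gC"), szg)
  pk <- peaks("chr1", c(1200, 10100), c(1400, 10400), tags = c(5, 5), sizes = szg)
  ## gA gets 10 tags, gB gets 3; gC has tags but no peak
  tg <- c(gi("chr1", seq(1000, 1900, by = 100), seq(1000, 1900, by = 100) + 50),
          gi("chr1", c(10100, 10200, 10300), c(10150, 10250, 10350)),
          gi("chr1", c(30100, 30200), c(30150, 30250)))
  rec <- count_tags_per_gene(tg, g, pk)
  expect_setequal(rec$gene_id, c("gA", "gB"))
  expect_equal(rec$tag_count[rec$gene_id == "gA"], 10L)
  expect_equal(rec$tag_count[rec$gene_id == "gB"], 3L)
  expect_equal(rec$density[rec$gene_id == "gA"], 10 / 1000)
})

test_that("a tag overlapping two counted genes contributes to neither", {
  g <- gene_models("chr1", c(1000, 1900), c(2000, 3000), c("+", "+"),
                   c("gA", "gB"), szg)  # overlapping bodies
  pk <- peaks("chr1", c(1100, 2100), c(1300, 2300), tags = c(5, 5), sizes = szg)
  amb <- gi("chr1", 1950, 1990)  # inside both bodies
  ua <- gi("chr1", 1100, 1150)   # gA only
  rec <- count_tags_per_gene(c(amb, ua), g, pk)
  expect_equal(rec$tag_count[rec$gene_id == "gA"], 1L)
  expect_equal(rec$tag_count[rec$gene_id == "gB"], 0L)
})

test_that("percentile binning reproduces the printed occupancies", {
  rec <- data.frame(gene_id = sprintf("g%03d", 1:100), tag_count = 1:100,
                    gene_length = 1000, density = (1:100) / 1000)
  b <- bin_by_percentile(rec)
  expect_equal(as.vector(table(b$bin)), c(25, 50, 23, 2))
  ## the top 2% are the two densest genes
  expect_setequal(b$gene_id[b$bin == "P98_100"], c("g099", "g100"))
  ## partition: every record in exactly one bin
  expect_false(anyNA(b$bin))
  expect_equal(nrow(b), 100L)
})

test_that("binning at minimal n and under ties is deterministic", {
  rec4 <- data.frame(gene_id = paste0("g", 1:4), density = c(4, 3, 2, 1) / 10)
  b4 <- bin_by_percentile(rec4)
  expect_equal(as.vector(table(b4$bin)), c(1, 2, 0, 1))
  expect_error(bin_by_percentile(rec4[1:3, ]), "at least 4")

  tied <- data.frame(gene_id = paste0("g", sprintf("%02d", 1:8)),
                     density = rep(0.5, 8))
  b1 <- bin_by_percentile(tied)
  b2 <- bin_by_percentile(tied[sample(8), ])
  b2 <- b2[match(b1$gene_id, b2$gene_id), ]
  expect_equal(as.character(b1$bin), as.character(b2$bin))  # stable under order
  expect_equal(as.vector(table(b1$bin)), c(2, 4, 1, 1))
})

test_that("metagene profile is flat for uniform coverage", {
  feats <- gi("chr1", c(20000, 60000, 100000), c(30000, 70000, 110000),
              strand = c("+", "-", "+"))
  ## tile the whole region densely and uniformly
  st <- seq(0, 149950, by = 50)
  tg <- gi("chr1", st, st + 50)
  p <- metagene_profile(tg, feats, body_bins = 20, flank = 2000, flank_bins = 4)
  expect_equal(nrow(p), 28L)
  expect_lt(diff(range(p$signal)), 1e-9)
})

test_that("metagene profile localizes a TSS spike and is depth-invariant", {
  feats <- gi("chr1", c(20000, 60000), c(30000, 70000), strand = c("+", "-"))
  tss0 <- c(20000, 69999)  # 5' base of each feature
  tg <- gi("chr1", rep(tss0, each = 50), rep(tss0, each = 50) + 1)
  p <- metagene_profile(tg, feats, body_bins = 10, flank = 1000, flank_bins = 2)
  body_first <- p$signal[p$region == "body"][1]
  expect_true(all(p$signal[p$bin != which(p$region == "body")[1]] <= body_first))
  expect_gt(body_first, 0)
  ## doubling the tags leaves the per-million profile unchanged
  p2 <- metagene_profile(c(tg, tg), feats, body_bins = 10, flank = 1000,
                         flank_bins = 2)
  expect_equal(p$signal, p2$signal, tolerance = 1e-12)
})

test_that("strand-flipping features reverses the profile", {
  set.seed(55)
  st <- sample(0:149000, 400, replace = TRUE)
  tg <- gi("chr1", st, st + sample(30:80, 400, TRUE))
  f_plus <- gi("chr1", c(20000, 90000), c(32000, 101000), strand = "+")
  f_minus <- f_plus
  strand(f_minus) <- "-"
  a <- metagene_profile(tg, f_plus, body_bins = 12, flank = 1200, flank_bins = 3)
  b <- metagene_profile(tg, f_minus, body_bins = 12, flank = 1200, flank_bins = 3)
  expect_equal(a$signal, rev(b$signal), tolerance = 1e-9)
})

test_that("synthetic gene densities show a unimodal right-tailed distribution", {
  cfg <- sim_config(seed = 17, n_genes = 400, n_peaks = 300,
                    annotation_fraction_q = 0.3)
  g <- simulate_genome(cfg)
  pt <- simulate_peaks_and_tags(cfg, annotation_set(get_bodies(g$genes)),
                                g$sizes)
  rec <- count_tags_per_gene(pt$tags, g$genes, pt$peaks)
  expect_gt(nrow(rec), 50)
  d <- rec$density
  skew <- mean((d - mean(d))^3) / stats::sd(d)^3
  expect_gt(skew, 0)
})
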