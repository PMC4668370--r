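test_that("observed_tags evaluates the intersection-times-density formula", {
  sz <- chrom_sizes(c(chr1 = 10000))
  pk <- peaks("chr1", 100, 200, tags = 50, sizes = sz)   # density 0.5
  ann <- annotation_set(gi("chr1", 160, 300))
  expect_equal(observed_tags(pk, ann), 40 * 0.5)          # 20 tag units

  full <- annotation_set(gi("chr1", 0, 10000))
  pk2 <- random_peaks(15, sz, seed = 5)
  expect_equal(observed_tags(pk2, full), sum(mcols(pk2)$tags))

  far <- annotation_set(gi("chr1", 9000, 9500))
  expect_equal(observed_tags(pk, far), 0)
})

test_that("observed_tags equals the per-base brute-force oracle", {
  set.seed(42)
  for (i in 1:100) {
    L <- sample(2000:10000, 1)
    sz <- chrom_sizes(c(g = L))
    n <- sample(1:20, 1)
    st <- sample(0:(L - 300), n, replace = TRUE)
    pk <- peaks("g", st, st + sample(20:250, n, replace = TRUE),
                tags = sample.int(80, n, replace = TRUE), sizes = sz)
    na <- sample(1:6, 1)
    as <- sample(0:(L - 400), na, replace = TRUE)
    ann <- annotation_set(gi("g", as, as + sample(50:350, na, replace = TRUE)))
    expect_equal(observed_tags(pk, ann),
                 brute_observed_tags(pk, ann, c(g = L)),
                 tolerance = 1e-9)
  }
})

test_that("tag mass is conserved over a partition of the genome", {
  sz <- chrom_sizes(c(chr1 = 50000, chr2 = 30000))
  pk <- random_peaks(40, sz, seed = 8)
  parts <- list(
    annotation_set(gi("chr1", 0, 20000)),
    annotation_set(gi("chr1", 20000, 50000)),
    annotation_set(gi("chr2", 0, 30000)))
  expect_equal(sum(vapply(parts, function(a) observed_tags(pk, a), 0)),
               sum(mcols(pk)$tags), tolerance = 1e-12)
})

test_that("expected_tags: full-genome annotation is shuffle-invariant", {
  sz <- chrom_sizes(c(chr1 = 40000, chr2 = 20000))
  pk <- random_peaks(25, sz, seed = 3)
  full <- annotation_set(gi(c("chr1", "chr2"), c(0, 0), c(40000, 20000)))
  et <- expected_tags(pk, full, sz, n_shuffles = 30, seed = 1)
  expect_equal(et$mean, sum(mcols(pk)$tags), tolerance = 1e-12)
  expect_equal(et$sd, 0, tolerance = 1e-9)
})

test_that("expected_tags is deterministic and matches the analytic mean", {
  sz <- chrom_sizes(c(chr1 = 100000))
  pk <- random_peaks(60, sz, max_width = 100, seed = 9)
  ann <- annotation_set(gi("chr1", seq(0, 90000, by = 10000),
                           seq(0, 90000, by = 10000) + 2000))  # f = 0.2
  a <- expected_tags(pk, ann, sz, n_shuffles = 200, seed = 77)
  b <- expected_tags(pk, ann, sz, n_shuffles = 200, seed = 77)
  expect_identical(a, b)
  f <- coverage_bases(ann) / 100000
  analytic <- f * sum(mcols(pk)$tags)
  expect_lt(abs(a$mean - analytic), 3 * a$sd / sqrt(200) + 0.02 * analytic)
})

test_that("the fast null loop equals explicit shuffle-and-measure", {
  sz <- chrom_sizes(c(chr1 = 60000, chr2 = 25000))
  pk <- random_peaks(30, sz, seed = 14)
  ann <- annotation_set(gi("chr1", c(0, 30000), c(10000, 42000)))
  et <- expected_tags(pk, ann, sz, n_shuffles = 25, seed = 5)
  seeds <- hmcdiff:::derive_seeds(5, 25)
  slow <- vapply(seq_len(25), function(i)
    observed_tags(shuffle_peaks(pk, sz, seed = seeds[i]), ann), 0)
  expect_equal(et$null_samples, slow, tolerance = 1e-12)
})

test_that("enrichment_test recovers the analytic limit for planted peaks", {
  ## all peaks inside an annotation covering fraction f -> enrichment ~ 1/f
  sz <- chrom_sizes(c(chr1 = 200000))
  f <- 0.05
  ann <- annotation_set(gi("chr1", 0, 200000 * f))
  set.seed(6)
  st <- sample(0:(200000 * f - 300), 80, replace = TRUE)
  pk <- peaks("chr1", st, st + 250, tags = sample.int(60, 80, TRUE), sizes = sz)
  r <- enrichment_test(pk, ann, sz, n_shuffles = 300, seed = 2)
  expect_equal(r$enrichment, 1 / f,
               tolerance = 4 * r$expected_sd / sqrt(300) / r$expected + 0.05)
  expect_lte(r$p_enrichment, 1 / 301 + 1e-12)
  expect_equal(r$p_depletion, 1)
})

test_that("uniformly placed peaks are unenriched and p has the add-one floor", {
  sz <- chrom_sizes(c(chr1 = 150000))
  ann <- annotation_set(gi("chr1", seq(0, 140000, 15000),
                           seq(0, 140000, 15000) + 7000))
  tmpl <- random_peaks(400, sz, max_width = 120, seed = 10)
  pk <- shuffle_peaks(tmpl, sz, seed = 123)   # uniform placement
  r <- enrichment_test(pk, ann, sz, n_shuffles = 250, seed = 4)
  expect_gt(r$enrichment, 0.85)
  expect_lt(r$enrichment, 1.15)
  expect_gte(r$p_enrichment, 1 / 251)
  expect_gte(r$p_depletion, 1 / 251)
})

test_that("empirical p is approximately uniform under the null", {
  sz <- chrom_sizes(c(chr1 = 50000))
  ann <- annotation_set(gi("chr1", c(5000, 25000), c(10000, 32000)))
  tmpl <- random_peaks(25, sz, max_width = 150, seed = 20)
  ps <- vapply(1:200, function(i) {
    pk <- shuffle_peaks(tmpl, sz, seed = 1000 + i)
    enrichment_test(pk, ann, sz, n_shuffles = 50, seed = 2000 + i)$p_enrichment
  }, 0)
  ## Kolmogorov-style distance to U(0,1); discreteness contributes ~1/51
  d <- max(abs(sort(ps) - (seq_along(ps)) / length(ps)))
  expect_lt(d, 0.15)
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
})

test_that("enrichment is monotone in the planted tag-mass fraction", {
  cfgs <- lapply(c(0.1, 0.4, 0.8), function(q)
    sim_config(seed = 33, chrom_lengths = c(chr1 = 1e6), n_peaks = 150,
               n_genes = 40, n_islands = 40, annotation_fraction_q = q))
  mean_enr <- vapply(cfgs, function(cfg) {
    g <- simulate_genome(cfg)
    e <- vapply(1:3, function(s) {
      pt <- simulate_peaks_and_tags(cfg, g$islands, g$sizes, seed = 100 + s)
      enrichment_test(pt$peaks, g$islands, g$sizes, n_shuffles = 60,
                      seed = 200 + s)$enrichment
    }, 0)
    mean(e)
  }, 0)
  expect_true(all(diff(mean_enr) > 0))
})

test_that("replicate averaging reports mean and sd of enrichment ratios", {
  mk <- function(e) structure(list(annotation = "x", enrichment = e),
                              class = "EnrichmentResult")
  avg <- average_replicates(list(mk(2), mk(4)))
  expect_equal(avg$mean_enrichment, 3)
  expect_equal(avg$sd_enrichment, sqrt(2))
  one <- average_replicates(list(mk(1.7)))
  expect_equal(one$mean_enrichment, 1.7)
  expect_equal(one$sd_enrichment, 0)
  expect_error(average_replicates(list()), "no replicates")
  bad <- structure(list(annotation = "y", enrichment = 1),
                   class = "EnrichmentResult")
  expect_error(average_replicates(list(mk(1), bad)), "different annotations")
})

test_that("zero expected overlap is flagged, p still reported", {
  sz <- chrom_sizes(c(chr1 = 10000, chr2 = 10000))
  pk <- peaks("chr1", 100, 300, tags = 10, sizes = sz)
  ## annotation too small for any 200 bp shuffled peak to ever overlap it?
  ## simpler: peaks wider than annotation chromosome -> never placed there
  skinny <- chrom_sizes(c(chr1 = 10000, chr2 = 150))
  pk2 <- peaks("chr1", 100, 300, tags = 10, sizes = skinny)
  ann <- annotation_set(gi("chr2", 0, 150))
  expect_warning(r <- enrichment_test(pk2, ann, skinny, n_shuffles = 20,
                                      seed = 1), "expected overlap is 0")
  expect_true(is.na(r$enrichment))
  expect_gte(r$p_enrichment, 1 / 21)
})
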