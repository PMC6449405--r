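# small multi-chromosome balanced map with controllable trans block
trans_toy_map <- function(n_chrom = 4, bins_per = 10, trans_base = 5,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_chrom * bins_per
  sizes <- setNames(rep(bins_per * 1e5, n_chrom),
                    paste0("chr", seq_len(n_chrom)))
  bins <- bin_table(sizes, 1e5)
  ch <- bins$chrom
  cis <- outer(ch, ch, "==")
  M <- matrix(trans_base, n, n)
  M[cis] <- 50
  map <- map_from_dense(M, chrom_sizes = sizes)
  map$weights <- rep(1, n); map$balanced <- TRUE
  map
}

test_that("uniform trans counts give all-zero Z-scores", {
  map <- trans_toy_map()
  pr <- locus_trans_zscores(map, anchor_bin = 0L, min_partners = 10)
  expect_equal(unique(pr$z), 0)
  expect_equal(nrow(pr), 30)  # partners on the other 3 chromosomes
})

test_that("trimming removes an extreme outlier and Z matches the hand computation", {
  map <- trans_toy_map()
  # hand-built 10-value trans vector for the anchor: one extreme outlier
  M <- as_dense(map, apply_mask = FALSE)
  vals <- c(4, 5, 6, 5, 4, 6, 5, 4, 6, 500)
  bins <- map$bins
  partners <- which(bins$chrom != "chr1")[1:10]
  M[1, ] <- 0; M[, 1] <- 0
  M[1, partners] <- vals; M[partners, 1] <- vals
  M[1, 1] <- 50
  m2 <- map_from_dense(M, chrom_sizes = c(chr1 = 1e6, chr2 = 1e6,
                                          chr3 = 1e6, chr4 = 1e6))
  m2$weights <- rep(1, 40); m2$balanced <- TRUE
  pr <- locus_trans_zscores(m2, anchor_bin = 0L, min_partners = 5)
  kept <- pr$value[pr$bin_id %in% (partners - 1L)]
  expect_false(500 %in% kept)
  expect_equal(attr(pr, "n_trimmed") >= 1, TRUE)
  ref <- vals[vals <= quantile(vals, 0.995)]
  z_ref <- (ref - mean(c(ref, rep(0, 20)))) / sd(c(ref, rep(0, 20)))
  # the anchor also faces 20 zero-count partner bins on chr3/chr4
  expect_equal(sort(unique(round(pr$z[pr$value > 0], 6))),
               sort(unique(round(z_ref, 6))))
  expect_equal(mean(pr$z), 0, tolerance = 1e-12)
  expect_equal(sd(pr$z), 1, tolerance = 1e-12)
})

test_that("trim = 0 keeps all bins and larger trims never keep more", {
  map <- trans_toy_map(seed = 81)
  M <- as_dense(map)
  n0 <- nrow(locus_trans_zscores(map, 0L, trim = 0, min_partners = 1))
  n1 <- nrow(locus_trans_zscores(map, 0L, trim = 0.05, min_partners = 1))
  n2 <- nrow(locus_trans_zscores(map, 0L, trim = 0.2, min_partners = 1))
  expect_equal(n0, 30)
  expect_gte(n0, n1); expect_gte(n1, n2)
})

test_that("gene-set trans score sums trans pairs only and is order-invariant", {
  sizes <- c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6)
  bins <- bin_table(sizes, 1e5)
  M <- matrix(0, 30, 30)
  # gene bins: chr1 bin0, chr2 bin0 (id 10), chr3 bin0 (id 20)
  M[1, 11] <- M[11, 1] <- 12
  M[1, 21] <- M[21, 1] <- 5
  M[11, 21] <- M[21, 11] <- 7
  map <- map_from_dense(M, chrom_sizes = sizes)
  map$weights <- rep(1, 30); map$balanced <- TRUE
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      chrom = c("chr1", "chr2", "chr3"),
                      tss = c(5e4, 5e4, 5e4))
  gs <- geneset_trans_score(map, genes)
  expect_equal(gs$score, 24)
  expect_equal(nrow(gs$edges), 3)
  # permuting gene order leaves the score unchanged
  expect_equal(geneset_trans_score(map, genes[c(3, 1, 2), ])$score, 24)
  # two genes on the same chromosome -> 0
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   tss = c(5e4, 8.5e5))
  expect_equal(geneset_trans_score(map, g2)$score, 0)
  # off-assembly gene errors by name
  g3 <- data.frame(gene_id = "zz", chrom = "chrX", tss = 1)
  expect_error(geneset_trans_score(map, g3), "zz")
})

test_that("permutation null is deterministic under a fixed seed and p is calibrated", {
  map <- trans_toy_map(seed = 82)
  set.seed(83)
  universe <- data.frame(
    gene_id = sprintf("u%03d", 1:80),
    chrom = rep(paste0("chr", 1:4), each = 20),
    tss = rep(seq(2.5e4, by = 5e4, length.out = 20), 4))
  seed_genes <- universe[c(1, 2, 21, 22, 41, 42, 61, 62), ]
  r1 <- permutation_null(map, seed_genes, universe, n = 50, seed = 9)
  r2 <- permutation_null(map, seed_genes, universe, n = 50, seed = 9)
  expect_identical(r1$null, r2$null)
  expect_gt(r1$p, 0); expect_lte(r1$p, 1)
  # uniform map: every gene set scores the same, p = 1
  expect_equal(r1$observed, unique(r1$null))
  expect_equal(r1$p, 1)
  # universe too small on a chromosome errors
  small_u <- universe[universe$chrom != "chr4", ]
  expect_error(permutation_null(map, seed_genes, small_u, n = 5, seed = 1),
               "chr4")
})

test_that("doubling all counts doubles observed and null scores, leaving p fixed", {
  set.seed(84)
  n <- 40
  sizes <- c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6, chr4 = 1e6)
  M <- matrix(runif(n^2, 1, 10), n); M <- M + t(M)
  m1 <- map_from_dense(M, chrom_sizes = sizes)
  m1$weights <- rep(1, n); m1$balanced <- TRUE
  m2 <- map_from_dense(2 * M, chrom_sizes = sizes)
  m2$weights <- rep(1, n); m2$balanced <- TRUE
  universe <- data.frame(gene_id = sprintf("u%03d", 1:40),
                         chrom = rep(paste0("chr", 1:4), each = 10),
                         tss = rep(seq(5e4, by = 1e5, length.out = 10), 4))
  seed_genes <- universe[c(1, 11, 21, 31), ]
  r1 <- permutation_null(m1, seed_genes, universe, n = 30, seed = 5)
  r2 <- permutation_null(m2, seed_genes, universe, n = 30, seed = 5)
  expect_equal(r2$observed, 2 * r1$observed)
  expect_equal(r2$null, 2 * r1$null)
  expect_equal(r1$p, r2$p)
})

test_that("a planted trans hub is detected by the permutation test", {
  cfg <- hic_sim_config(n_chromosomes = 4, bins_per_chrom = 20,
                        hub_gain = 5, seed = 85)
  universe <- data.frame(
    gene_id = sprintf("u%03d", 1:80),
    chrom = rep(paste0("chr", 1:4), each = 20),
    tss = rep(seq(2.5e5, by = 5e5, length.out = 20), 4))
  hub_genes <- universe[c(1, 3, 5, 7, 21, 23, 25, 27,
                          41, 43, 45, 47, 61, 63, 65, 67), ]
  cfg_sim <- sim_hic(cfg, hub_bins = locate_bin(
    bin_table(setNames(rep(1e7, 4), paste0("chr", 1:4)), 5e5),
    hub_genes$chrom, hub_genes$tss))
  pooled <- pool_maps(lapply(cfg_sim$maps[c("t4_r1", "t4_r2")],
                             ice_balance))
  r <- permutation_null(pooled, hub_genes, universe, n = 200, seed = 6)
  expect_lte(r$p, 0.01)
})

test_that("network edges filter at the late median and annotate fold change", {
  sizes <- c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6)
  n <- 30
  M_early <- matrix(2, n, n)
  M_late <- matrix(2, n, n)
  bins <- bin_table(sizes, 1e5)
  ch <- bins$chrom
  # one hub pair well above the trans median at the late time point
  M_late[1, 11] <- M_late[11, 1] <- 10
  mke <- function(M) {
    m <- map_from_dense(M, chrom_sizes = sizes)
    m$weights <- rep(1, n); m$balanced <- TRUE
    m
  }
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      chrom = c("chr1", "chr2", "chr3"),
                      tss = c(5e4, 5e4, 5e4))
  net <- build_network(mke(M_early), mke(M_late), genes)
  hub <- net[net$gene_a == "a" & net$gene_b == "b", ]
  expect_true(hub$display)
  expect_gt(hub$log2fc, 0)
  # all other edges equal the median: strict inequality keeps them out
  expect_false(any(net$display[!(net$gene_a == "a" & net$gene_b == "b")]))
  # swapping time points negates the fold change
  rev_net <- build_network(mke(M_late), mke(M_early), genes)
  expect_equal(rev_net$log2fc, -net$log2fc)
})
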