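balanced_from_mu <- function(mu) {
  map <- map_from_dense(mu, resolution = 5e5)
  map$weights <- rep(1, nrow(mu)); map$balanced <- TRUE
  map
}

test_that("PC1 partitions an exact 2-block structure and orients to the reference", {
  cb <- checkerboard_mu(n = 30, strength = 2)
  map <- balanced_from_mu(cb$mu)
  orient <- as.numeric(cb$lab > 0)  # gene-density proxy: dense in A
  tr <- compute_pc1(map, orient)
  called <- ifelse(tr$score > 0, 1, -1)
  expect_equal(called, cb$lab)
})

test_that("PC1 equals a brute-force dense eigendecomposition", {
  set.seed(61)
  cb <- checkerboard_mu(n = 30, strength = 2)
  mu <- cb$mu * matrix(rlnorm(900, 0, 0.05), 30)  # mild noise
  mu <- (mu + t(mu)) / 2
  map <- balanced_from_mu(mu)
  tr <- compute_pc1(map, as.numeric(cb$lab > 0))
  # independent path: brute-force O/E by explicit per-distance loops, then
  # correlation via crossprod of standardized columns, then full eigen
  n <- 30
  oe <- matrix(NA_real_, n, n)
  for (d in 1:(n - 1)) {
    v <- mu[cbind(1:(n - d), (1 + d):n)]
    e <- mean(v)
    for (i in 1:(n - d)) oe[i, i + d] <- oe[i + d, i] <- mu[i, i + d] / e
  }
  for (k in 1:n) oe[k, k] <- mean(oe[k, -k])
  Z <- scale(oe)
  C <- crossprod(Z) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  ref <- eg$vectors[, 1]
  cosine <- abs(sum(ref * tr$score) /
                  sqrt(sum(ref^2) * sum(tr$score^2)))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("PC1 is invariant to global scaling of the raw matrix", {
  cb <- checkerboard_mu(n = 30)
  m1 <- balanced_from_mu(cb$mu)
  m2 <- balanced_from_mu(cb$mu * 7)
  o <- as.numeric(cb$lab > 0)
  t1 <- compute_pc1(m1, o); t2 <- compute_pc1(m2, o)
  expect_equal(t1$score / sqrt(sum(t1$score^2)),
               t2$score / sqrt(sum(t2$score^2)), tolerance = 1e-10)
})

test_that("a planted 50/50 genome yields a ~50/50 compartment fraction", {
  cfg <- hic_sim_config(n_chromosomes = 2, bins_per_chrom = 100,
                        switch_fraction = 0, include_trans = FALSE,
                        seed = 62)
  sim <- sim_hic(cfg)
  bal <- ice_balance(sim$maps[[1]])
  tr <- compute_pc1(bal, sim$orientation)
  fr <- compartment_fraction(tr)
  expect_lt(abs(fr["A"] - 0.5), 0.05)
  expect_equal(unname(fr["A"] + fr["B"]), 1)
  # sign flip swaps A and B exactly
  fr2 <- compartment_fraction(-tr$score)
  expect_equal(unname(fr2["B"]),
               mean(tr$score[!is.na(tr$score)] > 0))
})

test_that("switch categories follow the sign-sequence rules", {
  mk <- function(means, noise = 0.01) {
    # 2 replicates per tp tightly around the given means
    m <- rep(means, each = 2)
    rbind(m + noise * c(1, -1))
  }
  tp <- rep(c("t1", "t2", "t3", "t4"), each = 2)
  rp <- rep(1:2, 4)
  sc <- rbind(
    mk(c(1, 1, 1, 1)),        # stable-A
    mk(c(-1, -1, -1, -1)),    # stable-B
    mk(c(1, 1, -1, -1)),      # A-B
    mk(c(-1, -1, 1, 1)),      # B-A
    mk(c(1, -1, -1, 1)),      # A-B-A
    mk(c(-1, 1, 1, -1)),      # B-A-B
    mk(c(1, -1, 1, -1)))      # A-B-A-B -> merged to A-B
  sw <- classify_switches(sc, tp, rp, alpha = 0.05)
  expect_equal(sw$category,
               c("stable-A", "stable-B", "A-B", "B-A", "A-B-A", "B-A-B",
                 "A-B"))
  expect_equal(sw$switching, c(FALSE, FALSE, rep(TRUE, 5)))
})

test_that("constant bins get p = 1 and zeros inherit the previous sign", {
  tp <- rep(c("t1", "t2"), each = 2); rp <- rep(1:2, 2)
  sc <- rbind(c(0.5, 0.5, 0.5, 0.5),      # no variance at all
              c(0.5, 0.7, 0.0, 0.0))      # exact-zero late means
  sw <- classify_switches(sc, tp, rp)
  expect_equal(sw$anova_p[1], 1)
  expect_equal(sw$category[1], "stable-A")
  # zero means inherit the previous (positive) sign: no transition
  expect_false(sw$switching[2])
})

test_that("alpha = 0 calls nothing and alpha = 1 calls all sign-changers", {
  set.seed(63)
  tp <- rep(c("t1", "t2", "t3", "t4"), each = 2); rp <- rep(1:2, 4)
  sc <- matrix(rnorm(200 * 8, 0, 1), 200)
  s0 <- classify_switches(sc, tp, rp, alpha = 0)
  expect_equal(sum(s0$switching), 0)
  s1 <- classify_switches(sc, tp, rp, alpha = 1)
  gm <- sapply(split(1:8, tp), function(ix) rowMeans(sc[, ix]))
  changer <- apply(gm, 1, function(m) any(m > 0) && any(m < 0))
  expect_equal(s1$switching, unname(changer))
})

test_that("type-I rate under a pure-noise null is controlled at alpha", {
  set.seed(64)
  tp <- rep(c("t1", "t2", "t3", "t4"), each = 2); rp <- rep(1:2, 4)
  # bins with a true nonzero mean and replicate noise: no real switching
  n <- 4000
  mu <- sample(c(-1, 1), n, replace = TRUE)
  sc <- matrix(rnorm(n * 8, rep(mu, 8), 0.35), n)
  sw <- classify_switches(sc, tp, rp, alpha = 0.05)
  rate <- mean(sw$switching)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("saddle grid is zero for O/E == 1 and corner-dominant for planted compartments", {
  n <- 40
  bins_mu <- checkerboard_mu(n = n, strength = 2)
  flat <- matrix(1, n, n)
  m_flat <- balanced_from_mu(flat)
  m_flat$normalization <- "oe"
  track <- rnorm(n)
  s0 <- saddle(m_flat, track, n_quantiles = 4)
  expect_equal(max(abs(s0), na.rm = TRUE), 0)
  # planted: aperiodic random A/B labels so no distance class is pure
  set.seed(66)
  lab <- sample(c(1, -1), n, replace = TRUE)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  dc <- D; dc[dc == 0] <- 1
  mu <- 100 * dc^(-1)
  mu[D == 0] <- 400
  same <- outer(lab, lab, "==")
  mu[same] <- mu[same] * 2
  map <- balanced_from_mu(mu)
  oe <- oe_normalize(map)
  tr <- compute_pc1(map, as.numeric(lab > 0))
  s <- saddle(oe, tr)
  corners <- c(s[1, 1], s[10, 10])
  center <- s[5, 6]
  expect_true(all(corners > center))
  expect_true(s[1, 1] > s[1, 10] && s[10, 10] > s[1, 10])
  # symmetric by construction
  expect_equal(unclass(s), t(unclass(s)))
  # delta of a grid with itself is identically zero
  expect_equal(max(abs(delta_saddle(s, s)), na.rm = TRUE), 0)
})

test_that("decay curves are flat for a single-class genome and weighted means are 1", {
  n <- 30
  cb <- checkerboard_mu(n = n, strength = 2)
  map <- balanced_from_mu(cb$mu)
  one_class <- rep(1, n)
  dc1 <- decay_curves(map, one_class, min_pairs = 1)
  expect_true(all(abs(dc1$value - 1) < 1e-12))
  dc <- decay_curves(map, cb$lab, min_pairs = 1)
  for (d in unique(dc$distance)) {
    sub <- dc[dc$distance == d & !is.na(dc$value), ]
    expect_equal(sum(sub$value * sub$n_pairs) / sum(sub$n_pairs), 1,
                 tolerance = 1e-9)
  }
})

test_that("planted long-range B-B gain appears in late vs early decay curves", {
  cfg <- hic_sim_config(n_chromosomes = 1, bins_per_chrom = 60,
                        switch_fraction = 0, include_trans = FALSE,
                        bb_longrange_gain_per_stage = 0.5,
                        noise_dispersion = 0.01, seed = 65)
  sim <- sim_hic(cfg)
  early <- ice_balance(sim$maps$t1_r1)
  late <- ice_balance(sim$maps$t4_r1)
  lab <- ifelse(sim$truth$labels[, 1] == "A", 1, -1)
  d_early <- decay_curves(early, lab, min_pairs = 5)
  d_late <- decay_curves(late, lab, min_pairs = 5)
  m <- merge(d_early, d_late, by = c("distance", "class"))
  far_bb <- m$class == "B-B" & m$distance > 1e7 &
    !is.na(m$value.x) & !is.na(m$value.y)
  expect_gt(sum(far_bb), 3)
  expect_gt(mean(m$value.y[far_bb] - m$value.x[far_bb]), 0)
})
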