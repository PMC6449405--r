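test_that("triplet round trip is exact and errors name the offending line", {
  set.seed(11)
  M <- matrix(rpois(64, 20), 8); M <- M + t(M)
  map <- map_from_dense(M)
  td <- withr::local_tempdir()
  mp <- file.path(td, "m.matrix"); bp <- file.path(td, "m.bed")
  write_contact_map(map, mp, bp)
  back <- read_contact_map(mp, bp)
  expect_identical(back$i, map$i)
  expect_identical(back$j, map$j)
  expect_equal(back$x, map$x)
  # written files are byte-stable across repeated writes
  mp2 <- file.path(td, "m2.matrix")
  write_contact_map(back, mp2)
  expect_identical(unname(tools::md5sum(mp)), unname(tools::md5sum(mp2)))

  writeLines(c("0\t1\t5", "3\t5\t2", "3\t5\t7"), mp)
  expect_error(read_contact_map(mp, bp), "duplicate.*\\(3, 5\\)")
  writeLines(c("0\t99\t5"), mp)
  expect_error(read_contact_map(mp, bp), "out of range")
  writeLines(c("0\t1\t-2"), mp)
  expect_error(read_contact_map(mp, bp), "negative")
})

test_that("an empty entry list is a valid all-zero map", {
  bins <- bin_table(c(chr1 = 5e5), 1e5)
  map <- contact_map(bins, integer(0), integer(0), numeric(0))
  expect_equal(sum(as_dense(map)), 0)
})

test_that("duplicate pairs are rejected at construction", {
  bins <- bin_table(c(chr1 = 1e6), 1e5)
  expect_error(contact_map(bins, c(3L, 3L), c(5L, 5L), c(1, 2)),
               "duplicate")
  # (5,3) and (3,5) are the same unordered pair
  expect_error(contact_map(bins, c(3L, 5L), c(5L, 3L), c(1, 2)),
               "duplicate")
})

test_that("statistics are invariant to triplet row order", {
  set.seed(12)
  M <- matrix(rpois(100, 30), 10); M <- M + t(M)
  bins <- bin_table(c(chr1 = 1e6), 1e5)
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  perm <- sample(nrow(ut))
  m1 <- contact_map(bins, ut[, 1] - 1L, ut[, 2] - 1L, M[ut])
  m2 <- contact_map(bins, ut[perm, 1] - 1L, ut[perm, 2] - 1L, M[ut][perm])
  expect_equal(as_dense(m1), as_dense(m2))
  expect_equal(as_dense(ice_balance(m1)), as_dense(ice_balance(m2)))
})

test_that("ICE leaves a doubly-stochastic matrix at its fixed point", {
  # symmetric with constant margins: balancing only applies a global scale
  M <- matrix(1, 4, 4) + diag(4)
  map <- map_from_dense(M)
  bal <- ice_balance(map, mask_quantile = 0)
  w <- bal$weights
  expect_equal(max(w) / min(w), 1, tolerance = 1e-8)
  B <- as_dense(bal)
  expect_equal(B / B[1, 1], M / M[1, 1], tolerance = 1e-8)
})

test_that("ICE matches an independent Sinkhorn iteration on a random 6x6", {
  set.seed(21)
  M <- matrix(runif(36, 1, 10), 6); M <- M + t(M)
  map <- map_from_dense(M)
  bal <- ice_balance(map, tol = 1e-8, max_iter = 2000, mask_quantile = 0)
  expect_true(attr(bal, "converged"))
  B <- as_dense(bal)
  rs <- rowSums(B)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-5)
  w_ref <- sinkhorn_reference(M)
  expect_equal(bal$weights, w_ref, tolerance = 1e-5)
})

test_that("an all-zero row is masked and the remaining rows balance", {
  set.seed(22)
  M <- matrix(runif(49, 1, 5), 7); M <- M + t(M)
  M[4, ] <- 0; M[, 4] <- 0
  map <- map_from_dense(M)
  bal <- ice_balance(map, mask_quantile = 0)
  expect_true(is.na(bal$weights[4]))
  B <- as_dense(bal)
  expect_true(all(is.na(B[4, ])))
  rs <- rowSums(B[-4, -4])
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-5)
})

test_that("balancing is idempotent up to tolerance", {
  set.seed(23)
  M <- matrix(runif(100, 1, 20), 10); M <- M + t(M)
  bal1 <- ice_balance(map_from_dense(M), mask_quantile = 0)
  bal2 <- ice_balance(bal1, mask_quantile = 0)
  expect_equal(max(bal2$weights) / min(bal2$weights), 1, tolerance = 1e-3)
})

test_that("expected-by-distance matches brute-force averaging on a toy", {
  set.seed(31)
  n <- 20
  M <- matrix(runif(n^2, 0, 10), n); M <- M + t(M)
  map <- map_from_dense(M)
  map$weights <- rep(1, n); map$balanced <- TRUE
  prof <- expected_by_distance(map)
  brute <- sapply(1:(n - 1), function(d) {
    v <- c()
    for (i in 1:(n - d)) v <- c(v, M[i, i + d])
    mean(v)
  })
  expect_equal(unname(prof$cis$chr1), brute)
})

test_that("O/E of a map equal to its expectation is 1, and per-distance means are 1", {
  prof_mu <- checkerboard_mu(n = 20)
  M <- prof_mu$mu
  map <- map_from_dense(M)
  map$weights <- rep(1, 20); map$balanced <- TRUE
  oe <- oe_normalize(map)
  D <- as_dense(oe)
  for (d in 1:19) {
    v <- D[cbind(1:(20 - d), (1 + d):20)]
    expect_equal(mean(v), 1, tolerance = 1e-12)
  }
  # identity case: a distance-only matrix gives O/E == 1 everywhere
  Mid <- matrix(0, 20, 20)
  for (d in 1:19) Mid[cbind(1:(20 - d), (1 + d):20)] <- 100 / d
  Mid <- Mid + t(Mid)
  mid <- map_from_dense(Mid)
  mid$weights <- rep(1, 20); mid$balanced <- TRUE
  Doe <- as_dense(oe_normalize(mid))
  off <- abs(row(Doe) - col(Doe)) > 0
  expect_equal(unname(Doe[off]), rep(1, sum(off)), tolerance = 1e-12)
})

test_that("trans O/E divides by the global trans mean", {
  set.seed(33)
  M <- matrix(runif(64, 1, 3), 8); M <- M + t(M)
  map <- map_from_dense(M, chrom_sizes = c(chr1 = 4e5, chr2 = 4e5))
  map$weights <- rep(1, 8); map$balanced <- TRUE
  oe <- oe_normalize(map)
  D <- as_dense(oe)
  tr <- D[1:4, 5:8]
  Mfull <- as_dense(map)
  expect_equal(mean(tr), 1, tolerance = 1e-12)
  expect_equal(tr, Mfull[1:4, 5:8] / mean(Mfull[1:4, 5:8]),
               tolerance = 1e-12)
})

test_that("virtual 4C is flat on a uniform matrix and linear in the anchor", {
  n <- 12
  M <- matrix(5, n, n)
  map <- map_from_dense(M)
  map$weights <- rep(1, n); map$balanced <- TRUE
  tr <- virtual_4c(map, "chr1", 2e5, 3e5)
  expect_equal(unname(tr$score), rep(5, n))
  expect_equal(sum(tr$is_anchor), 1)
  # multi-bin anchor equals the mean of single-bin tracks
  set.seed(41)
  M2 <- matrix(runif(n^2, 1, 9), n); M2 <- M2 + t(M2)
  m2 <- map_from_dense(M2)
  m2$weights <- rep(1, n); m2$balanced <- TRUE
  both <- virtual_4c(m2, "chr1", 2e5, 4e5)
  one <- virtual_4c(m2, "chr1", 2e5, 3e5)
  two <- virtual_4c(m2, "chr1", 3e5, 4e5)
  expect_equal(both$score, (one$score + two$score) / 2)
  expect_error(virtual_4c(m2, "chrX", 0, 1e5), "no bin")
})

test_that("virtual 4C peaks at a planted loop partner", {
  n <- 30
  mu <- checkerboard_mu(n = n)$mu
  mu[5, 25] <- mu[25, 5] <- mu[5, 25] * 10  # planted loop
  map <- map_from_dense(mu)
  map$weights <- rep(1, n); map$balanced <- TRUE
  tr <- virtual_4c(map, "chr1", 4e5, 5e5)  # anchor = bin 5 (0-based 4)
  far <- tr$score[15:n]  # away from the anchor's local decay
  expect_equal(which.max(far) + 14, 25)
})

test_that("masked bins never contribute to downstream statistics", {
  set.seed(51)
  M <- matrix(runif(400, 5, 15), 20); M <- M + t(M)
  M[7, ] <- 0; M[, 7] <- 0
  map <- map_from_dense(M)
  bal <- ice_balance(map, mask_quantile = 0)
  prof <- expected_by_distance(bal)
  # removing the masked bin entirely gives the same expected profile
  keep <- setdiff(1:20, 7)
  map2 <- map_from_dense(M[keep, keep])
  bal2 <- ice_balance(map2, mask_quantile = 0)
  expect_true(is.na(as_dense(bal)[7, 7]))
  expect_equal(masked_bins(bal)[7], TRUE)
  oe <- oe_normalize(bal)
  expect_false(7L %in% (c(oe$i, oe$j) + 1L))
})
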