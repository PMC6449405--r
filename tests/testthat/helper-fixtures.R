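# shared fixture builders: everything is generated in code at test time

# contact map from a dense symmetric matrix on a single-resolution toy genome
map_from_dense <- function(M, chrom_sizes = NULL, resolution = 1e5) {
  n <- nrow(M)
  if (is.null(chrom_sizes))
    chrom_sizes <- c(chr1 = n * resolution)
  bins <- bin_table(chrom_sizes, resolution)
  stopifnot(n_bins(bins) == n)
  ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_map(bins, ut[, 1] - 1L, ut[, 2] - 1L, M[ut])
}

# independent brute-force Sinkhorn scaling (reference for ice_balance):
# alternating row/column normalization run to high precision
sinkhorn_reference <- function(M, iters = 5000, tol = 1e-12) {
  r <- rep(1, nrow(M))
  for (k in seq_len(iters)) {
    s <- as.numeric((M * outer(r, r)) %*% rep(1, nrow(M)))
    r_new <- r / sqrt(s / mean(s))
    if (max(abs(s / mean(s) - 1)) < tol) break
    r <- r_new
  }
  s <- as.numeric((M * outer(r, r)) %*% rep(1, nrow(M)))
  r / sqrt(mean(s))  # weights scaling rows to sum 1
}

# a clean 2-compartment checkerboard expectation matrix (single chromosome)
checkerboard_mu <- function(n = 30, block = 5, base = 100, alpha = 1,
                            strength = 2) {
  lab <- ifelse(((seq_len(n) - 1) %/% block) %% 2 == 0, 1, -1)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  dc <- D; dc[dc == 0] <- 1
  mu <- base * dc^(-alpha)
  mu[D == 0] <- base * 4
  same <- outer(lab, lab, "==")
  mu[same] <- mu[same] * strength
  list(mu = mu, lab = lab)
}

# spot-table row builder for hand-constructed FISH cells
spot_rows <- function(cell_id, channel, coords, volume = 500,
                      periphery = 1) {
  do.call(rbind, lapply(seq_len(nrow(coords)), function(k)
    data.frame(cell_id = cell_id, channel = channel,
               x = coords[k, 1], y = coords[k, 2], z = coords[k, 3],
               nucleus_volume = volume, periphery_distance = periphery,
               stringsAsFactors = FALSE)))
}
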