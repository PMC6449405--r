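#' ICE matrix balancing
#'
#' Iterative correction of a raw contact map: finds per-bin multiplicative
#' weights so that every unmasked row of the balanced matrix
#' `balanced(i,j) = w_i * w_j * raw(i,j)` sums to 1. Bins with a zero
#' marginal, and bins in the lowest `mask_quantile` fraction of non-zero
#' marginals, are masked before iterating (low-coverage bins destabilize the
#' correction and carry no usable signal).
#'
#' @param map a raw `contact_map`.
#' @param tol convergence tolerance: maximum relative deviation of unmasked
#'   row sums from their mean.
#' @param max_iter iteration cap; non-convergence raises a warning and sets
#'   the `converged` attribute to `FALSE`.
#' @param mask_quantile fraction of lowest non-zero marginals to mask
#'   (default 0.02).
#' @return a balanced `contact_map` (values include the weights) with
#'   per-bin `weights`, and attributes `converged` and `iterations`.
#' @export
ice_balance <- function(map, tol = 1e-5, max_iter = 200, mask_quantile = 0.02) {
  M <- as_dense(map, apply_mask = FALSE)
  nb <- nrow(M)
  marg <- rowSums(M)
  mask <- marg == 0
  nz_idx <- which(!mask)
  n_mask <- floor(mask_quantile * length(nz_idx))
  if (n_mask > 0) {
    low <- nz_idx[order(marg[nz_idx])][seq_len(n_mask)]
    mask[low] <- TRUE
  }
  keep <- which(!mask)
  if (length(keep) == 0L) stop("all bins masked; nothing to balance")
  A <- M[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  converged <- FALSE
  it <- 0L
  # row sums of A / (b_i b_j) via a matrix-vector product
  marg <- function(b) as.numeric(A %*% (1 / b)) / b
  while (it < max_iter) {
    it <- it + 1L
    s <- marg(b)
    ds <- s / mean(s)
    if (max(abs(ds - 1)) < tol) { converged <- TRUE; break }
    # sqrt-damped symmetric update: the undamped rescaling oscillates
    # between two bias sequences on symmetric matrices
    b <- b * sqrt(ds)
  }
  s <- marg(b)
  # final global scale: unmasked rows sum to 1
  b <- b * sqrt(mean(s))
  if (!converged)
    warning(sprintf("ICE did not converge in %d iterations (max dev %.3g)",
                    max_iter, max(abs(s / mean(s) - 1))))
  w <- rep(NA_real_, nb)
  w[keep] <- 1 / b
  B <- M * w * rep(w, each = nb)
  out <- dense_to_map(B, map$bins, weights = w, balanced = TRUE,
                      normalization = "balanced")
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Expected contact value by genomic distance
#'
#' For each chromosome, the mean balanced contact value at each bin
#' separation (diagonal excluded), averaged over all unmasked pairs
#' including zero entries; plus a single scalar mean over all unmasked
#' inter-chromosomal pairs.
#'
#' @param map a balanced `contact_map`.
#' @return an `expected_profile`: list with `cis` (named list of per-chrom
#'   numeric vectors indexed by distance in bins) and `trans` (scalar).
#' @export
expected_by_distance <- function(map) {
  mask <- masked_bins(map)
  M <- as_dense(map, apply_mask = TRUE)
  by_ch <- bins_by_chrom(map$bins)
  cis <- lapply(by_ch, function(ids) {
    idx <- ids + 1L
    sub <- M[idx, idx, drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) return(numeric(0))
    vapply(seq_len(n - 1L), function(d) {
      v <- sub[cbind(seq_len(n - d), seq_len(n - d) + d)]
      mean(v, na.rm = TRUE)
    }, numeric(1))
  })
  # trans: mean over unmasked inter-chromosomal pairs
  ch_of <- map$bins$chrom
  tsum <- 0; tn <- 0
  chs <- unique(ch_of)
  if (length(chs) > 1L) {
    for (a in seq_along(chs)[-length(chs)]) for (b in (a + 1L):length(chs)) {
      ia <- which(ch_of == chs[a] & !mask); ib <- which(ch_of == chs[b] & !mask)
      if (length(ia) && length(ib)) {
        blk <- M[ia, ib, drop = FALSE]
        tsum <- tsum + sum(blk); tn <- tn + length(blk)
      }
    }
  }
  structure(list(cis = cis, trans = if (tn > 0) tsum / tn else NA_real_),
            class = "expected_profile")
}

#' Observed/expected normalization
#'
#' Divides each cis contact by the expected value at its distance and each
#' trans contact by the global trans mean. Cis pairs at a distance whose
#' expected value is zero (with observations) are masked from the output and
#' counted in the `dropped_pairs` attribute. The per-distance mean of the
#' output is 1 over unmasked pairs by construction.
#'
#' @param map a balanced `contact_map`.
#' @param profile an `expected_profile` from [expected_by_distance()];
#'   recomputed from `map` if omitted.
#' @return a `contact_map` with `normalization = "oe"`.
#' @export
oe_normalize <- function(map, profile = NULL) {
  if (is.null(profile)) profile <- expected_by_distance(map)
  ch_of <- map$bins$chrom
  ci <- ch_of[map$i + 1L]; cj <- ch_of[map$j + 1L]
  x <- map$x
  dropped <- 0L
  cis <- ci == cj
  if (any(cis)) {
    d <- abs(map$j - map$i)
    for (ch in names(profile$cis)) {
      sel <- which(cis & ci == ch & d > 0L)
      if (!length(sel)) next
      e <- profile$cis[[ch]][d[sel]]
      zero <- !is.na(e) & e == 0
      x[sel] <- ifelse(zero, NA, x[sel] / e)
      dropped <- dropped + sum(zero & map$x[sel] > 0)
    }
    x[cis & d == 0L] <- NA  # diagonal excluded from O/E
  }
  if (any(!cis)) x[!cis] <- map$x[!cis] / profile$trans
  keep <- !is.na(x)
  out <- contact_map(map$bins, map$i[keep], map$j[keep], x[keep],
                     weights = map$weights, balanced = TRUE,
                     normalization = "oe")
  attr(out, "dropped_pairs") <- dropped
  out
}

#' Virtual 4C track
#'
#' Extracts the mean balanced contact between an anchor region's bin(s) and
#' every other bin, i.e. the anchor row(s) of the matrix, as a per-bin track
#' suitable for bedGraph output. A multi-bin anchor yields the mean of the
#' single-bin tracks.
#'
#' @param map a balanced `contact_map`.
#' @param anchor_chrom,anchor_start,anchor_end anchor interval (bp, 0-based
#'   half-open).
#' @return data.frame `chrom, start, end, score, is_anchor`; masked bins get
#'   `NA` scores.
#' @export
virtual_4c <- function(map, anchor_chrom, anchor_start, anchor_end) {
  bins <- map$bins
  sel <- which(bins$chrom == anchor_chrom & bins$start < anchor_end &
                 bins$end > anchor_start)
  if (length(sel) == 0L)
    stop("anchor region maps to no bin in the assembly")
  M <- as_dense(map, apply_mask = TRUE)
  score <- colMeans(M[sel, , drop = FALSE])
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             score = score,
             is_anchor = seq_len(nrow(bins)) %in% sel,
             stringsAsFactors = FALSE)
}
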