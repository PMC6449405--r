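#' A/B compartment score (PC1) from a balanced contact map
#'
#' Per chromosome: the cis observed/expected matrix is turned into a Pearson
#' correlation matrix over unmasked bins and its leading eigenvector taken
#' as the compartment score, scaled by the square root of the leading
#' eigenvalue. The matrix diagonal is excluded from O/E and replaced by
#' each column's off-diagonal mean before the correlation. The eigenvector sign is arbitrary, so each chromosome is
#' oriented to correlate positively with `orientation` (typically gene
#' density or an active-chromatin proxy); positive scores are then the A
#' compartment, negative the B compartment.
#'
#' Bins with zero variance across the correlation rows are masked;
#' chromosomes with fewer than `min_bins` unmasked bins are skipped with a
#' warning.
#'
#' @param map a balanced `contact_map` (compartment-scale resolution,
#'   typically 500 kb).
#' @param orientation numeric per-bin reference track used only to fix the
#'   per-chromosome sign.
#' @param min_bins minimum unmasked bins per chromosome (default 10).
#' @return a `compartment_track`: data.frame `chrom, start, end, bin_id,
#'   score` with `NA` scores on masked/skipped bins.
#' @export
compute_pc1 <- function(map, orientation, min_bins = 10) {
  bins <- map$bins
  stopifnot(length(orientation) == n_bins(bins))
  oe <- oe_normalize(map)
  M <- as_dense(oe, apply_mask = TRUE)
  score <- rep(NA_real_, n_bins(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    sub <- M[idx, idx, drop = FALSE]
    diag(sub) <- NA
    ok <- which(colSums(!is.na(sub)) > 1)
    if (length(ok) < min_bins) {
      warning(sprintf("chromosome %s: fewer than %d usable bins, skipped",
                      ch, min_bins))
      next
    }
    sub <- sub[ok, ok, drop = FALSE]
    # zero-variance bins cannot enter a correlation matrix
    v <- apply(sub, 2, stats::var, na.rm = TRUE)
    ok2 <- which(is.finite(v) & v > 0)
    if (length(ok2) < min_bins) {
      warning(sprintf("chromosome %s: fewer than %d variable bins, skipped",
                      ch, min_bins))
      next
    }
    sub <- sub[ok2, ok2, drop = FALSE]
    # the diagonal is excluded from O/E; impute it with each column's
    # off-diagonal mean so a dense (BLAS) correlation can be used
    cmn <- colMeans(sub, na.rm = TRUE)
    diag(sub) <- cmn
    C <- suppressWarnings(stats::cor(sub))
    C[!is.finite(C)] <- 0
    eg <- eigen(C, symmetric = TRUE)
    v1 <- eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
    keep <- idx[ok][ok2]
    if (sum(v1 * orientation[keep], na.rm = TRUE) < 0) v1 <- -v1
    score[keep] <- v1
  }
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    bin_id = bins$bin_id, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Fraction of the genome in each compartment
#'
#' @param score replicate-averaged per-bin PC1 scores (`NA` = masked).
#' @return named vector `c(A = ..., B = ...)` over unmasked bins; A is
#'   `score > 0`, B is `score <= 0`.
#' @export
compartment_fraction <- function(score) {
  if (inherits(score, "compartment_track")) score <- score$score
  s <- score[!is.na(score)]
  if (!length(s)) return(c(A = NA_real_, B = NA_real_))
  c(A = mean(s > 0), B = mean(s <= 0))
}

# sign sequence of time-point means with zeros inheriting the previous sign
# (leading zeros inherit the first non-zero sign: tie toward no transition)
sign_sequence <- function(means) {
  s <- sign(means)
  nz <- which(s != 0)
  if (!length(nz)) return(integer(0))
  s[seq_len(nz[1] - 1)] <- s[nz[1]]
  for (k in seq_along(s)[-1]) if (s[k] == 0) s[k] <- s[k - 1]
  s[c(TRUE, diff(s) != 0)]
}

category_from_signs <- function(sq) {
  lab <- function(v) paste(ifelse(v > 0, "A", "B"), collapse = "-")
  if (length(sq) == 0L) return(NA_character_)
  if (length(sq) == 1L) return(if (sq > 0) "stable-A" else "stable-B")
  # 4-segment oscillations are merged into the 2-segment category given by
  # their first and last sign
  if (length(sq) >= 4L) sq <- c(sq[1], sq[length(sq)])
  lab(sq)
}

#' Classify compartment switching across a time course
#'
#' Per bin, a one-way ANOVA F-test of PC1 scores across time points (with
#' replicates as within-group observations). A bin switches when the ANOVA
#' p-value is below `alpha` AND at least one time-point mean is positive and
#' one negative. The category is the sign sequence of time-point means with
#' consecutive duplicates collapsed (`A-B`, `B-A`, `A-B-A`, `B-A-B`);
#' 4-segment oscillations are merged into `A-B`/`B-A` by their first and
#' last sign. Non-switching bins are `stable-A`/`stable-B` by the sign of
#' their grand mean. Bins whose values are identical across all samples get
#' p = 1 (no evidence of change). Bins with any missing replicate value are
#' excluded and counted in the `excluded` attribute.
#'
#' @param scores numeric matrix, bins x samples, of PC1 scores.
#' @param timepoint factor/vector of length `ncol(scores)` giving each
#'   sample's time point (>= 2 levels).
#' @param replicate vector of replicate labels (>= 2 per time point).
#' @param alpha switching significance threshold (default 0.05).
#' @param bins optional `bin_table` to carry coordinates into the result.
#' @return a `switch_calls` data.frame: `bin_id`, `category`, `anova_p`,
#'   one `mean_<tp>` column per time point.
#' @export
classify_switches <- function(scores, timepoint, replicate, alpha = 0.05,
                              bins = NULL) {
  scores <- as.matrix(scores)
  tp <- factor(timepoint, levels = unique(timepoint))
  if (nlevels(tp) < 2L) stop("need at least two time points")
  if (any(table(tp) < 2L)) stop("need at least two replicates per time point")
  Tn <- nlevels(tp)
  n <- ncol(scores)
  complete <- rowSums(is.na(scores)) == 0L
  grp <- split(seq_len(n), tp)
  gm <- sapply(grp, function(ix) rowMeans(scores[, ix, drop = FALSE]))
  gm <- matrix(gm, nrow = nrow(scores),
               dimnames = list(NULL, levels(tp)))
  grand <- rowMeans(scores)
  # closed-form one-way ANOVA, vectorized over bins
  ssb <- rowSums(sapply(seq_along(grp), function(k)
    length(grp[[k]]) * (gm[, k] - grand)^2))
  ssw <- rowSums(sapply(seq_along(grp), function(k) {
    ix <- grp[[k]]
    rowSums((scores[, ix, drop = FALSE] - gm[, k])^2)
  }))
  df1 <- Tn - 1L; df2 <- n - Tn
  Fst <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  p[!is.finite(Fst) | ssw == 0] <- 1  # zero within-variance: no evidence
  p[ssb == 0] <- 1
  has_sign_change <- apply(gm, 1, function(m) any(m > 0) && any(m < 0))
  switching <- complete & p < alpha & has_sign_change
  category <- character(nrow(scores))
  for (b in seq_len(nrow(scores))) {
    if (!complete[b]) { category[b] <- NA_character_; next }
    if (switching[b]) {
      category[b] <- category_from_signs(sign_sequence(gm[b, ]))
      # a significant bin whose zero-inheritance collapses to one segment is
      # stable after all
      if (category[b] %in% c("stable-A", "stable-B")) switching[b] <- FALSE
    } else {
      category[b] <- if (grand[b] > 0) "stable-A" else "stable-B"
    }
  }
  out <- data.frame(bin_id = if (!is.null(bins)) bins$bin_id else
                      seq_len(nrow(scores)) - 1L,
                    category = category, anova_p = p,
                    switching = switching,
                    stringsAsFactors = FALSE)
  colnames(gm) <- paste0("mean_", levels(tp))
  out <- cbind(out, gm)
  if (!is.null(bins))
    out <- cbind(bins[, c("chrom", "start", "end")], out)
  attr(out, "excluded") <- sum(!complete)
  class(out) <- c("switch_calls", "data.frame")
  out
}

#' @export
summary.switch_calls <- function(object, ...) {
  ok <- !is.na(object$category)
  cat(sprintf("switch calls: %d bins (%d excluded)\n", sum(ok),
              attr(object, "excluded")))
  cat(sprintf("  switching fraction: %.3f\n", mean(object$switching[ok])))
  print(table(object$category[ok]))
  invisible(object)
}

#' Saddle matrix of compartmentalization strength
#'
#' Bins are assigned to `n_quantiles` quantile groups (deciles by default)
#' of the PC1 track, ordered from most-B to most-A; each unmasked bin pair
#' contributes its O/E value to its quantile-pair cell, and the cell stores
#' the log2 of the mean. Strong compartmentalization shows as high corner
#' cells (B-B and A-A) relative to the off-corner cells.
#'
#' @param oe_map an O/E-normalized `contact_map` (see [oe_normalize()]).
#' @param track per-bin PC1 scores (`compartment_track` or numeric).
#' @param n_quantiles number of quantile groups (default 10).
#' @param domain `"cis"` (intra-chromosomal, diagonal excluded) or
#'   `"trans"`.
#' @return a `saddle_matrix`: `n_quantiles x n_quantiles` numeric matrix
#'   (log2 mean O/E; empty cells `NA`) with attributes `edges` and
#'   `domain`.
#' @export
saddle <- function(oe_map, track, n_quantiles = 10,
                   domain = c("cis", "trans")) {
  domain <- match.arg(domain)
  if (inherits(track, "compartment_track")) track <- track$score
  bins <- oe_map$bins
  stopifnot(length(track) == n_bins(bins))
  usable <- !is.na(track) & !masked_bins(oe_map)
  edges <- stats::quantile(track[usable], probs = seq(0, 1, length.out =
                                                        n_quantiles + 1))
  q <- rep(NA_integer_, n_bins(bins))
  q[usable] <- cut(track[usable], breaks = unique(edges),
                   include.lowest = TRUE, labels = FALSE)
  # with duplicate edges cut() yields fewer groups; map back to 1..n
  M <- as_dense(oe_map, apply_mask = TRUE)
  ch <- bins$chrom
  ut <- which(upper.tri(M), arr.ind = TRUE)  # diagonal excluded
  a <- ut[, 1]; b <- ut[, 2]
  same <- ch[a] == ch[b]
  keep <- if (domain == "cis") same else !same
  a <- a[keep]; b <- b[keep]
  v <- M[cbind(a, b)]
  qa <- q[a]; qb <- q[b]
  ok <- !is.na(v) & !is.na(qa) & !is.na(qb)
  lo <- pmin(qa[ok], qb[ok]); hi <- pmax(qa[ok], qb[ok])
  cell <- factor((lo - 1L) * n_quantiles + hi,
                 levels = seq_len(n_quantiles^2))
  sums_v <- as.numeric(tapply(v[ok], cell, sum))
  cnts_v <- as.numeric(table(cell))
  sums <- matrix(0, n_quantiles, n_quantiles)
  cnts <- matrix(0, n_quantiles, n_quantiles)
  # cell index k encodes (lo, hi) as (k-1) %/% n and (k-1) %% n
  idx_lo <- ((seq_len(n_quantiles^2) - 1L) %/% n_quantiles) + 1L
  idx_hi <- ((seq_len(n_quantiles^2) - 1L) %% n_quantiles) + 1L
  sums[cbind(idx_lo, idx_hi)] <- ifelse(is.na(sums_v), 0, sums_v)
  cnts[cbind(idx_lo, idx_hi)] <- cnts_v
  sums <- sums + t(sums) - diag(diag(sums))
  cnts <- cnts + t(cnts) - diag(diag(cnts))
  grid <- ifelse(cnts > 0, log2(sums / cnts), NA)
  structure(grid, edges = edges, domain = domain, counts = cnts,
            class = c("saddle_matrix", class(grid)))
}

#' Difference between two saddle matrices
#'
#' The change in compartmentalization between two samples as the difference
#' of their log2 saddle grids (late minus early).
#'
#' @param s_late,s_early `saddle_matrix` objects on the same grid.
#' @return numeric matrix of per-cell differences.
#' @export
delta_saddle <- function(s_late, s_early) {
  stopifnot(all(dim(s_late) == dim(s_early)))
  unclass(s_late) - unclass(s_early)
}

#' Compartment-stratified distance-decay curves
#'
#' Cis contacts are classed A-A, B-B or A-B by the compartment sign of their
#' two bins; at each distance, the class mean balanced contact is divided by
#' the mean over all pairs at that distance. The pair-count-weighted mean of
#' the class values is therefore 1 at every distance.
#'
#' @param map a balanced `contact_map`.
#' @param track per-bin PC1 scores giving the A/B assignment (sign).
#' @param min_pairs distances where a class has fewer pairs than this are
#'   reported as `NA` (default 20).
#' @return data.frame `distance` (bp), `class`, `value`, `n_pairs`.
#' @export
decay_curves <- function(map, track, min_pairs = 20) {
  if (inherits(track, "compartment_track")) track <- track$score
  bins <- map$bins
  res <- attr(bins, "resolution")
  M <- as_dense(map, apply_mask = TRUE)
  lab <- ifelse(is.na(track), NA, ifelse(track > 0, "A", "B"))
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    n <- length(idx)
    if (n < 2L) next
    sub <- M[idx, idx, drop = FALSE]
    l <- lab[idx]
    for (d in seq_len(n - 1L)) {
      ii <- seq_len(n - d)
      v <- sub[cbind(ii, ii + d)]
      cl <- ifelse(is.na(l[ii]) | is.na(l[ii + d]), NA,
                   ifelse(l[ii] == l[ii + d],
                          ifelse(l[ii] == "A", "A-A", "B-B"), "A-B"))
      ok <- !is.na(v) & !is.na(cl)
      if (!any(ok)) next
      key <- paste0(ch, "@", d)
      out[[key]] <- data.frame(chrom = ch, distance = d * res,
                               class = cl[ok], value = v[ok],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(distance = numeric(0), class = character(0),
                      value = numeric(0), n_pairs = integer(0)))
  df <- do.call(rbind, out)
  # pool chromosomes at each distance
  agg <- stats::aggregate(value ~ distance + class, df, function(x)
    c(sum = sum(x), n = length(x)))
  agg <- data.frame(distance = agg$distance, class = agg$class,
                    sum = agg$value[, "sum"], n_pairs = agg$value[, "n"])
  tot <- stats::aggregate(cbind(sum, n_pairs) ~ distance, agg, sum)
  tot$mean_all <- tot$sum / tot$n_pairs
  agg <- merge(agg, tot[, c("distance", "mean_all")], by = "distance")
  agg$value <- ifelse(agg$mean_all > 0,
                      (agg$sum / agg$n_pairs) / agg$mean_all, NA)
  agg$value[agg$n_pairs < min_pairs] <- NA
  agg[order(agg$distance, agg$class),
      c("distance", "class", "value", "n_pairs")]
}
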