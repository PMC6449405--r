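#' Directionality index track
#'
#' For each bin, `A` is the sum of balanced contacts to bins within `window`
#' upstream and `B` the same downstream. With `E = (A + B) / 2`, the
#' directionality index is
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`:
#' zero when contacts are balanced, strongly positive at domain starts
#' (downstream bias) and strongly negative at domain ends. Bins within
#' `window` of a chromosome end are computed from the truncated window and
#' flagged `edge`.
#'
#' @param map a balanced `contact_map` at TAD-scale resolution (40 kb).
#' @param window one-sided window in bp (default 2 Mb).
#' @return data.frame `chrom, start, end, bin_id, A, B, di, edge`.
#' @export
directionality_index <- function(map, window = 2e6) {
  bins <- map$bins
  res <- attr(bins, "resolution")
  w <- max(1L, as.integer(round(window / res)))
  M <- as_dense(map, apply_mask = TRUE)
  out <- vector("list", length(unique(bins$chrom)))
  names(out) <- unique(bins$chrom)
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    n <- length(idx)
    if (n <= w) {
      warning(sprintf("chromosome %s shorter than the DI window, skipped", ch))
      next
    }
    sub <- M[idx, idx, drop = FALSE]
    A <- B <- di <- rep(NA_real_, n)
    edge <- seq_len(n) <= w | seq_len(n) > n - w
    for (k in seq_len(n)) {
      up <- sub[k, max(1L, k - w):max(1L, k - 1L)]
      dn <- sub[k, min(n, k + 1L):min(n, k + w)]
      if (k == 1L) up <- numeric(0)
      if (k == n) dn <- numeric(0)
      a <- sum(up, na.rm = TRUE); b <- sum(dn, na.rm = TRUE)
      A[k] <- a; B[k] <- b
      e <- (a + b) / 2
      di[k] <- if (e == 0) 0 else
        sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
    }
    out[[ch]] <- data.frame(chrom = ch, start = bins$start[idx],
                            end = bins$end[idx], bin_id = bins$bin_id[idx],
                            A = A, B = B, di = di, edge = edge,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' TAD segmentation from a directionality index track
#'
#' Deterministic run-length segmentation: a domain opens at the start of a
#' stretch with `di >= pos_thresh` (downstream-biased) and closes at the end
#' of the next stretch with `di <= neg_thresh` (upstream-biased). Boundaries
#' are the domain edges. Thresholds default to the 0.9 / 0.1 quantiles of
#' the track.
#'
#' @param di_track output of [directionality_index()].
#' @param pos_thresh,neg_thresh numeric thresholds; `NULL` uses the track
#'   quantiles `pos_q` / `neg_q`.
#' @param pos_q,neg_q quantiles used when thresholds are not given.
#' @return list with `tads` (data.frame `chrom, start, end`) and
#'   `boundaries` (a `boundary_set` data.frame `chrom, start, end, pos`
#'   where `pos` is the boundary bin start).
#' @export
di_domains <- function(di_track, pos_thresh = NULL, neg_thresh = NULL,
                       pos_q = 0.9, neg_q = 0.1) {
  di <- di_track$di
  if (is.null(pos_thresh))
    pos_thresh <- stats::quantile(di, pos_q, na.rm = TRUE, names = FALSE)
  if (is.null(neg_thresh))
    neg_thresh <- stats::quantile(di, neg_q, na.rm = TRUE, names = FALSE)
  tads <- list()
  for (ch in unique(di_track$chrom)) {
    d <- di_track[di_track$chrom == ch, ]
    state <- ifelse(is.na(d$di), 0L,
                    ifelse(d$di >= pos_thresh, 1L,
                           ifelse(d$di <= neg_thresh, -1L, 0L)))
    open_at <- NA_integer_
    k <- 1L
    n <- nrow(d)
    while (k <= n) {
      if (state[k] == 1L && is.na(open_at)) {
        open_at <- k
      } else if (state[k] == -1L && !is.na(open_at)) {
        # extend through the full upstream-biased stretch
        while (k < n && state[k + 1L] == -1L) k <- k + 1L
        tads[[length(tads) + 1L]] <-
          data.frame(chrom = ch, start = d$start[open_at], end = d$end[k],
                     stringsAsFactors = FALSE)
        open_at <- NA_integer_
      }
      k <- k + 1L
    }
  }
  tads <- if (length(tads)) do.call(rbind, tads) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  boundaries <- tad_boundaries(tads)
  list(tads = tads, boundaries = boundaries,
       pos_thresh = pos_thresh, neg_thresh = neg_thresh)
}

#' Boundaries (edges) of a TAD set
#' @param tads data.frame `chrom, start, end`.
#' @return a `boundary_set` data.frame `chrom, pos`, sorted and unique.
#' @export
tad_boundaries <- function(tads) {
  if (!nrow(tads))
    return(structure(data.frame(chrom = character(0), pos = numeric(0)),
                     class = c("boundary_set", "data.frame")))
  b <- rbind(data.frame(chrom = tads$chrom, pos = tads$start),
             data.frame(chrom = tads$chrom, pos = tads$end))
  b <- unique(b[order(b$chrom, b$pos), ])
  rownames(b) <- NULL
  class(b) <- c("boundary_set", "data.frame")
  b
}

#' Insulation score track
#'
#' Mean contact in a `square` x `square` window sliding along the diagonal
#' (upstream rows x downstream columns of each bin), log2-normalized to the
#' chromosome-wide mean of that statistic. Defined only where the full
#' square fits; `NA` near chromosome ends.
#'
#' @param map a balanced `contact_map` at 40 kb resolution.
#' @param square side of the sliding square in bp (default 500 kb).
#' @return data.frame `chrom, start, end, bin_id, insulation`.
#' @export
insulation_score <- function(map, square = 5e5) {
  bins <- map$bins
  res <- attr(bins, "resolution")
  w <- max(1L, as.integer(round(square / res)))
  M <- as_dense(map, apply_mask = TRUE)
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    n <- length(idx)
    sub <- M[idx, idx, drop = FALSE]
    raw <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      if (k - w < 1L || k + w > n) next
      block <- sub[(k - w):(k - 1L), (k + 1L):(k + w), drop = FALSE]
      raw[k] <- mean(block, na.rm = TRUE)
    }
    m <- mean(raw, na.rm = TRUE)
    ins <- if (is.finite(m) && m > 0) log2(raw / m) else rep(NA_real_, n)
    out[[ch]] <- data.frame(chrom = ch, start = bins$start[idx],
                            end = bins$end[idx], bin_id = bins$bin_id[idx],
                            insulation = ins, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score whose strength --
#' the smaller of the drops from the two nearest flanking local maxima to
#' the minimum -- is at least `min_strength`. Raising `min_strength` can
#' only remove boundaries.
#'
#' @param track output of [insulation_score()].
#' @param min_strength minimum boundary strength in log2 units (default
#'   0.1).
#' @return a `boundary_set` data.frame `chrom, pos, strength`.
#' @export
insulation_boundaries <- function(track, min_strength = 0.1) {
  out <- list()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, ]
    v <- d$insulation
    ok <- which(!is.na(v))
    if (length(ok) < 3L) next
    vv <- v[ok]
    n <- length(vv)
    is_min <- c(FALSE, vv[2:(n - 1)] < vv[1:(n - 2)] &
                  vv[2:(n - 1)] < vv[3:n], FALSE)
    is_max <- c(TRUE, vv[2:(n - 1)] > vv[1:(n - 2)] &
                  vv[2:(n - 1)] > vv[3:n], TRUE)
    mins <- which(is_min); maxs <- which(is_max)
    for (k in mins) {
      left <- maxs[maxs < k]; right <- maxs[maxs > k]
      if (!length(left) || !length(right)) next
      strength <- min(vv[max(left)] - vv[k], vv[min(right)] - vv[k])
      if (strength >= min_strength)
        out[[length(out) + 1L]] <-
          data.frame(chrom = ch, pos = d$start[ok[k]], strength = strength,
                     stringsAsFactors = FALSE)
    }
  }
  b <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0),
               strength = numeric(0))
  class(b) <- c("boundary_set", "data.frame")
  b
}

#' Compare two boundary sets
#'
#' Greedy one-to-one nearest matching: candidate cross-set pairs within
#' `tolerance` are matched closest-first, each boundary used at most once.
#' `jaccard = shared / union` where `union = nA + nB - shared`.
#'
#' @param set_a,set_b `boundary_set` data.frames (`chrom`, `pos`).
#' @param tolerance maximum distance in bp for two boundaries to be the
#'   same (e.g. 8e4 between replicates, 2e5 between time points).
#' @return list `shared`, `a_specific`, `b_specific` (data.frames),
#'   `n_shared`, `jaccard`.
#' @export
compare_boundaries <- function(set_a, set_b, tolerance) {
  pairs <- list()
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    ia <- which(set_a$chrom == ch); ib <- which(set_b$chrom == ch)
    dmat <- abs(outer(set_a$pos[ia], set_b$pos[ib], "-"))
    hit <- which(dmat <= tolerance, arr.ind = TRUE)
    if (nrow(hit))
      pairs[[ch]] <- data.frame(a = ia[hit[, 1]], b = ib[hit[, 2]],
                                d = dmat[hit])
  }
  used_a <- logical(nrow(set_a)); used_b <- logical(nrow(set_b))
  n_shared <- 0L
  matched_a <- integer(0)
  if (length(pairs)) {
    cand <- do.call(rbind, pairs)
    cand <- cand[order(cand$d), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; b <- cand$b[k]
      if (used_a[a] || used_b[b]) next
      used_a[a] <- TRUE; used_b[b] <- TRUE
      n_shared <- n_shared + 1L
      matched_a <- c(matched_a, a)
    }
  }
  union_n <- nrow(set_a) + nrow(set_b) - n_shared
  list(shared = set_a[used_a, , drop = FALSE],
       a_specific = set_a[!used_a, , drop = FALSE],
       b_specific = set_b[!used_b, , drop = FALSE],
       n_shared = n_shared,
       jaccard = if (union_n > 0) n_shared / union_n else NA_real_)
}

#' Assign TADs to compartment-dynamics categories
#'
#' Each TAD takes the category of the switch calls covering the majority of
#' its span (the 51\% majority rule; if no category reaches 51\%, for
#' instance when a TAD spans a category boundary, the plurality category is
#' used). TADs entirely in masked bins are `NA`.
#'
#' @param tads data.frame `chrom, start, end` (40 kb scale).
#' @param switch_calls a `switch_calls` data.frame with `chrom, start, end,
#'   category` (500 kb scale).
#' @return `tads` with an added `category` column.
#' @export
tad_compartment_assignment <- function(tads, switch_calls) {
  gr_t <- GenomicRanges::GRanges(tads$chrom,
                                 IRanges::IRanges(tads$start + 1, tads$end))
  ok <- !is.na(switch_calls$category)
  sc <- switch_calls[ok, ]
  gr_s <- GenomicRanges::GRanges(sc$chrom,
                                 IRanges::IRanges(sc$start + 1, sc$end))
  hits <- GenomicRanges::findOverlaps(gr_t, gr_s)
  cat_out <- rep(NA_character_, nrow(tads))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(gr_t[S4Vectors::queryHits(hits)],
                                    gr_s[S4Vectors::subjectHits(hits)])
    wdf <- data.frame(tad = S4Vectors::queryHits(hits),
                      category = sc$category[S4Vectors::subjectHits(hits)],
                      w = BiocGenerics::width(ov))
    for (t in unique(wdf$tad)) {
      sub <- wdf[wdf$tad == t, ]
      tot <- tapply(sub$w, sub$category, sum)
      cat_out[t] <- names(tot)[which.max(tot)]
    }
  }
  tads$category <- cat_out
  tads
}

#' Enrichment of boundary classes in compartment-dynamics categories
#'
#' For each boundary class (e.g. gained / lost / shared), boundaries are
#' assigned to the compartment category of their covering 500 kb bin, and
#' the class distribution over categories is compared with the union set's
#' distribution: `log2(class share / union share)` per category, with a
#' chi-squared test of the class counts against expected counts
#' proportional to the union distribution.
#'
#' @param boundary_classes named list of `boundary_set` data.frames.
#' @param switch_calls `switch_calls` with coordinates.
#' @param union_set the union `boundary_set` used as background; defaults
#'   to the row-bind of `boundary_classes`.
#' @return an `enrichment_result` data.frame (see [category_enrichment()]).
#' @export
boundary_category_enrichment <- function(boundary_classes, switch_calls,
                                         union_set = NULL) {
  if (is.null(union_set))
    union_set <- do.call(rbind, lapply(boundary_classes, function(b)
      b[, c("chrom", "pos")]))
  assign_cat <- function(b) {
    g <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$pos + 1, b$pos + 1))
    ok <- !is.na(switch_calls$category)
    sc <- switch_calls[ok, ]
    s <- GenomicRanges::GRanges(sc$chrom,
                                IRanges::IRanges(sc$start + 1, sc$end))
    hits <- GenomicRanges::findOverlaps(g, s, select = "first")
    sc$category[hits]
  }
  feats <- lapply(boundary_classes, assign_cat)
  bg <- assign_cat(union_set)
  res <- lapply(names(feats), function(cl)
    cbind(class = cl, enrichment_table(feats[[cl]], bg)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Expression change of the gene nearest each boundary
#'
#' For each boundary the nearest TSS (by absolute distance) is found and
#' the gene's `log2((fpkm_late + pseudocount) / (fpkm_early + pseudocount))`
#' recorded; each boundary class is then tested against 0 with a one-sample
#' two-sided t-test.
#'
#' @param boundary_classes named list of `boundary_set` data.frames.
#' @param genes data.frame `gene_id, chrom, tss`.
#' @param fpkm_early,fpkm_late named numeric vectors of FPKM per gene.
#' @param pseudocount added to both FPKM values (default 0.1).
#' @return list per class: `log2fc` vector, `t`, `p`, `n`; boundaries on
#'   chromosomes without genes are dropped.
#' @export
nearest_gene_expression_change <- function(boundary_classes, genes,
                                           fpkm_early, fpkm_late,
                                           pseudocount = 0.1) {
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tss + 1, genes$tss + 1))
  lapply(boundary_classes, function(b) {
    if (!nrow(b)) return(list(log2fc = numeric(0), t = NA, p = NA, n = 0L))
    gr_b <- GenomicRanges::GRanges(b$chrom,
                                   IRanges::IRanges(b$pos + 1, b$pos + 1))
    near <- GenomicRanges::nearest(gr_b, gr_g)
    keep <- !is.na(near)
    g <- genes$gene_id[near[keep]]
    fc <- log2((fpkm_late[g] + pseudocount) /
                 (fpkm_early[g] + pseudocount))
    fc <- as.numeric(fc)
    if (length(fc) >= 2 && stats::sd(fc) > 0) {
      tt <- stats::t.test(fc, mu = 0)
      tval <- unname(tt$statistic); pval <- tt$p.value
    } else if (length(fc) >= 2) {
      # zero-variance vector: the t statistic degenerates
      tval <- if (fc[1] == 0) 0 else Inf * sign(fc[1])
      pval <- if (fc[1] == 0) 1 else 0
    } else {
      tval <- NA_real_; pval <- NA_real_
    }
    list(log2fc = fc, t = tval, p = pval, n = length(fc))
  })
}
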