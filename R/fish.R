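#' Volume-normalized distance
#'
#' Rescales a raw 3D distance by the cube root of the nucleus volume
#' relative to a reference volume:
#' `x_norm = x_raw * ref_volume^(1/3) * volume^(-1/3)`.
#' This removes the trivial effect of nuclear size on spot separation
#' (distances are compared against the mean nuclear volume of the
#' reference condition, typically the pluripotent one). Identity when
#' `volume == ref_volume`; isotropic rescaling of a nucleus leaves the
#' normalized distance unchanged.
#'
#' @param x raw distances in um.
#' @param volume per-cell nucleus volume in um^3.
#' @param ref_volume reference volume in um^3.
#' @export
normalize_distance <- function(x, volume, ref_volume) {
  stopifnot(all(volume > 0), ref_volume > 0)
  x * ref_volume^(1 / 3) * volume^(-1 / 3)
}

#' Keep diploid cells of a FISH spot table
#'
#' Diploid cells show exactly two spots in each locus channel; cells with
#' any other count (including zero) are excluded. Focus-channel spots (e.g.
#' protein foci in immunoFISH) do not constrain ploidy.
#'
#' @param spots data.frame `cell_id, channel, x, y, z, nucleus_volume`
#'   (one row per spot; um / um^3 units).
#' @param locus_channels the two locus channel names (default
#'   `c("green", "orange")`).
#' @return the diploid subset, with attribute `excluded`: data.frame
#'   `cell_id` and per-channel spot counts of the removed cells.
#' @export
filter_diploid <- function(spots, locus_channels = c("green", "orange")) {
  stopifnot(length(locus_channels) == 2)
  counts <- table(factor(spots$cell_id),
                  factor(spots$channel, levels = locus_channels))
  ok_cells <- rownames(counts)[counts[, 1] == 2 & counts[, 2] == 2]
  keep <- spots$cell_id %in% ok_cells
  out <- spots[keep, , drop = FALSE]
  excl <- spots[!keep, , drop = FALSE]
  report <- unique(data.frame(cell_id = excl$cell_id))
  if (nrow(report)) {
    report$n_ch1 <- as.integer(counts[as.character(report$cell_id),
                                      locus_channels[1]])
    report$n_ch2 <- as.integer(counts[as.character(report$cell_id),
                                      locus_channels[2]])
  }
  attr(out, "excluded") <- report
  out
}

#' Minimum locus-pair distance per cell
#'
#' For each diploid cell, the minimum over the four green-orange
#' center-to-center 3D distances, volume-normalized against `ref_volume`;
#' the proximity flag marks cells whose normalized minimum distance is
#' below `proximity_thresh` (default 2 um, twice the diameter of a
#' 1-um-wide spot).
#'
#' @param spots a diploid spot table (see [filter_diploid()]).
#' @param ref_volume reference nucleus volume in um^3 (mean volume of the
#'   reference condition).
#' @param locus_channels the two locus channel names.
#' @param proximity_thresh proximity call threshold on the normalized
#'   distance, in um (default 2).
#' @return data.frame `cell_id, nucleus_volume, raw_min, norm_min,
#'   proximity`; cells with missing coordinates are dropped and reported
#'   in attribute `dropped`.
#' @export
min_pair_distance <- function(spots, ref_volume,
                              locus_channels = c("green", "orange"),
                              proximity_thresh = 2) {
  cells <- unique(spots$cell_id)
  rows <- vector("list", length(cells))
  dropped <- character(0)
  for (k in seq_along(cells)) {
    cs <- spots[spots$cell_id == cells[k], ]
    g <- cs[cs$channel == locus_channels[1], c("x", "y", "z")]
    o <- cs[cs$channel == locus_channels[2], c("x", "y", "z")]
    if (anyNA(g) || anyNA(o) || nrow(g) == 0 || nrow(o) == 0) {
      dropped <- c(dropped, as.character(cells[k]))
      next
    }
    d <- sqrt(outer(g$x, o$x, "-")^2 + outer(g$y, o$y, "-")^2 +
                outer(g$z, o$z, "-")^2)
    vol <- cs$nucleus_volume[1]
    raw <- min(d)
    nrm <- normalize_distance(raw, vol, ref_volume)
    rows[[k]] <- data.frame(cell_id = cells[k], nucleus_volume = vol,
                            raw_min = raw, norm_min = nrm,
                            proximity = nrm < proximity_thresh,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cell_id = character(0), nucleus_volume = numeric(0),
                      raw_min = numeric(0), norm_min = numeric(0),
                      proximity = logical(0))
  attr(out, "dropped") <- dropped
  out
}

#' Proximity fraction with a binomial confidence interval
#'
#' @param results output of [min_pair_distance()] (or any data.frame with
#'   a logical `proximity` column); an error if empty.
#' @param conf confidence level (default 0.95).
#' @return list `fraction`, `n`, `ci` (exact binomial).
#' @export
proximity_fraction <- function(results, conf = 0.95) {
  n <- nrow(results)
  if (n == 0) stop("no cells to summarize")
  x <- sum(results$proximity)
  bt <- stats::binom.test(x, n, conf.level = conf)
  list(fraction = x / n, n = n, ci = unname(bt$conf.int))
}

#' Locus-focus overlap calls
#'
#' A locus spot overlaps a focus (e.g. an RBM20 protein focus) when the
#' raw center-to-center distance to any focus is strictly below
#' `overlap_thresh` (1 um, the spot diameter; raw distances because the
#' threshold encodes physical spot size). Focus counts are reported for
#' all cells, including polyploid ones.
#'
#' @param spots full spot table (any ploidy).
#' @param locus_channel,focus_channel channel names.
#' @param overlap_thresh um (default 1).
#' @return list `loci` (data.frame `cell_id, x, y, z, min_focus_dist,
#'   overlap`), `cells` (data.frame `cell_id, n_foci, any_overlap`).
#' @export
focus_overlap <- function(spots, locus_channel = "green",
                          focus_channel = "focus", overlap_thresh = 1) {
  cells <- unique(spots$cell_id)
  li <- list(); ci <- list()
  for (k in seq_along(cells)) {
    cs <- spots[spots$cell_id == cells[k], ]
    loc <- cs[cs$channel == locus_channel, , drop = FALSE]
    foc <- cs[cs$channel == focus_channel, , drop = FALSE]
    if (nrow(loc)) {
      if (nrow(foc)) {
        d <- sqrt(outer(loc$x, foc$x, "-")^2 + outer(loc$y, foc$y, "-")^2 +
                    outer(loc$z, foc$z, "-")^2)
        mind <- apply(d, 1, min)
      } else mind <- rep(Inf, nrow(loc))
      li[[k]] <- data.frame(cell_id = cells[k], x = loc$x, y = loc$y,
                            z = loc$z, min_focus_dist = mind,
                            overlap = mind < overlap_thresh,
                            stringsAsFactors = FALSE)
    }
    ci[[k]] <- data.frame(cell_id = cells[k], n_foci = nrow(foc),
                          any_overlap = nrow(loc) > 0 && nrow(foc) > 0 &&
                            any(li[[k]]$overlap),
                          stringsAsFactors = FALSE)
  }
  list(loci = do.call(rbind, li[!vapply(li, is.null, logical(1))]),
       cells = do.call(rbind, ci))
}

# Dunn's rank-based pairwise post-hoc z statistic with tie correction
dunn_pairwise <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(r, groups, mean)
  ns <- table(groups)
  levs <- levels(groups)
  cmb <- utils::combn(length(levs), 2)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[a] + 1 / ns[b]))
    z[k] <- (rb[a] - rb[b]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = levs[cmb[1, ]], group_b = levs[cmb[2, ]], z = z,
             p = p, p_adj = stats::p.adjust(p, p_adjust),
             stringsAsFactors = FALSE)
}

#' Rank-based comparison of distance distributions across conditions
#'
#' Two conditions: two-sided Wilcoxon rank-sum test. More than two:
#' Kruskal-Wallis followed by Dunn's pairwise z-tests with multiplicity
#' adjustment (Bonferroni by default, Dunn's classical correction).
#'
#' @param values numeric vector (e.g. normalized minimum distances).
#' @param groups condition label per value (>= 2 levels).
#' @param p_adjust adjustment method for the pairwise p-values.
#' @return list `method`, `statistic`, `p`, and for > 2 groups `pairwise`
#'   (the Dunn table). Groups smaller than 3 raise a warning.
#' @export
group_compare <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two conditions")
  small <- names(which(table(groups) < 3))
  if (length(small))
    warning("groups with fewer than 3 observations: ",
            paste(small, collapse = ", "))
  if (nlevels(groups) == 2) {
    sp <- split(values, groups)
    wt <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]]))
    list(method = "wilcoxon", statistic = unname(wt$statistic),
         p = wt$p.value)
  } else {
    kw <- stats::kruskal.test(values, groups)
    list(method = "kruskal-dunn", statistic = unname(kw$statistic),
         p = kw$p.value,
         pairwise = dunn_pairwise(values, groups, p_adjust))
  }
}

#' Read / write FISH spot tables
#'
#' CSV with one row per spot: `cell_id, channel, x, y, z, nucleus_volume,
#' periphery_distance` (um / um^3).
#' @param path file path.
#' @export
read_spot_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_spot_table
#' @param spots spot table data.frame.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
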