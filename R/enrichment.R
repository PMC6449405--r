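# core enrichment table: observed category vector vs background category
# vector; expected counts proportional to the background distribution
enrichment_table <- function(obs_cat, bg_cat) {
  obs_cat <- obs_cat[!is.na(obs_cat)]
  bg_cat <- bg_cat[!is.na(bg_cat)]
  cats <- sort(unique(c(obs_cat, bg_cat)))
  obs <- table(factor(obs_cat, levels = cats))
  bg <- table(factor(bg_cat, levels = cats))
  p_bg <- as.numeric(bg) / sum(bg)
  expd <- sum(obs) * p_bg
  # chi-squared needs positive expected counts in every cell
  usable <- expd > 0
  chi <- if (sum(usable) >= 2 && sum(obs) > 0)
    suppressWarnings(stats::chisq.test(as.numeric(obs[usable]),
                                       p = p_bg[usable] / sum(p_bg[usable])))
  else NULL
  data.frame(category = cats,
             observed = as.numeric(obs),
             expected = expd,
             log2_ratio = log2((as.numeric(obs) / sum(obs)) / p_bg),
             chisq = if (is.null(chi)) NA_real_ else unname(chi$statistic),
             p = if (is.null(chi)) NA_real_ else chi$p.value,
             stringsAsFactors = FALSE)
}

#' Peak expression stage of differentially expressed genes
#'
#' The DE gene set is the externally flagged genes (the differential model
#' itself is consumed, not refit) whose maximum FPKM over the time course
#' reaches `min_fpkm`. Each DE gene's peak stage is the time point of its
#' maximum FPKM; exact ties resolve to the earliest stage and are counted
#' in the `ties` attribute. Genes with all-zero expression are excluded.
#'
#' @param fpkm numeric matrix, genes x time points (column order = stage
#'   order, column names = stage names); rownames are gene ids.
#' @param de_flag logical vector per gene (externally computed q < 0.05).
#' @param min_fpkm expression floor for the DE set (default 5).
#' @return data.frame `gene_id, peak_stage, max_fpkm` for the DE set.
#' @export
classify_gene_stage <- function(fpkm, de_flag, min_fpkm = 5) {
  fpkm <- as.matrix(fpkm)
  stopifnot(length(de_flag) == nrow(fpkm), !is.null(colnames(fpkm)))
  mx <- apply(fpkm, 1, max)
  keep <- de_flag & mx >= min_fpkm & mx > 0
  sub <- fpkm[keep, , drop = FALSE]
  peak <- apply(sub, 1, which.max)  # which.max: first maximum = earliest
  n_ties <- sum(apply(sub, 1, function(r) sum(r == max(r)) > 1))
  out <- data.frame(gene_id = rownames(sub),
                    peak_stage = colnames(fpkm)[peak],
                    max_fpkm = mx[keep], stringsAsFactors = FALSE)
  attr(out, "ties") <- n_ties
  out
}

# midpoint of intervals / TSS of genes -> covering bin -> category
assign_category <- function(chrom, pos, switch_calls) {
  ok <- !is.na(switch_calls$category)
  sc <- switch_calls[ok, ]
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  s <- GenomicRanges::GRanges(sc$chrom, IRanges::IRanges(sc$start + 1, sc$end))
  hit <- GenomicRanges::findOverlaps(g, s, select = "first")
  sc$category[hit]
}

#' Enrichment of a feature set in compartment-dynamics categories
#'
#' Features (intervals, assigned by midpoint, or genes, assigned by TSS)
#' are placed in the 500 kb bin covering them and take that bin's
#' switch-call category. Each class of features is compared with the
#' background set: `log2(class share / background share)` per category and
#' a chi-squared test of the class counts against expected counts
#' proportional to the background distribution (this is the "normalized to
#' gene density" correction: the background is typically all genes or the
#' union peak set).
#'
#' @param features data.frame with `chrom` and either `pos` (points/TSS) or
#'   `start`,`end` (intervals, midpoint used), plus optional `class`
#'   column; all rows form one class when absent.
#' @param switch_calls a `switch_calls` data.frame with coordinates.
#' @param background same format as `features` (no class column needed).
#' @return an `enrichment_result` data.frame: `class, category, observed,
#'   expected, log2_ratio, chisq, p`.
#' @export
category_enrichment <- function(features, switch_calls, background) {
  midpos <- function(df) {
    if ("pos" %in% names(df)) df$pos
    else (df$start + df$end) %/% 2
  }
  cls <- if ("class" %in% names(features)) features$class else "all"
  fcat <- assign_category(features$chrom, midpos(features), switch_calls)
  bcat <- assign_category(background$chrom, midpos(background), switch_calls)
  out <- do.call(rbind, lapply(unique(cls), function(cl)
    cbind(class = cl, enrichment_table(fcat[cls == cl], bcat))))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Stage-specific, shared and constitutive interval sets
#'
#' Given one peak set per stage, classifies each peak as stage-specific
#' (no >= 1 bp overlap with any other stage's peaks), constitutive
#' (overlaps a peak in every other stage), or shared (anything in
#' between).
#'
#' @param peak_sets named list of data.frames `chrom, start, end` (0-based
#'   half-open).
#' @return named list (per stage) of the input data.frames with an added
#'   `status` column.
#' @export
stage_specific_features <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 2, !is.null(names(peak_sets)))
  grs <- lapply(peak_sets, function(p)
    GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1, p$end)))
  lapply(names(peak_sets), function(s) {
    others <- grs[setdiff(names(peak_sets), s)]
    hits <- vapply(others, function(o)
      IRanges::overlapsAny(grs[[s]], o), logical(length(grs[[s]])))
    hits <- matrix(hits, ncol = length(others))
    n_other <- rowSums(hits)
    df <- peak_sets[[s]]
    df$status <- ifelse(n_other == 0, "stage-specific",
                        ifelse(n_other == length(others), "constitutive",
                               "shared"))
    df
  }) |> stats::setNames(names(peak_sets))
}

#' Fraction of features within a distance of another feature set
#'
#' For each interval in `set_a`, the distance to the nearest interval in
#' `set_b` (0 for any overlap); returns the fraction of `set_a` within
#' `max_dist`. Used e.g. for the fraction of TAD boundaries with a CTCF
#' peak within 1 kb.
#'
#' @param set_a,set_b data.frames `chrom, start, end` (points may use
#'   `start == end`; 0-based half-open).
#' @param max_dist maximum distance in bp (inclusive).
#' @return the fraction in `[0, 1]`; an empty `set_b` gives 0 with a
#'   warning.
#' @export
feature_proximity_fraction <- function(set_a, set_b, max_dist) {
  if (!nrow(set_b)) {
    warning("empty reference set; proximity fraction is 0")
    return(0)
  }
  if (!nrow(set_a)) return(NA_real_)
  mk <- function(df) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, pmax(df$end, df$start + 1)))
  a <- mk(set_a); b <- mk(set_b)
  d <- GenomicRanges::distanceToNearest(a, b)
  dist <- rep(NA_real_, length(a))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  mean(!is.na(dist) & dist <= max_dist)
}
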