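#' Z-scored trans-contact profile of one anchor bin
#'
#' Extracts all inter-chromosomal balanced counts for the anchor bin,
#' removes values strictly above the `1 - trim` quantile (top 0.5\% by
#' default; Hi-C trans rows carry rare extreme values, typically
#' translocation- or repeat-driven, that would dominate the Z scale), and
#' Z-scores the remainder. Partner bins are labelled A/B by the sign of the
#' supplied compartment track so profiles can be compared by compartment
#' with a rank-sum test.
#'
#' @param map a balanced `contact_map` (replicates pooled).
#' @param anchor_bin 0-based bin id of the anchor; an error if masked.
#' @param track per-bin PC1 scores for partner labelling (optional).
#' @param trim upper-tail fraction to remove before Z-scoring (default
#'   0.005).
#' @param min_partners warn below this many retained partner bins.
#' @return a `trans_profile` data.frame `bin_id, chrom, value, z,
#'   compartment` (retained bins only), with attribute `n_trimmed`.
#' @export
locus_trans_zscores <- function(map, anchor_bin, track = NULL, trim = 0.005,
                                min_partners = 100) {
  bins <- map$bins
  if (masked_bins(map)[anchor_bin + 1L]) stop("anchor bin is masked")
  M <- as_dense(map, apply_mask = TRUE)
  a <- anchor_bin + 1L
  partners <- which(bins$chrom != bins$chrom[a])
  v <- M[a, partners]
  ok <- !is.na(v)
  partners <- partners[ok]; v <- v[ok]
  keep <- rep(TRUE, length(v))
  if (trim > 0 && length(v)) {
    cut <- stats::quantile(v, 1 - trim, names = FALSE)
    keep <- v <= cut
  }
  partners <- partners[keep]; v <- v[keep]
  if (length(v) < min_partners)
    warning(sprintf("only %d retained partner bins", length(v)))
  z <- if (length(v) > 1 && stats::sd(v) > 0)
    (v - mean(v)) / stats::sd(v) else rep(0, length(v))
  comp <- if (is.null(track)) NA_character_ else {
    if (inherits(track, "compartment_track")) track <- track$score
    ifelse(is.na(track[partners]), NA,
           ifelse(track[partners] > 0, "A", "B"))
  }
  out <- data.frame(bin_id = bins$bin_id[partners],
                    chrom = bins$chrom[partners], value = v, z = z,
                    compartment = comp, stringsAsFactors = FALSE)
  attr(out, "n_trimmed") <- sum(!keep)
  class(out) <- c("trans_profile", "data.frame")
  out
}

#' Compare Z-score groups with a rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test between two groups of trans Z-scores
#' (e.g. A-compartment partners at two time points), with group medians.
#'
#' @param z1,z2 numeric vectors.
#' @return list `median1`, `median2`, `p`.
#' @export
trans_z_compare <- function(z1, z2) {
  p <- if (length(z1) && length(z2))
    suppressWarnings(stats::wilcox.test(z1, z2)$p.value) else NA_real_
  list(median1 = stats::median(z1), median2 = stats::median(z2), p = p)
}

# promoter (TSS) bin per gene; error listing genes that fall off-assembly
promoter_bins <- function(map, genes) {
  b <- locate_bin(map$bins, genes$chrom, genes$tss)
  if (anyNA(b))
    stop("genes outside the assembly: ",
         paste(genes$gene_id[is.na(b)], collapse = ", "))
  b
}

#' Trans-contact score of a gene set
#'
#' Sum of balanced contact values over all unordered gene pairs lying on
#' different chromosomes, each gene represented by the bin containing its
#' promoter (TSS). Same-chromosome pairs contribute nothing.
#'
#' @param map a balanced `contact_map` (replicates pooled).
#' @param genes data.frame `gene_id, chrom, tss`.
#' @return list `score` (numeric) and `edges` (data.frame `gene_a, gene_b,
#'   count` for trans pairs).
#' @export
geneset_trans_score <- function(map, genes) {
  b <- promoter_bins(map, genes)
  M <- as_dense(map, apply_mask = TRUE)
  n <- nrow(genes)
  if (n < 2)
    return(list(score = 0,
                edges = data.frame(gene_a = character(0),
                                   gene_b = character(0),
                                   count = numeric(0))))
  cmb <- utils::combn(n, 2)
  trans <- genes$chrom[cmb[1, ]] != genes$chrom[cmb[2, ]]
  cmb <- cmb[, trans, drop = FALSE]
  v <- M[cbind(b[cmb[1, ]] + 1L, b[cmb[2, ]] + 1L)]
  v[is.na(v)] <- 0
  list(score = sum(v),
       edges = data.frame(gene_a = genes$gene_id[cmb[1, ]],
                          gene_b = genes$gene_id[cmb[2, ]], count = v,
                          stringsAsFactors = FALSE))
}

#' Chromosome-matched permutation null for a gene-set trans score
#'
#' Repeatedly draws a random gene set with the same number of genes per
#' chromosome as the seed set (without replacement within a chromosome,
#' excluding the seed genes themselves by default), scores each draw with
#' [geneset_trans_score()], and reports the add-one empirical p-value
#' `p = (1 + #(null >= observed)) / (n + 1)`.
#'
#' @param map a balanced `contact_map`.
#' @param genes the seed gene set (data.frame `gene_id, chrom, tss`).
#' @param universe candidate gene table to draw from (same columns); may be
#'   pre-filtered (e.g. expressed genes, constitutive-A genes).
#' @param n number of permutations (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param exclude_seed drop the seed genes from the universe before
#'   sampling (default TRUE).
#' @return list `observed`, `null` (length-`n` vector), `p`.
#' @export
permutation_null <- function(map, genes, universe, n = 1000, seed,
                             exclude_seed = TRUE) {
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  if (exclude_seed)
    universe <- universe[!universe$gene_id %in% genes$gene_id, ]
  need <- table(genes$chrom)
  avail <- table(universe$chrom)
  short <- names(need)[is.na(avail[names(need)]) |
                         avail[names(need)] < need]
  if (length(short))
    stop("universe too small on chromosome(s): ",
         paste(short, collapse = ", "))
  M <- as_dense(map, apply_mask = TRUE)
  ub <- locate_bin(map$bins, universe$chrom, universe$tss)
  if (anyNA(ub))
    stop("universe genes outside the assembly: ",
         paste(universe$gene_id[is.na(ub)], collapse = ", "))
  by_ch <- split(seq_len(nrow(universe)), universe$chrom)
  m <- nrow(genes)
  cmb <- utils::combn(m, 2)
  obs <- geneset_trans_score(map, genes)$score
  null <- numeric(n)
  for (k in seq_len(n)) {
    pick <- unlist(lapply(names(need), function(ch) {
      pool <- by_ch[[ch]]
      pool[sample.int(length(pool), need[[ch]])]
    }))
    bb <- ub[pick] + 1L; ch <- universe$chrom[pick]
    trans <- ch[cmb[1, ]] != ch[cmb[2, ]]
    v <- M[cbind(bb[cmb[1, trans]], bb[cmb[2, trans]])]
    null[k] <- sum(v, na.rm = TRUE)
  }
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (n + 1))
}

#' Trans-network edge table across time points
#'
#' Builds the per-pair trans contact table for a gene set at each time
#' point. An edge is flagged for display when its late-time-point count
#' exceeds the genome-wide median trans balanced count of the late map
#' (strictly greater). The fold-change annotation is
#' `log2((count_late / median_late) / (count_early / median_early))`, with
#' `pseudocount` substituted for zero counts (flagged).
#'
#' @param map_early,map_late balanced `contact_map`s for the two time
#'   points being contrasted.
#' @param genes data.frame `gene_id, chrom, tss`.
#' @param pseudocount used when a count is zero (default half the smallest
#'   non-zero trans count of the corresponding map).
#' @return data.frame `gene_a, gene_b, count_early, count_late, display,
#'   log2fc, pseudo_used`.
#' @export
build_network <- function(map_early, map_late, genes, pseudocount = NULL) {
  e_early <- geneset_trans_score(map_early, genes)$edges
  e_late <- geneset_trans_score(map_late, genes)$edges
  med_early <- median_trans_count(map_early)
  med_late <- median_trans_count(map_late)
  stopifnot(nrow(e_early) == nrow(e_late))
  ce <- e_early$count; cl <- e_late$count
  if (is.null(pseudocount)) {
    nz <- c(ce[ce > 0], cl[cl > 0])
    pseudocount <- if (length(nz)) min(nz) / 2 else 1
  }
  pseudo_used <- ce == 0 | cl == 0
  ce2 <- ifelse(ce == 0, pseudocount, ce)
  cl2 <- ifelse(cl == 0, pseudocount, cl)
  data.frame(gene_a = e_late$gene_a, gene_b = e_late$gene_b,
             count_early = ce, count_late = cl,
             display = cl > med_late,
             log2fc = log2((cl2 / med_late) / (ce2 / med_early)),
             pseudo_used = pseudo_used, stringsAsFactors = FALSE)
}

#' Genome-wide median trans balanced count
#' @param map a balanced `contact_map`.
#' @return the median over all unmasked inter-chromosomal bin pairs
#'   (implicit zeros included).
#' @export
median_trans_count <- function(map) {
  M <- as_dense(map, apply_mask = TRUE)
  ch <- map$bins$chrom
  ut <- which(upper.tri(M), arr.ind = TRUE)
  tr <- ch[ut[, 1]] != ch[ut[, 2]]
  stats::median(M[ut[tr, , drop = FALSE]], na.rm = TRUE)
}
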