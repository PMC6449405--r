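#' Configuration for the Hi-C simulator
#'
#' Defaults describe the study conditions the generator emulates: a toy
#' genome of 4 chromosomes binned at 500 kb, a 4-stage differentiation time
#' course with 2 replicates, 19\% of bins switching compartment with
#' category mix A-B 33\%, B-A 49\%, A-B-A 8\%, B-A-B 10\%, power-law
#' distance decay, a homotypic contact boost producing the checkerboard,
#' a progressive gain of long-range (>10 Mb) B-B contacts across stages,
#' and negative-binomial replicate noise around the expectation.
#'
#' @param n_chromosomes,bins_per_chrom toy genome shape (default 4 x 20
#'   bins).
#' @param resolution bin width in bp (default 5e5).
#' @param n_timepoints,n_replicates time course shape (default 4 x 2).
#' @param switch_fraction fraction of bins planted to switch (default
#'   0.19).
#' @param switch_category_mix proportions over categories
#'   `c("A-B", "B-A", "A-B-A", "B-A-B")`; must sum to 1.
#' @param decay_exponent alpha in cis expectation `base * d^-alpha`
#'   (default 1).
#' @param compartment_strength multiplicative homotypic boost (default
#'   1.6).
#' @param bb_longrange_gain_per_stage extra multiplicative gain per stage
#'   for B-B pairs beyond `longrange_cutoff` (models heterochromatin
#'   compaction; default 0.15).
#' @param longrange_cutoff bp distance where the B-B gain applies (default
#'   1e7).
#' @param trans_aa_boost multiplicative boost for trans A-A pairs (default
#'   0.3, i.e. 1.3x).
#' @param hub_gain multiplicative gain between planted hub-gene bins
#'   (default 5).
#' @param hub_timepoints stages where the hub is active (default: the last
#'   stage only, a differentiation-acquired hub).
#' @param compartment_block_bins size in bins of the alternating A/B base
#'   blocks (default 5).
#' @param base_cis,base_trans expectation scale at distance 1 bin / for
#'   trans pairs (defaults 100 and 5).
#' @param diag_boost multiplier for the diagonal (default 4).
#' @param noise_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives deterministic rounded counts.
#' @param include_trans emit inter-chromosomal entries (default TRUE).
#' @param stage_names names of the time points (default hESC, MES, CP, CM
#'   when there are four).
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @return a validated `hic_sim_config` list.
#' @export
hic_sim_config <- function(n_chromosomes = 4, bins_per_chrom = 20,
                           resolution = 5e5, n_timepoints = 4,
                           n_replicates = 2, switch_fraction = 0.19,
                           switch_category_mix =
                             c("A-B" = 0.33, "B-A" = 0.49,
                               "A-B-A" = 0.08, "B-A-B" = 0.10),
                           decay_exponent = 1, compartment_strength = 1.6,
                           bb_longrange_gain_per_stage = 0.15,
                           longrange_cutoff = 1e7, trans_aa_boost = 0.3,
                           hub_gain = 5, hub_timepoints = NULL,
                           compartment_block_bins = 5, base_cis = 100,
                           base_trans = 5, diag_boost = 4,
                           noise_dispersion = 0.1, include_trans = TRUE,
                           stage_names = NULL, seed = 1) {
  if (abs(sum(switch_category_mix) - 1) > 1e-8)
    stop("switch_category_mix must sum to 1")
  if (switch_fraction < 0 || switch_fraction > 1)
    stop("switch_fraction must be in [0, 1]")
  gains <- c(compartment_strength, bb_longrange_gain_per_stage,
             trans_aa_boost, hub_gain, noise_dispersion)
  if (any(gains < 0)) stop("gains and dispersion must be >= 0")
  if (is.null(stage_names))
    stage_names <- if (n_timepoints == 4) c("hESC", "MES", "CP", "CM")
      else paste0("t", seq_len(n_timepoints))
  if (is.null(hub_timepoints)) hub_timepoints <- n_timepoints
  structure(list(
    n_chromosomes = n_chromosomes, bins_per_chrom = bins_per_chrom,
    resolution = resolution, n_timepoints = n_timepoints,
    n_replicates = n_replicates, switch_fraction = switch_fraction,
    switch_category_mix = switch_category_mix,
    decay_exponent = decay_exponent,
    compartment_strength = compartment_strength,
    bb_longrange_gain_per_stage = bb_longrange_gain_per_stage,
    longrange_cutoff = longrange_cutoff, trans_aa_boost = trans_aa_boost,
    hub_gain = hub_gain, hub_timepoints = hub_timepoints,
    compartment_block_bins = compartment_block_bins, base_cis = base_cis,
    base_trans = base_trans, diag_boost = diag_boost,
    noise_dispersion = noise_dispersion, include_trans = include_trans,
    stage_names = stage_names, seed = seed), class = "hic_sim_config")
}

# sign pattern (+1 = A, -1 = B) over T time points for a switch category
switch_pattern <- function(category, T) {
  half <- ceiling(T / 2)
  switch(category,
         "A-B" = c(rep(1, half), rep(-1, T - half)),
         "B-A" = c(rep(-1, half), rep(1, T - half)),
         "A-B-A" = c(1, rep(-1, T - 2), 1),
         "B-A-B" = c(-1, rep(1, T - 2), -1),
         stop("unknown switch category: ", category))
}

#' Simulate a Hi-C time course with known compartment ground truth
#'
#' Builds one contact map per (time point, replicate). Per stage, each bin
#' carries a true A/B label: stable bins keep the alternating base-block
#' label, planted switching bins follow their category's sign pattern. The
#' expectation model is multiplicative: cis pairs decay as
#' `base_cis * d^-alpha`, boosted by `compartment_strength` when the two
#' bins share the stage's true label, with the long-range B-B gain applied
#' beyond `longrange_cutoff`; trans pairs sit at `base_trans`, boosted for
#' A-A pairs and for planted hub-bin pairs at the hub's active stages.
#' Replicate counts are negative-binomial around the expectation
#' (deterministic rounding when `noise_dispersion = 0`).
#'
#' @param config an [hic_sim_config()].
#' @param hub_bins optional integer vector of 0-based bin ids forming the
#'   planted trans hub.
#' @return list with `maps` (named `t<stage>_r<rep>` list of
#'   `contact_map`s), `bins`, `samples` (data.frame `name, timepoint,
#'   replicate`), `orientation` (per-bin gene-density-like track for PC1
#'   sign fixing), and `truth` (per-bin label matrix, per-bin category,
#'   switching flag, hub bins, config).
#' @export
sim_hic <- function(config, hub_bins = NULL) {
  stopifnot(inherits(config, "hic_sim_config"))
  set.seed(config$seed)
  cf <- config
  nb <- cf$n_chromosomes * cf$bins_per_chrom
  sizes <- stats::setNames(rep(cf$bins_per_chrom * cf$resolution,
                               cf$n_chromosomes),
                           paste0("chr", seq_len(cf$n_chromosomes)))
  bins <- bin_table(sizes, cf$resolution)
  T <- cf$n_timepoints
  # base labels: alternating blocks within each chromosome
  blk <- ((seq_len(cf$bins_per_chrom) - 1) %/% cf$compartment_block_bins)
  base_lab <- rep(ifelse(blk %% 2 == 0, 1, -1), cf$n_chromosomes)
  L <- matrix(rep(base_lab, T), ncol = T)
  n_switch <- round(cf$switch_fraction * nb)
  category <- ifelse(base_lab > 0, "stable-A", "stable-B")
  if (n_switch > 0) {
    sw <- sample.int(nb, n_switch)
    mix <- cf$switch_category_mix
    cats <- sample(names(mix), n_switch, replace = TRUE, prob = mix)
    for (k in seq_along(sw)) {
      L[sw[k], ] <- switch_pattern(cats[k], T)
      category[sw[k]] <- cats[k]
    }
  }
  ch <- bins$chrom
  cis_mask <- outer(ch, ch, "==")
  pos <- bins$start + cf$resolution / 2
  Dbp <- abs(outer(pos, pos, "-"))
  Dbin <- round(Dbp / cf$resolution)
  hub_mask <- NULL
  if (!is.null(hub_bins)) {
    hb <- seq_len(nb) %in% (hub_bins + 1L)
    hub_mask <- outer(hb, hb, "&") & !cis_mask
  }
  maps <- list()
  samples <- data.frame(name = character(0), timepoint = character(0),
                        replicate = integer(0))
  ut <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
  for (t in seq_len(T)) {
    lab <- L[, t]
    same <- outer(lab, lab, "==")
    mu <- matrix(0, nb, nb)
    # cis: power-law decay with homotypic boost
    dc <- Dbin
    dc[dc == 0] <- 1
    cis_mu <- cf$base_cis * dc^(-cf$decay_exponent)
    cis_mu[Dbin == 0] <- cf$base_cis * cf$diag_boost
    boost <- ifelse(same, cf$compartment_strength, 1)
    bb_long <- outer(lab < 0, lab < 0, "&") & Dbp > cf$longrange_cutoff
    gain <- 1 + cf$bb_longrange_gain_per_stage * (t - 1)
    boost[bb_long] <- boost[bb_long] * gain
    mu[cis_mask] <- (cis_mu * boost)[cis_mask]
    if (cf$include_trans) {
      tr_mu <- matrix(cf$base_trans, nb, nb)
      aa <- outer(lab > 0, lab > 0, "&")
      tr_mu[aa] <- tr_mu[aa] * (1 + cf$trans_aa_boost)
      if (!is.null(hub_mask) && t %in% cf$hub_timepoints)
        tr_mu[hub_mask] <- tr_mu[hub_mask] * cf$hub_gain
      mu[!cis_mask] <- tr_mu[!cis_mask]
    }
    mu_ut <- mu[ut]
    for (r in seq_len(cf$n_replicates)) {
      x <- if (cf$noise_dispersion == 0) round(mu_ut)
      else stats::rnbinom(length(mu_ut), mu = mu_ut,
                          size = 1 / cf$noise_dispersion)
      keep <- x > 0
      nm <- sprintf("t%d_r%d", t, r)
      maps[[nm]] <- contact_map(bins, ut[keep, 1] - 1L, ut[keep, 2] - 1L,
                                x[keep])
      samples <- rbind(samples,
                       data.frame(name = nm,
                                  timepoint = cf$stage_names[t],
                                  replicate = r))
    }
  }
  # static gene-density-like orientation reference: A-leaning bins dense
  orientation <- rowMeans(L > 0)
  truth <- list(labels = ifelse(L > 0, "A", "B"), category = category,
                switching = !category %in% c("stable-A", "stable-B"),
                hub_bins = hub_bins, config = cf)
  list(maps = maps, bins = bins, samples = samples,
       orientation = orientation, truth = truth)
}

#' Simulate a TAD-scale contact map with planted domain blocks
#'
#' One or more chromosomes of consecutive square domains: contacts decay as
#' `base * d^-alpha` and pairs within the same planted block are boosted by
#' `tad_strength`, so every block junction is a true insulation boundary.
#'
#' @param n_bins bins per chromosome (default 250, i.e. 10 Mb at 40 kb).
#' @param n_chromosomes default 1.
#' @param resolution default 4e4.
#' @param block_bins domain size in bins (default 25, i.e. 1 Mb).
#' @param base,decay_exponent,diag_boost cis expectation model as in
#'   [sim_hic()].
#' @param tad_strength homotypic (same-block) boost (default 3).
#' @param noise_dispersion negative-binomial dispersion (default 0.1).
#' @param seed RNG seed.
#' @return list `map` (a `contact_map`), `junctions` (data.frame
#'   `chrom, pos` of true internal block junctions, bp).
#' @export
sim_tad_map <- function(n_bins = 250, n_chromosomes = 1, resolution = 4e4,
                        block_bins = 25, base = 100, decay_exponent = 1,
                        diag_boost = 4, tad_strength = 3,
                        noise_dispersion = 0.1, seed = 1) {
  set.seed(seed)
  sizes <- stats::setNames(rep(n_bins * resolution, n_chromosomes),
                           paste0("chr", seq_len(n_chromosomes)))
  bins <- bin_table(sizes, resolution)
  nb <- n_bins(bins)
  blk_of <- rep((seq_len(n_bins) - 1L) %/% block_bins, n_chromosomes) +
    rep(seq_len(n_chromosomes) * 1000L, each = n_bins)
  ch <- bins$chrom
  cis <- outer(ch, ch, "==")
  idx <- rep(seq_len(n_bins), n_chromosomes)
  D <- abs(outer(idx, idx, "-"))
  dc <- D; dc[dc == 0] <- 1
  mu <- base * dc^(-decay_exponent)
  mu[D == 0] <- base * diag_boost
  same_blk <- outer(blk_of, blk_of, "==")
  mu[same_blk] <- mu[same_blk] * tad_strength
  mu[!cis] <- 0
  ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
  mu_ut <- mu[ut]
  x <- if (noise_dispersion == 0) round(mu_ut)
  else stats::rnbinom(length(mu_ut), mu = mu_ut,
                      size = 1 / noise_dispersion)
  keep <- x > 0
  map <- contact_map(bins, ut[keep, 1] - 1L, ut[keep, 2] - 1L, x[keep])
  jb <- seq(block_bins, n_bins - 1, by = block_bins)
  junctions <- do.call(rbind, lapply(unique(ch), function(c0)
    data.frame(chrom = c0, pos = jb * resolution)))
  list(map = map, junctions = junctions)
}

#' Simulate gene annotation, expression and peak tracks
#'
#' Emits the gene-level inputs matched to a [sim_hic()] genome: a gene
#' table (TSS and span), an FPKM matrix over the stages with a planted
#' peak stage per gene, DE flags (simulated q-values), and one peak BED
#' set per stage. Genes whose TSS falls in a planted B-to-A bin peak at
#' the last stage with odds multiplied by `late_stage_or`; last-stage
#' -specific peaks are placed in B-to-A bins with odds multiplied by
#' `peak_or`.
#'
#' @param sim output of [sim_hic()] (uses its bins and truth).
#' @param genes_per_chrom genes per chromosome (default 40; at least 10).
#' @param de_fraction fraction of genes flagged differential (default
#'   0.5).
#' @param peak_fpkm,base_fpkm FPKM at / off the peak stage (defaults 30
#'   and 2).
#' @param fpkm_noise_sd lognormal sd of FPKM noise (default 0.1).
#' @param late_stage_or odds ratio for late peaking of DE genes in B-to-A
#'   bins (default 4; 1 = no planted association).
#' @param n_peaks_per_stage peaks per stage (default 200).
#' @param peak_specific_fraction fraction of each stage's peaks that are
#'   stage-specific (default 0.5; the rest are constitutive, identical in
#'   every stage).
#' @param peak_or odds ratio for placing last-stage-specific peaks in
#'   B-to-A bins (default 4).
#' @param seed RNG seed.
#' @return list `genes` (`gene_id, chrom, tss, start, end`), `fpkm`
#'   (matrix genes x stages), `de_flag`, `q_value`, `peaks` (named list of
#'   BED data.frames per stage), `truth` (`peak_stage` per gene).
#' @export
sim_tracks <- function(sim, genes_per_chrom = 40, de_fraction = 0.5,
                       peak_fpkm = 30, base_fpkm = 2, fpkm_noise_sd = 0.1,
                       late_stage_or = 4, n_peaks_per_stage = 200,
                       peak_specific_fraction = 0.5, peak_or = 4,
                       seed = 1) {
  stopifnot(genes_per_chrom >= 10)
  set.seed(seed)
  bins <- sim$bins
  cf <- sim$truth$config
  stages <- cf$stage_names
  T <- length(stages)
  chroms <- unique(bins$chrom)
  chrom_len <- vapply(chroms, function(c0)
    max(bins$end[bins$chrom == c0]), numeric(1))
  genes <- do.call(rbind, lapply(chroms, function(c0) {
    tss <- sort(sample.int(chrom_len[[c0]] - 1e4, genes_per_chrom))
    data.frame(chrom = c0, tss = tss, start = tss,
               end = pmin(tss + round(stats::rlnorm(genes_per_chrom,
                                                    log(3e4), 0.8)),
                          chrom_len[[c0]]),
               stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "tss", "start", "end")]
  gbin <- locate_bin(bins, genes$chrom, genes$tss)
  gcat <- sim$truth$category[gbin + 1L]
  n <- nrow(genes)
  de_flag <- stats::runif(n) < de_fraction
  q_value <- ifelse(de_flag, stats::runif(n, 0, 0.049),
                    stats::runif(n, 0.05, 1))
  # peak-stage assignment: uniform odds, late-stage odds boosted for DE
  # genes sitting in planted B-to-A bins
  peak_stage <- integer(n)
  for (g in seq_len(n)) {
    odds <- rep(1, T)
    if (de_flag[g] && identical(gcat[g], "B-A")) odds[T] <- late_stage_or
    peak_stage[g] <- sample.int(T, 1, prob = odds / sum(odds))
  }
  fpkm <- matrix(base_fpkm, n, T, dimnames = list(genes$gene_id, stages))
  fpkm[cbind(seq_len(n), peak_stage)] <- peak_fpkm
  # non-DE genes: flat moderate expression (no stage structure)
  fpkm[!de_flag, ] <- 8
  fpkm <- fpkm * matrix(stats::rlnorm(n * T, 0, fpkm_noise_sd), n, T)
  n_spec <- round(n_peaks_per_stage * peak_specific_fraction)
  n_const <- n_peaks_per_stage - n_spec
  ba_bins <- which(sim$truth$category == "B-A")
  place_peak <- function(bin_idx) {
    s <- bins$start[bin_idx] +
      sample.int(bins$end[bin_idx] - bins$start[bin_idx] - 500, 1)
    data.frame(chrom = bins$chrom[bin_idx], start = s, end = s + 500,
               stringsAsFactors = FALSE)
  }
  const_bins <- sample.int(n_bins(bins), n_const, replace = TRUE)
  const_peaks <- do.call(rbind, lapply(const_bins, place_peak))
  peaks <- stats::setNames(vector("list", T), stages)
  for (t in seq_len(T)) {
    w <- rep(1, n_bins(bins))
    if (t == T && length(ba_bins)) w[ba_bins] <- peak_or
    spec_bins <- sample.int(n_bins(bins), n_spec, replace = TRUE,
                            prob = w / sum(w))
    spec <- do.call(rbind, lapply(spec_bins, place_peak))
    # stage-specific peaks must not collide with other stages: offset them
    # into a stage-private 10 kb phase within the bin
    spec$start <- spec$start - (spec$start %% 1e4) + (t - 1) * 600
    spec$end <- spec$start + 500
    pk <- rbind(const_peaks, spec)
    pk <- pk[order(pk$chrom, pk$start), ]
    rownames(pk) <- NULL
    peaks[[t]] <- pk
  }
  list(genes = genes, fpkm = fpkm, de_flag = de_flag, q_value = q_value,
       peaks = peaks,
       truth = list(peak_stage = stages[peak_stage], gene_bin = gbin,
                    gene_category = gcat))
}

# uniform point in an ellipsoid with the given semi-axes
runif_ellipsoid <- function(axes) {
  repeat {
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) <= 1) return(p * axes)
  }
}

ellipsoid_periphery_distance <- function(p, axes) {
  rho <- sqrt(sum((p / axes)^2))
  if (rho == 0) return(min(axes))
  sqrt(sum(p^2)) * (1 / rho - 1)
}

#' Simulate a 3D FISH spot table with known proximity ground truth
#'
#' Each cell is an ellipsoidal nucleus (volume lognormal around
#' `volume_mean`) with two spots per locus channel (more for planted
#' aneuploid cells). A `p_true` fraction of diploid cells carries one
#' green-orange pair planted closer than 2 um after volume normalization
#' against `ref_volume`; the remaining cells are rejected-sampled to stay
#' beyond it, so the planted fraction is the true proximity rate.
#' Optionally a focus channel (protein foci) is added with a planted
#' locus-overlap fraction (< 1 um raw). Periphery distances are the exact
#' center-to-surface distances along the radial ray of the ellipsoid.
#'
#' @param n_cells number of cells.
#' @param p_true true proximity fraction in `[0, 1]`.
#' @param condition label stored in the `condition` column.
#' @param volume_mean,volume_cv nucleus volume distribution (um^3;
#'   defaults 650 and 0.2).
#' @param ref_volume reference volume for the planted normalized
#'   distances (default `volume_mean`).
#' @param aneuploid_fraction fraction of cells given extra locus spots
#'   (default 0).
#' @param include_focus add a focus channel (default FALSE).
#' @param focus_overlap_fraction fraction of cells with a focus planted
#'   within 1 um of a green spot (default 0).
#' @param focus_lambda Poisson mean of extra focus count (default 2).
#' @param seed RNG seed.
#' @return a spot table data.frame (`cell_id, condition, channel, x, y, z,
#'   nucleus_volume, periphery_distance`) with attribute `truth`
#'   (per-cell `proximal`, `aneuploid`, `focus_overlap` flags).
#' @export
sim_spots <- function(n_cells, p_true, condition = "cond",
                      volume_mean = 650, volume_cv = 0.2,
                      ref_volume = volume_mean, aneuploid_fraction = 0,
                      include_focus = FALSE, focus_overlap_fraction = 0,
                      focus_lambda = 2, seed = 1) {
  if (p_true < 0 || p_true > 1) stop("p_true must be in [0, 1]")
  set.seed(seed)
  sdlog <- sqrt(log(1 + volume_cv^2))
  rows <- list()
  proximal <- stats::runif(n_cells) < p_true
  aneu <- stats::runif(n_cells) < aneuploid_fraction
  f_over <- stats::runif(n_cells) < focus_overlap_fraction
  for (cc in seq_len(n_cells)) {
    vol <- stats::rlnorm(1, log(volume_mean) - sdlog^2 / 2, sdlog)
    scale_f <- (vol / ref_volume)^(1 / 3)  # raw = normalized * scale_f
    # mild random anisotropy around a sphere of the same volume
    an <- stats::runif(2, 0.6, 0.95)
    a <- (3 * vol / (4 * pi * an[1] * an[2]))^(1 / 3)
    axes <- c(a, a * an[1], a * an[2])
    g <- list(runif_ellipsoid(axes), runif_ellipsoid(axes))
    place_orange <- function() list(runif_ellipsoid(axes),
                                    runif_ellipsoid(axes))
    min_norm <- function(o) {
      d <- min(vapply(g, function(gg) min(vapply(o, function(oo)
        sqrt(sum((gg - oo)^2)), numeric(1))), numeric(1)))
      d / scale_f
    }
    if (proximal[cc]) {
      target <- stats::runif(1, 0.3, 1.7) * scale_f
      o1 <- NULL
      for (try in 1:500) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- g[[1]] + u * target
        if (sqrt(sum((cand / axes)^2)) < 1) { o1 <- cand; break }
      }
      if (is.null(o1)) o1 <- g[[1]] * (1 - target / sqrt(sum(g[[1]]^2)))
      o <- list(o1, runif_ellipsoid(axes))
    } else {
      o <- place_orange()
      for (try in 1:500) {
        if (min_norm(o) >= 2.3) break
        o <- place_orange()
      }
    }
    spots <- list(green = g, orange = o)
    if (aneu[cc]) {
      extra_ch <- sample(c("green", "orange"), 1)
      spots[[extra_ch]] <- c(spots[[extra_ch]],
                             list(runif_ellipsoid(axes)))
    }
    if (include_focus) {
      nf <- stats::rpois(1, focus_lambda) + 1L
      foci <- replicate(nf, runif_ellipsoid(axes), simplify = FALSE)
      if (f_over[cc]) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        foci[[1]] <- g[[1]] + u * stats::runif(1, 0.2, 0.8)
      } else {
        # keep all foci away from both green spots
        for (k in seq_along(foci)) for (try in 1:200) {
          dmin <- min(vapply(g, function(gg)
            sqrt(sum((gg - foci[[k]])^2)), numeric(1)))
          if (dmin >= 1.2) break
          foci[[k]] <- runif_ellipsoid(axes)
        }
      }
      spots$focus <- foci
    }
    for (chn in names(spots)) for (p in spots[[chn]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("%s_c%04d", condition, cc),
        condition = condition, channel = chn,
        x = p[1], y = p[2], z = p[3], nucleus_volume = vol,
        periphery_distance = ellipsoid_periphery_distance(p, axes),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(proximal = proximal, aneuploid = aneu,
                             focus_overlap = f_over)
  out
}

#' Write a simulated Hi-C data set to disk
#'
#' Emits the exact pipeline input formats: one triplet matrix per sample
#' plus the shared bin BED, the orientation track as bedGraph, and the
#' ground truth as plain TSV sidecars.
#'
#' @param sim output of [sim_hic()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_sim_hic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  bp <- file.path(dir, "bins.bed")
  write_bins(sim$bins, bp); files <- c(files, bp)
  for (nm in names(sim$maps)) {
    mp <- file.path(dir, paste0(nm, ".matrix"))
    write_contact_map(sim$maps[[nm]], mp)
    files <- c(files, mp)
  }
  op <- file.path(dir, "orientation.bedgraph")
  write_bedgraph(sim$bins, sim$orientation, op); files <- c(files, op)
  tp <- file.path(dir, "truth_bins.tsv")
  tr <- data.frame(bin_id = sim$bins$bin_id, category = sim$truth$category,
                   switching = sim$truth$switching)
  tr <- cbind(tr, as.data.frame(sim$truth$labels))
  utils::write.table(tr, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tp)
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(sim$samples, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, sp)
  invisible(files)
}
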