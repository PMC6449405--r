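#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end demo run: simulator settings,
#' switching alpha, TAD parameters, permutation count and FISH thresholds,
#' all seeded from one root seed. Stochastic stages derive their seeds
#' deterministically from `seed`, so a rerun with the same configuration
#' is bit-identical.
#'
#' @param out_dir output directory.
#' @param seed root seed for every stochastic stage.
#' @param sim an [hic_sim_config()]; a default toy config when `NULL`.
#' @param alpha switching significance threshold.
#' @param di_window,insulation_square,boundary_tolerance TAD parameters
#'   (bp).
#' @param n_permutations trans-test permutation count.
#' @param fish_proximity_thresh,fish_overlap_thresh FISH call thresholds
#'   (um).
#' @param n_cells cells per simulated FISH condition.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL, alpha = 0.05,
                            di_window = 2e6, insulation_square = 5e5,
                            boundary_tolerance = 2e5,
                            n_permutations = 1000,
                            fish_proximity_thresh = 2,
                            fish_overlap_thresh = 1, n_cells = 200) {
  if (is.null(sim)) sim <- hic_sim_config(seed = seed)
  stopifnot(alpha > 0, alpha <= 1, n_permutations >= 1, n_cells >= 1,
            fish_proximity_thresh > 0, fish_overlap_thresh > 0)
  structure(list(out_dir = out_dir, seed = seed, sim = sim, alpha = alpha,
                 di_window = di_window,
                 insulation_square = insulation_square,
                 boundary_tolerance = boundary_tolerance,
                 n_permutations = n_permutations,
                 fish_proximity_thresh = fish_proximity_thresh,
                 fish_overlap_thresh = fish_overlap_thresh,
                 n_cells = n_cells),
            class = "pipeline_config")
}

#' Run the full demo pipeline on generated data
#'
#' Simulates a Hi-C time course, balances every map, calls PC1 and
#' compartment switches, computes saddle and decay summaries, calls TAD
#' boundaries on a planted-domain map by both methods and compares them,
#' runs the trans-hub permutation test, and summarizes a simulated FISH
#' experiment. All tables are written under `config$out_dir` together
#' with a manifest (`manifest.tsv`) of md5 checksums; the run log records
#' parameters and seeds.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the in-memory results plus the manifest
#'   path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("hicdyn %s | root seed %d | alpha %.3g | permutations %d",
       as.character(utils::packageVersion("hicdyn")), config$seed,
       config$alpha, config$n_permutations)

  # --- compartments on the simulated time course ------------------------
  cfg <- config$sim
  n_genes_pc <- max(10, min(40, cfg$bins_per_chrom * 2))
  hub_bins <- NULL
  sim <- sim_hic(cfg)
  tracks <- sim_tracks(sim, genes_per_chrom = n_genes_pc,
                       seed = config$seed + 1)
  # plant the trans hub on 16 gene promoters spread over the chromosomes
  hub_genes <- tracks$genes[seq(1, nrow(tracks$genes),
                                length.out = 16), ]
  hub_bins <- unique(locate_bin(sim$bins, hub_genes$chrom, hub_genes$tss))
  sim <- sim_hic(cfg, hub_bins = hub_bins)
  balanced <- lapply(sim$maps, ice_balance)
  pc1 <- lapply(balanced, compute_pc1, orientation = sim$orientation)
  scores <- sapply(pc1, function(t) t$score)
  sw <- classify_switches(scores, sim$samples$timepoint,
                          sim$samples$replicate, alpha = config$alpha,
                          bins = sim$bins)
  utils::write.table(sw, file.path(config$out_dir, "switch_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  first <- sim$samples$name[1]
  last <- sim$samples$name[nrow(sim$samples)]
  oe_first <- oe_normalize(balanced[[first]])
  oe_last <- oe_normalize(balanced[[last]])
  sad_first <- saddle(oe_first, pc1[[first]])
  sad_last <- saddle(oe_last, pc1[[last]])
  utils::write.table(delta_saddle(sad_last, sad_first),
                     file.path(config$out_dir, "delta_saddle.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  decay <- decay_curves(balanced[[last]], pc1[[last]])
  utils::write.table(decay, file.path(config$out_dir, "decay_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  frac <- compartment_fraction(rowMeans(scores[, sim$samples$timepoint ==
                                                 sim$samples$timepoint[1]]))
  logf("compartment fraction (first stage): A=%.3f B=%.3f",
       frac["A"], frac["B"])

  # --- TADs on a planted-domain 40 kb map -------------------------------
  tad <- sim_tad_map(seed = config$seed + 2)
  bal40 <- ice_balance(tad$map)
  di <- directionality_index(bal40, window = config$di_window)
  dom <- di_domains(di)
  ins <- insulation_score(bal40, square = config$insulation_square)
  ib <- insulation_boundaries(ins)
  cmp <- compare_boundaries(dom$boundaries, ib,
                            tolerance = config$boundary_tolerance)
  logf("TAD boundaries: DI=%d insulation=%d jaccard=%.3f",
       nrow(dom$boundaries), nrow(ib), cmp$jaccard)
  utils::write.table(dom$tads, file.path(config$out_dir, "tads_di.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  # --- trans hub permutation test ---------------------------------------
  pooled <- pool_maps(balanced[sim$samples$name[
    sim$samples$timepoint == cfg$stage_names[cfg$n_timepoints]]])
  perm <- permutation_null(pooled, hub_genes, tracks$genes,
                           n = config$n_permutations,
                           seed = config$seed + 3)
  logf("trans hub: observed=%.3f p=%.4g", perm$observed, perm$p)

  # --- FISH --------------------------------------------------------------
  ref <- sim_spots(config$n_cells, p_true = 0.15, condition = "hESC",
                   seed = config$seed + 4)
  cm <- sim_spots(config$n_cells, p_true = 0.45, condition = "CM",
                  volume_mean = 900, seed = config$seed + 5)
  ref_d <- filter_diploid(ref); cm_d <- filter_diploid(cm)
  ref_vol <- mean(tapply(ref_d$nucleus_volume, ref_d$cell_id, mean))
  res_ref <- min_pair_distance(ref_d, ref_vol,
                               proximity_thresh = config$fish_proximity_thresh)
  res_cm <- min_pair_distance(cm_d, ref_vol,
                              proximity_thresh = config$fish_proximity_thresh)
  gc <- group_compare(c(res_ref$norm_min, res_cm$norm_min),
                      c(rep("hESC", nrow(res_ref)),
                        rep("CM", nrow(res_cm))))
  logf("FISH proximity: hESC=%.3f CM=%.3f (rank-sum p=%.3g)",
       proximity_fraction(res_ref)$fraction,
       proximity_fraction(res_cm)$fraction, gc$p)
  utils::write.csv(rbind(cbind(condition = "hESC", res_ref),
                         cbind(condition = "CM", res_cm)),
                   file.path(config$out_dir, "fish_distances.csv"),
                   row.names = FALSE)

  # --- manifest ----------------------------------------------------------
  outs <- setdiff(list.files(config$out_dir, full.names = TRUE),
                  file.path(config$out_dir, "manifest.tsv"))
  manifest <- data.frame(file = basename(outs),
                         md5 = unname(tools::md5sum(outs)))
  mpath <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(switches = sw, compartment_fraction = frac,
                 boundary_comparison = cmp, permutation = perm,
                 fish = list(hESC = res_ref, CM = res_cm, test = gc),
                 manifest = mpath))
}

#' Pool replicate contact maps
#'
#' Entry-wise mean of the maps' values; a bin masked in any input is
#' masked in the pool.
#'
#' @param maps list of `contact_map`s on the same bin table (all raw or
#'   all balanced).
#' @return a pooled `contact_map`.
#' @export
pool_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  M <- as_dense(maps[[1]], apply_mask = FALSE)
  for (k in seq_along(maps)[-1]) {
    stopifnot(n_bins(maps[[k]]$bins) == nrow(M))
    M <- M + as_dense(maps[[k]], apply_mask = FALSE)
  }
  w <- maps[[1]]$weights
  if (length(maps) > 1) for (k in seq_along(maps)[-1]) {
    wk <- maps[[k]]$weights
    if (!is.null(wk) && !is.null(w)) w[is.na(wk)] <- NA
  }
  dense_to_map(M / length(maps), maps[[1]]$bins, weights = w,
               balanced = maps[[1]]$balanced,
               normalization = maps[[1]]$normalization)
}
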