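#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running the whole simulator: genome, planted truth,
#' annotations, array replicates, sequencing fragments and (optionally)
#' chromatin marks and staged expression, all from one seed.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @param n_replicates,n_control array replicate counts.
#' @param include_marks,include_stages simulate mark tracks / staged
#'   expression (switch off to save time when not needed).
#' @return named list with `genome`, `truth`, `genes`, `repeats`, `array`,
#'   `seq`, and optionally `marks`, `stages`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L,
                             n_replicates = 3, n_control = 1,
                             include_marks = FALSE,
                             include_stages = FALSE) {
  genome <- build_genome(config)
  truth <- plant_truth(genome, config, seed = seed)
  ann <- annotate_genome(genome, truth, config, seed = seed + 1L)
  arr <- simulate_array(truth, genome, config, n_replicates = n_replicates,
                        n_control = n_control, seed = seed + 2L)
  frags <- simulate_seq(truth, genome, config, seed = seed + 3L)
  out <- list(genome = genome, truth = truth, genes = ann$genes,
              repeats = ann$repeats, array = arr, seq = frags)
  if (include_marks)
    out$marks <- simulate_marks(truth, ann$genes, genome, config,
                                seed = seed + 4L)
  if (include_stages)
    out$stages <- simulate_expression_stages(ann$genes, truth, genome,
                                             config, seed = seed + 5L)
  out
}

#' Normalize and call on the tiling-array platform
#'
#' GC-normalizes each replicate, combines replicates by pooled 300-bp
#' windowed medians, binarizes, averages in 200-probe windows sliding one
#' probe, and thresholds strictly at the array threshold; positive windows
#' are merged into candidate regions. The control-antibody track runs
#' through the identical path to give the empirical false-discovery ratio.
#'
#' @param arr output of [simulate_array()] (or a compatible list with
#'   `probes`, `ip`, `control`).
#' @param params an [analysis_params()].
#' @param gc_bins GC strata for normalization.
#' @param smooth_bp replicate-pooling window in bp.
#' @return list with the combined `ip_track` and `control_track`, the
#'   window score sets, `positives`, merged `regions`, and `fdr` (control
#'   positives / IP positives at the default threshold).
#' @export
array_pipeline <- function(arr, params = analysis_params(), gc_bins = 10,
                           smooth_bp = 300) {
  ip <- combine_replicates(lapply(arr$ip, normalize_gc, probes = arr$probes,
                                  gc_bins = gc_bins), smooth_bp)
  ctl <- combine_replicates(lapply(arr$control, normalize_gc,
                                   probes = arr$probes, gc_bins = gc_bins),
                            smooth_bp)
  ws_ip <- window_scores(binarize(ip), "array", params)
  ws_ctl <- window_scores(binarize(ctl), "array", params)
  pos <- call_windows(ws_ip, params$array_threshold)
  n_ctl <- nrow(call_windows(ws_ctl, params$array_threshold))
  list(ip_track = ip, control_track = ctl,
       windows_ip = ws_ip, windows_control = ws_ctl, positives = pos,
       regions = merge_regions(pos, params$min_overlap),
       fdr = if (nrow(pos) > 0) n_ctl / nrow(pos) else NA_real_)
}

#' Normalize and call on the sequencing platform
#'
#' Builds extended-fragment base-count tracks for IP and control, downsamples
#' the input library to each ChIP's fragment count, subtracts, z-scores
#' genome-wide, smooths in 300-bp windows at the grid offset, binarizes
#' (ties to -1), averages in 10-kb windows, and thresholds strictly at the
#' sequencing threshold.
#'
#' @param frags output of [simulate_seq()] (list `ip`, `control`, `input`).
#' @param genome a [build_genome()] result.
#' @param params an [analysis_params()].
#' @param seed seed for the input downsampling.
#' @param smooth_bp z-score smoothing window in bp.
#' @return list with `ip_track` and `control_track` (smoothed z), window
#'   score sets, `positives`, merged `regions`, and `fdr`.
#' @export
seq_pipeline <- function(frags, genome, params = analysis_params(),
                         seed = 1L, smooth_bp = 300) {
  ext <- params$extension_ip
  gs <- params$seq_offset
  zt <- function(chip, nth_seed) {
    cov <- coverage_from_fragments(chip, ext, genome, gs)
    n <- min(nrow(frags$input), nrow(chip))
    ds <- downsample(frags$input, n, seed = nth_seed)
    cov_in <- coverage_from_fragments(ds, ext, genome, gs)
    slide_average(subtract_zscore(cov, cov_in), smooth_bp, gs)
  }
  z_ip <- zt(frags$ip, seed)
  z_ctl <- zt(frags$control, seed + 1L)
  ws_ip <- window_scores(binarize(z_ip), "seq", params)
  ws_ctl <- window_scores(binarize(z_ctl), "seq", params)
  pos <- call_windows(ws_ip, params$seq_threshold)
  n_ctl <- nrow(call_windows(ws_ctl, params$seq_threshold))
  list(ip_track = z_ip, control_track = z_ctl,
       windows_ip = ws_ip, windows_control = ws_ctl, positives = pos,
       regions = merge_regions(pos, params$min_overlap),
       fdr = if (nrow(pos) > 0) n_ctl / nrow(pos) else NA_real_)
}

#' Cross-validate platforms and derive the subdomain/gap tiling
#'
#' @param array_regions,seq_regions candidate regions from
#'   [array_pipeline()] and [seq_pipeline()].
#' @param genome a [build_genome()] result.
#' @param params an [analysis_params()].
#' @return list with `subdomains`, classified `gaps`, the arm/`centers`
#'   partition, and per-chromosome `occupancy`.
#' @export
call_subdomains <- function(array_regions, seq_regions, genome,
                            params = analysis_params()) {
  subs <- cross_validate(array_regions, seq_regions)
  # window extents run to "last element + grid step", which can poke past
  # the final probe's chromosome end; truncate at the assembly bounds
  if (nrow(subs)) {
    subs$end <- pmin(subs$end, genome_length(genome, subs$chrom))
    subs <- subs[subs$end > subs$start, , drop = FALSE]
  }
  gaps <- classify_gaps(derive_gaps(subs, genome), params)
  list(subdomains = subs, gaps = gaps,
       centers = define_centers(gaps, genome),
       occupancy = occupancy(subs, genome))
}
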