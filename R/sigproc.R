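# ---- tiling-array processing --------------------------------------------

#' GC-stratified robust standardization of per-probe log-ratios
#'
#' Approximates GC-model array normalization: probes are stratified into GC
#' bins (quantile bins of the GC fraction) and, within each bin, scores are
#' centered by the bin median and scaled by the bin MAD (scaled to be
#' SD-consistent). Bins whose MAD is zero fall back to the global MAD; if
#' that is also zero the scale is 1, so constant input maps to all zeros.
#'
#' @param raw a log-ratio [signal_track()] with one score per probe.
#' @param probes the matching [probe_set()].
#' @param gc_bins number of GC strata (>= 1).
#' @return a normalized [signal_track()] on the same layout.
#' @export
normalize_gc <- function(raw, probes, gc_bins = 10) {
  stopifnot(gc_bins >= 1)
  if (nrow(raw) != nrow(probes) ||
      !all(raw$chrom == probes$chrom & raw$pos == probes$pos))
    stop("probe/score layout mismatch")
  x <- raw$score
  br <- unique(stats::quantile(probes$gc, probs = seq(0, 1, length.out = gc_bins + 1),
                               names = FALSE))
  bin <- if (length(br) > 2)
    cut(probes$gc, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(x))
  gscale <- stats::mad(x, na.rm = TRUE)
  out <- x
  for (b in unique(bin)) {
    sel <- which(bin == b)
    med <- stats::median(x[sel], na.rm = TRUE)
    sc <- stats::mad(x[sel], na.rm = TRUE)
    if (!is.finite(sc) || sc == 0) sc <- gscale
    if (!is.finite(sc) || sc == 0) sc <- 1
    out[sel] <- (x[sel] - med) / sc
  }
  signal_track(raw$chrom, raw$pos, out, kind = "normalized",
               step = track_step(raw))
}

#' Median smoothing over bp-delimited sliding windows
#'
#' Each position's score is replaced by the median of all scores at
#' positions within `window_bp / 2` on either side (an isolated probe keeps
#' its own value). Output stays aligned to the input positions.
#'
#' @param track a [signal_track()].
#' @param window_bp window size in bp.
#' @return a smoothed [signal_track()].
#' @export
median_smooth <- function(track, window_bp = 300) {
  track_by_chrom(track, function(pos, score, chrom) {
    data.frame(chrom = chrom, pos = pos,
               score = cpp_window_median(pos, as.matrix(score), window_bp / 2))
  }, kind = "normalized")
}

#' Combine replicate tracks by pooled windowed medians
#'
#' Per position, takes the median over the pooled multiset of all
#' replicates' scores at positions within `window_bp / 2`, reproducing how
#' replicate arrays are merged into a single smoothed score. A single
#' replicate reduces to [median_smooth()].
#'
#' @param replicates list of [signal_track()]s sharing one probe layout.
#' @param window_bp pooling window in bp.
#' @return a combined [signal_track()].
#' @export
combine_replicates <- function(replicates, window_bp = 300) {
  stopifnot(length(replicates) >= 1)
  ref <- replicates[[1]]
  for (r in replicates[-1])
    if (nrow(r) != nrow(ref) || !all(r$chrom == ref$chrom & r$pos == ref$pos))
      stop("replicates must share the probe layout")
  scores <- do.call(cbind, lapply(replicates, function(r) r$score))
  out <- ref
  for (cc in unique(ref$chrom)) {
    sel <- which(ref$chrom == cc)
    out$score[sel] <- cpp_window_median(ref$pos[sel],
                                        scores[sel, , drop = FALSE],
                                        window_bp / 2)
  }
  signal_track(out$chrom, out$pos, out$score, kind = "normalized",
               step = track_step(ref))
}

# ---- sequencing processing ----------------------------------------------

fragment_intervals <- function(fragments, extension_bp, genome) {
  L <- genome_length(genome, fragments$chrom)
  if (any(fragments$pos < 0 | fragments$pos >= L))
    stop("fragment outside chromosome bounds")
  plus <- fragments$strand == "+"
  s <- ifelse(plus, fragments$pos, fragments$pos - extension_bp + 1)
  e <- ifelse(plus, fragments$pos + extension_bp, fragments$pos + 1)
  data.frame(chrom = fragments$chrom, start = pmax(0, s), end = pmin(L, e),
             stringsAsFactors = FALSE)
}

#' Base-count coverage of extended fragments, sampled on a regular grid
#'
#' Each fragment is extended to `extension_bp` in its strand direction
#' (plus-strand rightward from its start, minus-strand leftward from its
#' reported 3'-most coordinate), clipped at chromosome ends, and the number
#' of extended fragments overlapping each grid base is counted.
#'
#' @param fragments a stranded fragment set (`chrom`, `pos`, `strand`).
#' @param extension_bp extension length in bp (>= 1).
#' @param genome a [build_genome()] result.
#' @param grid_step grid spacing in bp (1 gives true per-base counts).
#' @return a count [signal_track()] on the regular grid.
#' @export
coverage_from_fragments <- function(fragments, extension_bp, genome,
                                    grid_step = 50) {
  stopifnot(extension_bp >= 1)
  iv <- fragment_intervals(fragments, extension_bp, genome)
  chrom <- pos <- score <- list()
  for (i in seq_len(nrow(genome))) {
    cc <- genome$chrom[i]; L <- genome$length[i]
    grid <- seq(0, L - 1, by = grid_step)
    sel <- iv$chrom == cc & iv$end > iv$start
    if (any(sel)) {
      cov <- IRanges::coverage(
        IRanges::IRanges(start = iv$start[sel] + 1, end = iv$end[sel]),
        width = L)
      vals <- as.integer(cov)[grid + 1]
    } else vals <- integer(length(grid))
    chrom[[i]] <- rep(cc, length(grid)); pos[[i]] <- grid; score[[i]] <- vals
  }
  signal_track(unlist(chrom), unlist(pos), unlist(score), kind = "count",
               step = grid_step)
}

#' Downsample a fragment set without replacement
#'
#' @param fragments a fragment set.
#' @param n number of fragments to keep (0 <= n <= nrow).
#' @param seed integer RNG seed; the selection is seed-reproducible.
#' @return a fragment set of `n` fragments.
#' @export
downsample <- function(fragments, n, seed = 1L) {
  if (n < 0 || n > nrow(fragments))
    stop("n must be between 0 and the number of fragments")
  set.seed(seed)
  keep <- sort(sample.int(nrow(fragments), n))
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(fragments)
  out
}

#' Input subtraction and genome-wide z-scoring
#'
#' Subtracts the input base-count from the IP base-count at each grid
#' position and standardizes the difference by its own genome-wide mean and
#' population SD: `z = (count - mean) / SD`. The output has mean 0 and SD 1
#' by construction.
#'
#' @param ip,input count [signal_track()]s on identical grids.
#' @return a z-score [signal_track()].
#' @export
subtract_zscore <- function(ip, input) {
  if (nrow(ip) != nrow(input) ||
      !all(ip$chrom == input$chrom & ip$pos == input$pos))
    stop("ip and input must share an identical grid")
  d <- ip$score - input$score
  mu <- mean(d)
  sdv <- sqrt(mean((d - mu)^2))
  if (!is.finite(sdv) || sdv == 0)
    stop("degenerate input: difference track has zero SD")
  out <- signal_track(ip$chrom, ip$pos, (d - mu) / sdv, kind = "zscore",
                      step = track_step(ip))
  # z-value of a zero count difference; count data put an atom of exact
  # ties there, and binarization must send that atom to -1 (see binarize)
  attr(out, "zero_z") <- -mu / sdv
  out
}

#' Sliding windowed mean onto a regular offset grid
#'
#' Reports, at each offset-spaced position, the mean of scores at positions
#' within `window_bp / 2` on either side. Windows containing no finite
#' value are missing (`NA`), never 0.
#'
#' @param track a [signal_track()] (gridded or probe-based).
#' @param window_bp window size in bp.
#' @param offset_bp spacing of output positions in bp (must not exceed
#'   `window_bp`).
#' @return a [signal_track()] on the regular `offset_bp` grid.
#' @export
slide_average <- function(track, window_bp = 300, offset_bp = 50) {
  if (offset_bp > window_bp) stop("offset_bp must not exceed window_bp")
  out <- track_by_chrom(track, function(pos, score, chrom) {
    q <- seq(offset_bp * floor(min(pos) / offset_bp),
             offset_bp * ceiling(max(pos) / offset_bp), by = offset_bp)
    data.frame(chrom = chrom, pos = q,
               score = cpp_window_mean(pos, score, q, window_bp / 2))
  }, kind = "zscore", step = offset_bp)
  # averaging is linear, so the zero-difference point is unchanged
  attr(out, "zero_z") <- attr(track, "zero_z")
  out
}

#' Non-overlapping bin means for visualization
#'
#' Averages scores within non-overlapping `bin_bp` bins; the trailing
#' partial bin is reported (as the mean of its members), not dropped, so
#' the output preserves genome coverage.
#'
#' @param track a [signal_track()].
#' @param bin_bp bin size in bp.
#' @return a binned [signal_track()] positioned at bin starts.
#' @export
bin_mean <- function(track, bin_bp = 5000) {
  track_by_chrom(track, function(pos, score, chrom) {
    b <- floor(pos / bin_bp)
    agg <- tapply(score, b, function(v) mean(v, na.rm = TRUE))
    data.frame(chrom = chrom, pos = as.numeric(names(agg)) * bin_bp,
               score = as.numeric(agg))
  }, kind = "binned", step = bin_bp)
}
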