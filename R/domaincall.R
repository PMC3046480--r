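# ---- binarized window calling -------------------------------------------

#' Binarize a score track
#'
#' Positive scores map to +1 and non-positive scores to -1 (a score of
#' exactly 0 is treated as non-associated); missing stays missing.
#'
#' Input-subtracted count tracks (from [subtract_zscore()], possibly
#' smoothed) carry the z-value of a zero count difference. Count data put
#' an atom of exact ties at that point, and whether it sits a hair above or
#' below z = 0 is decided only by the sampling sign of the genome-wide
#' mean; the tie rule therefore bounds the positive class at the
#' zero-difference point as well, so a non-positive count difference always
#' binarizes to -1. Tracks above their genome mean everywhere outside true
#' signal (the usual IP situation) are unaffected, since there the
#' zero-difference point lies below z = 0.
#'
#' @param track a [signal_track()].
#' @return a binary [signal_track()] with values in `{+1, -1, NA}`.
#' @export
binarize <- function(track) {
  z0 <- attr(track, "zero_z")
  thr <- if (is.null(z0) || !is.finite(z0)) 0 else max(0, z0)
  signal_track(track$chrom, track$pos,
               ifelse(is.na(track$score), NA_real_,
                      ifelse(track$score > thr, 1, -1)),
               kind = "binary", step = track_step(track))
}

#' Average binarized values in sliding windows
#'
#' Array mode slides a window of `array_window` probes by `array_offset`
#' probes; sequencing mode slides a window of `seq_window` bp (converted to
#' grid elements) by `seq_offset` bp. The window mean is taken over
#' non-missing binarized values; windows with more than `max_missing`
#' missing values are flagged and excluded from calling. A window's genomic
#' extent is `[first element position, last element position + grid step)`.
#' Chromosomes shorter than one window yield no windows.
#'
#' @param binary a binary [signal_track()] from [binarize()].
#' @param mode `"array"` or `"seq"`.
#' @param params an [analysis_params()].
#' @return an object of class `window_scores`: data frame with `chrom`,
#'   `start`, `end`, `mean`, `flagged`, plus windowing metadata attributes.
#' @export
window_scores <- function(binary, mode = c("array", "seq"), params) {
  mode <- match.arg(mode)
  step <- track_step(binary)
  if (is.null(step)) stop("binary track must carry its grid step")
  if (mode == "array") {
    n <- params$array_window; by <- params$array_offset
  } else {
    n <- round(params$seq_window / step)
    by <- max(1L, round(params$seq_offset / step))
  }
  pieces <- lapply(split(seq_len(nrow(binary)), binary$chrom), function(idx) {
    v <- binary$score[idx]; pos <- binary$pos[idx]
    m <- length(v)
    if (m < n) return(NULL)
    cs <- cumsum(c(0, ifelse(is.na(v), 0, v)))
    cn <- cumsum(c(0, !is.na(v)))
    i <- seq(1, m - n + 1, by = by)
    cnt <- cn[i + n] - cn[i]
    data.frame(chrom = binary$chrom[idx][1],
               start = pos[i], end = pos[i + n - 1] + step,
               mean = ifelse(cnt > 0, (cs[i + n] - cs[i]) / cnt, NA_real_),
               flagged = (n - cnt) / n > params$max_missing,
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  ws <- if (length(pieces))
    do.call(rbind, c(unname(pieces), make.row.names = FALSE))
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  mean = numeric(0), flagged = logical(0))
  structure(ws, class = c("window_scores", "data.frame"),
            platform = mode, window = n, offset = by, step = step)
}

#' Select positive windows at a strict threshold
#'
#' A window is positive when its binary mean is strictly greater than the
#' threshold ("over" 0.8 or 0.4); flagged windows never qualify.
#'
#' @param ws a [window_scores()] result.
#' @param threshold strict threshold in (-1, 1).
#' @return the positive subset, same class.
#' @export
call_windows <- function(ws, threshold) {
  stopifnot(threshold > -1, threshold < 1)
  out <- ws[!ws$flagged & !is.na(ws$mean) & ws$mean > threshold, , drop = FALSE]
  rownames(out) <- NULL
  a <- attributes(ws)
  structure(out, class = class(ws), platform = a$platform,
            window = a$window, offset = a$offset, step = a$step)
}

#' Empirical false-discovery-ratio curve
#'
#' For each threshold, the ratio of the number of positive control-antibody
#' windows to the number of positive IP windows, both built with identical
#' windowing. Thresholds with zero positive IP windows are flagged
#' undefined.
#'
#' @param ip,control [window_scores()] built with the same windowing.
#' @param thresholds numeric vector of thresholds.
#' @return data frame with `threshold`, `ip_positive`, `control_positive`,
#'   `ratio`, `undefined`.
#' @export
fdr_curve <- function(ip, control, thresholds) {
  if (!identical(attr(ip, "window"), attr(control, "window")) ||
      !identical(attr(ip, "offset"), attr(control, "offset")))
    stop("ip and control must use identical windowing")
  res <- lapply(thresholds, function(th) {
    nip <- nrow(call_windows(ip, th))
    nct <- nrow(call_windows(control, th))
    data.frame(threshold = th, ip_positive = nip, control_positive = nct,
               ratio = if (nip > 0) nct / nip else NA_real_,
               undefined = nip == 0)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Merge overlapping positive windows into candidate regions
#'
#' Joins windows sharing at least `min_overlap_bp` of genuine overlap
#' (transitively); abutting windows with zero overlap are not merged.
#'
#' @param positives positive [window_scores()] (or any interval data frame).
#' @param min_overlap_bp minimum overlap in bp.
#' @return an [interval_set()] of disjoint, sorted candidate regions.
#' @export
merge_regions <- function(positives, min_overlap_bp = 1) {
  if (nrow(positives) == 0) return(interval_set())
  merged <- lapply(split(positives, positives$chrom), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    s <- df$start; e <- df$end
    run_end <- cummax(e)
    # new component when the window overlaps the running region < min bp
    new_comp <- c(TRUE, s[-1] > run_end[-length(e)] - min_overlap_bp)
    grp <- cumsum(new_comp)
    data.frame(chrom = df$chrom[1],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max))
  })
  df <- do.call(rbind, c(unname(merged), make.row.names = FALSE))
  interval_set(df$chrom, df$start, df$end, label = "subdomain")
}

#' Cross-platform validation of called regions
#'
#' Regions of either platform with no >= 1 bp overlap in the other platform
#' are discarded; each connected overlap component of the remainder is
#' merged into one subdomain spanning the union of its members.
#'
#' @param array_regions,seq_regions [interval_set()]s of candidate regions.
#' @return an [interval_set()] of subdomains.
#' @export
cross_validate <- function(array_regions, seq_regions) {
  ka <- overlaps_any(array_regions, seq_regions)
  ks <- overlaps_any(seq_regions, array_regions)
  pool <- rbind(as.data.frame(array_regions)[ka, c("chrom", "start", "end")],
                as.data.frame(seq_regions)[ks, c("chrom", "start", "end")])
  if (nrow(pool) == 0) return(interval_set())
  merge_regions(pool, min_overlap_bp = 1)
}

#' Derive gaps as the per-chromosome complement of subdomains
#'
#' Subdomains and gaps of each chromosome tile it exactly. Gaps abutting a
#' chromosome end carry the terminal flag.
#'
#' @param subdomains an [interval_set()] of subdomains.
#' @param genome a [build_genome()] result.
#' @return an [interval_set()] of gaps.
#' @export
derive_gaps <- function(subdomains, genome) {
  out <- list()
  for (i in seq_len(nrow(genome))) {
    cc <- genome$chrom[i]; L <- genome$length[i]
    sub <- subdomains[subdomains$chrom == cc, , drop = FALSE]
    if (any(sub$start < 0 | sub$end > L))
      stop("subdomain outside chromosome bounds on ", cc)
    bounds <- c(0, as.vector(rbind(sub$start, sub$end)), L)
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    keep <- e > s
    if (!any(keep)) next
    out[[cc]] <- data.frame(chrom = cc, start = s[keep], end = e[keep],
                            terminal = s[keep] == 0 | e[keep] == L)
  }
  if (!length(out)) return(interval_set(label = "gap"))
  df <- do.call(rbind, c(unname(out), make.row.names = FALSE))
  interval_set(df$chrom, df$start, df$end, label = "gap",
               terminal = df$terminal)
}

#' Classify gaps by length
#'
#' Left-closed classes at the configured cutoffs: S `[0, 10 kb)`,
#' M `[10 kb, 100 kb)`, L `[100 kb, 1 Mb)`, XL `[1 Mb, Inf)`.
#'
#' @param gaps an [interval_set()] of gaps.
#' @param params an [analysis_params()].
#' @return the gaps with `size_class` filled in.
#' @export
classify_gaps <- function(gaps, params = analysis_params()) {
  len <- gaps$end - gaps$start
  cls <- c("S", "M", "L", "XL")[findInterval(len, params$gap_cutoffs) + 1]
  gaps$size_class <- cls
  gaps
}

#' Partition chromosomes into arms and centers
#'
#' Every XL gap is a center segment; the remainder of each chromosome is
#' arm. Used to restrict subdomain-vs-gap statistics to the arm context.
#'
#' @param gaps classified gaps from [classify_gaps()].
#' @param genome a [build_genome()] result.
#' @return data frame with `chrom`, `start`, `end`, `part` (`"arm"`/`"center"`).
#' @export
define_centers <- function(gaps, genome) {
  centers <- gaps[!is.na(gaps$size_class) & gaps$size_class == "XL", ,
                  drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genome))) {
    cc <- genome$chrom[i]; L <- genome$length[i]
    ctr <- centers[centers$chrom == cc, , drop = FALSE]
    bounds <- c(0, as.vector(rbind(ctr$start, ctr$end)), L)
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    arm <- data.frame(chrom = cc, start = s[e > s], end = e[e > s],
                      part = "arm")
    ctr2 <- if (nrow(ctr))
      data.frame(chrom = cc, start = ctr$start, end = ctr$end, part = "center")
    else NULL
    out[[cc]] <- rbind(arm, ctr2)
  }
  df <- do.call(rbind, c(unname(out), make.row.names = FALSE))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-chromosome subdomain occupancy
#'
#' @param subdomains an [interval_set()].
#' @param genome a [build_genome()] result.
#' @return data frame with `chrom`, `size_mb`, and `occupancy_pct`
#'   (100 x covered bp / chromosome length).
#' @export
occupancy <- function(subdomains, genome) {
  cov <- vapply(seq_len(nrow(genome)), function(i) {
    sub <- subdomains[subdomains$chrom == genome$chrom[i], , drop = FALSE]
    if (any(sub$start < 0 | sub$end > genome$length[i]))
      stop("subdomain outside chromosome bounds")
    sum(sub$end - sub$start)
  }, numeric(1))
  data.frame(chrom = genome$chrom, size_mb = genome$length / 1e6,
             occupancy_pct = 100 * cov / genome$length,
             stringsAsFactors = FALSE)
}

#' Base-level Jaccard index between two interval sets
#'
#' @param a,b interval data frames (`chrom`, `start`, `end`).
#' @return intersection bases over union bases (1 when both are empty).
#' @export
interval_jaccard <- function(a, b) {
  wa <- sum(a$end - a$start); wb <- sum(b$end - b$start)
  if (wa == 0 && wb == 0) return(1)
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}
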