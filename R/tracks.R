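#' Construct a signal track
#'
#' A signal track is a long-format data frame of per-position scores, one
#' row per probe or grid point, sorted by chromosome and position, with the
#' score kind and (for regular grids) the grid step carried as attributes.
#'
#' @param chrom character vector of chromosome names.
#' @param pos numeric positions (bp, 0-based).
#' @param score numeric scores; `NA` marks missing.
#' @param kind score kind, one of `"log-ratio"`, `"normalized"`,
#'   `"zscore"`, `"count"`, `"binned"`, `"binary"`, `"mark"`.
#' @param step grid step in bp for regular grids (probe spacing for arrays).
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(chrom, pos, score, kind = "log-ratio", step = NULL) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(score))
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  o <- order(df$chrom, df$pos)
  if (is.unsorted(o)) df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("signal_track", "data.frame"),
            kind = kind, step = step)
}

track_kind <- function(x) attr(x, "kind")
track_step <- function(x) attr(x, "step")

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track [%s]: %d positions on %d chromosome(s)%s\n",
              attr(x, "kind"), nrow(x), length(unique(x$chrom)),
              if (!is.null(attr(x, "step")))
                sprintf(", %g-bp grid", attr(x, "step")) else ""))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# apply f(pos, score, chrom) per chromosome and re-assemble a signal_track,
# preserving kind/step unless overridden
track_by_chrom <- function(track, f, kind = track_kind(track),
                           step = track_step(track)) {
  pieces <- lapply(split(seq_len(nrow(track)), track$chrom), function(idx) {
    f(track$pos[idx], track$score[idx], track$chrom[idx][1])
  })
  pieces <- pieces[lengths(pieces) > 0]
  df <- if (length(pieces))
    do.call(rbind, c(unname(pieces), make.row.names = FALSE))
  else data.frame(chrom = character(0), pos = numeric(0),
                  score = numeric(0))
  signal_track(df$chrom, df$pos, df$score, kind = kind, step = step)
}

#' Construct a probe set
#'
#' @param chrom,pos probe chromosome and center coordinate (bp).
#' @param gc per-probe GC fraction in `[0, 1]`.
#' @param unique logical uniqueness flag (repeat-overlapping probes are
#'   non-unique and masked from sliding-window analyses, though not from
#'   subdomain calling).
#' @return an object of class `probe_set`.
#' @export
probe_set <- function(chrom, pos, gc, unique = TRUE) {
  stopifnot(all(gc >= 0 & gc <= 1))
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   gc = as.numeric(gc),
                   unique = rep_len(as.logical(unique), length(pos)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  for (cc in split(df$pos, df$chrom))
    if (anyDuplicated(cc) || is.unsorted(cc, strictly = TRUE))
      stop("probe coordinates must be strictly increasing per chromosome")
  rownames(df) <- NULL
  structure(df, class = c("probe_set", "data.frame"))
}

#' Construct an interval set
#'
#' Sorted, disjoint, labeled half-open intervals: subdomains, or gaps with a
#' size class and a terminal flag for intervals abutting a chromosome end.
#'
#' @param chrom,start,end interval coordinates (bp, 0-based half-open).
#' @param label `"subdomain"` or `"gap"`.
#' @param size_class gap size class (`"S"`, `"M"`, `"L"`, `"XL"`) or `NA`.
#' @param terminal logical: interval touches a chromosome end.
#' @return an object of class `interval_set`.
#' @export
interval_set <- function(chrom = character(0), start = numeric(0),
                         end = numeric(0), label = "subdomain",
                         size_class = NA_character_, terminal = FALSE) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep_len(label, length(start)),
                   size_class = rep_len(as.character(size_class), length(start)),
                   terminal = rep_len(terminal, length(start)),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("intervals must satisfy start < end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (idx in split(seq_len(nrow(df)), df$chrom)) {
    if (length(idx) > 1 &&
        any(df$start[idx][-1] < df$end[idx][-length(idx)]))
      stop("intervals must be disjoint within a chromosome")
  }
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d interval(s), %.2f Mb total\n",
              nrow(x), sum(x$end - x$start) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

# conversions between the package's 0-based half-open intervals and
# 1-based closed GRanges, applied only at the GenomicRanges boundary
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

from_granges0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# total bases of `a` covered by the union of `b`, per row of `a`
covered_bases <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) return(numeric(nrow(a)))
  ga <- as_granges0(a)
  gb <- GenomicRanges::reduce(as_granges0(b))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  ov <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                  gb[S4Vectors::subjectHits(hits)])
  out <- numeric(nrow(a))
  if (length(hits))
    out <- out + as.numeric(tapply(GenomicRanges::width(ov),
                                   factor(S4Vectors::queryHits(hits),
                                          levels = seq_len(nrow(a))),
                                   sum, default = 0))
  out[is.na(out)] <- 0
  out
}

# TRUE for rows of `a` overlapping any row of `b` by >= 1 bp
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  IRanges::overlapsAny(as_granges0(a), as_granges0(b))
}
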