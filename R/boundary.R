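meta_profile <- function(offset, mean, n, ci = NA_real_) {
  structure(data.frame(offset = offset, mean = mean, n = n, ci = ci),
            class = c("meta_profile", "data.frame"))
}

#' Mask non-unique probes from a track
#'
#' Sliding-window analyses use only unique probes; probes flagged
#' non-unique have their scores set to missing (calling, by contrast, uses
#' every probe).
#'
#' @param track a [signal_track()] on the probe layout.
#' @param probes the matching [probe_set()].
#' @return the masked [signal_track()].
#' @export
mask_nonunique <- function(track, probes) {
  if (nrow(track) != nrow(probes) ||
      !all(track$chrom == probes$chrom & track$pos == probes$pos))
    stop("probe/track layout mismatch")
  sc <- ifelse(probes$unique, track$score, NA_real_)
  signal_track(track$chrom, track$pos, sc, kind = track_kind(track),
               step = track_step(track))
}

#' Deduplicate transcripts sharing identical coordinates
#'
#' Keeps one transcript per exact (chromosome, start, end, strand) key,
#' giving the non-redundant coding-sequence set used for translation-start
#' analyses.
#'
#' @param genes a `gene_table`.
#' @return the deduplicated `gene_table`.
#' @export
nonredundant_genes <- function(genes) {
  key <- paste(genes$chrom, genes$start, genes$end, genes$strand)
  out <- genes[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select subdomain-gap boundaries for metaplot analyses
#'
#' One boundary per subdomain left edge; subdomains whose left edge touches
#' a chromosome start are excluded (their "gap side" does not exist). The
#' usable gap-side flank is the full default flank unless the adjoining gap
#' is shorter than the small-gap limit, in which case it is the gap length;
#' the subdomain-side flank is capped at the subdomain length.
#'
#' @param subdomains,gaps tiling [interval_set()]s from the caller.
#' @param params an [analysis_params()].
#' @return an object of class `boundary_set`: data frame with `chrom`,
#'   `pos`, `gap_side`, `gap_flank`, `sub_flank`, `gap_len`.
#' @export
select_boundaries <- function(subdomains, gaps, params = analysis_params()) {
  sub <- as.data.frame(subdomains)
  keep <- sub$start > 0
  sub <- sub[keep, , drop = FALSE]
  gkey <- paste(gaps$chrom, gaps$end)
  gi <- match(paste(sub$chrom, sub$start), gkey)
  gap_len <- ifelse(is.na(gi), 0, gaps$end[gi] - gaps$start[gi])
  gap_flank <- ifelse(gap_len < params$small_gap_flank, gap_len,
                      params$boundary_flank)
  out <- data.frame(chrom = sub$chrom, pos = sub$start, gap_side = "left",
                    gap_flank = gap_flank,
                    sub_flank = pmin(params$boundary_flank,
                                     sub$end - sub$start),
                    gap_len = gap_len, stringsAsFactors = FALSE)
  structure(out, class = c("boundary_set", "data.frame"))
}

# signed boundary-relative coordinate: gap side negative, the boundary
# coordinate itself (offset 0) on the subdomain side
boundary_rel <- function(pos, boundary_pos, gap_side) {
  (pos - boundary_pos) * ifelse(gap_side == "left", 1, -1)
}

profile_offsets <- function(flank_bp, window_bp, offset_bp) {
  seq(-flank_bp + window_bp / 2, flank_bp - window_bp / 2, by = offset_bp)
}

# assemble a profile from a boundaries x offsets matrix with NA marking
# non-contributing cells
profile_from_matrix <- function(m, offsets) {
  n <- colSums(!is.na(m))
  mu <- suppressWarnings(colMeans(m, na.rm = TRUE))
  mu[n == 0] <- NA_real_
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * sdv / sqrt(n), NA_real_)
  meta_profile(offsets, mu, n, ci)
}

#' Feature-count metaprofile across boundaries
#'
#' Counts point features (repeat centers, translation starts) within
#' sliding windows at offsets relative to each boundary, with the gap side
#' at negative offsets, then averages over the boundaries contributing at
#' each offset. A boundary contributes at an offset only where the window
#' lies within its usable flanks.
#'
#' @param points data frame with `chrom` and `pos` (single coordinates).
#' @param boundaries a [select_boundaries()] result.
#' @param window_bp,offset_bp window size and offset (bp).
#' @param flank_bp maximal flank on each side (bp).
#' @return a `meta_profile` data frame (`offset`, `mean`, `n`, `ci`).
#' @export
count_metaplot <- function(points, boundaries, window_bp = 1000,
                           offset_bp = 500, flank_bp = 10e3) {
  if (flank_bp <= 0) stop("flank_bp must be positive")
  offsets <- profile_offsets(flank_bp, window_bp, offset_bp)
  m <- matrix(NA_real_, nrow(boundaries), length(offsets))
  bychrom <- split(points$pos, points$chrom)
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i, ]
    p <- sort(bychrom[[b$chrom]])
    rel <- boundary_rel(p, b$pos, b$gap_side)
    rel <- sort(rel)
    ok <- offsets - window_bp / 2 >= -b$gap_flank &
      offsets + window_bp / 2 <= b$sub_flank
    lo <- findInterval(offsets - window_bp / 2 - 1e-9, rel)
    hi <- findInterval(offsets + window_bp / 2 - 1e-9, rel)
    m[i, ok] <- (hi - lo)[ok]
  }
  profile_from_matrix(m, offsets)
}

#' Signal metaprofile across boundaries
#'
#' Windowed means of a score track at offsets relative to each boundary
#' (gap side negative), averaged across boundaries; windows with no finite
#' value in a boundary's flank are excluded from both numerator and count.
#'
#' @param track a [signal_track()].
#' @param boundaries a [select_boundaries()] result.
#' @param window_bp,offset_bp window size and offset (bp).
#' @param flank_bp maximal flank on each side (bp).
#' @return a `meta_profile` data frame.
#' @export
signal_metaplot <- function(track, boundaries, window_bp = 100,
                            offset_bp = 50, flank_bp = 10e3) {
  offsets <- profile_offsets(flank_bp, window_bp, offset_bp)
  m <- matrix(NA_real_, nrow(boundaries), length(offsets))
  idx <- split(seq_len(nrow(track)), track$chrom)
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i, ]
    ii <- idx[[b$chrom]]
    if (is.null(ii)) next
    ok <- offsets - window_bp / 2 >= -b$gap_flank &
      offsets + window_bp / 2 <= b$sub_flank
    if (!any(ok)) next
    centers <- if (b$gap_side == "left") b$pos + offsets[ok] else
      b$pos - offsets[ok]
    m[i, ok] <- cpp_window_mean(track$pos[ii], track$score[ii], centers,
                                window_bp / 2)
  }
  profile_from_matrix(m, offsets)
}

#' Orientation-split translation-start metaprofiles and traversing genes
#'
#' Splits translation-start count profiles by whether transcription points
#' toward the subdomain or toward the gap at each boundary, and reports the
#' mean number of boundary-traversing gene bodies per boundary for each
#' orientation. Transcripts are deduplicated to the non-redundant set first.
#'
#' @param genes a `gene_table`.
#' @param boundaries a [select_boundaries()] result.
#' @param params an [analysis_params()].
#' @param flank_bp maximal flank on each side (bp).
#' @return list with `profiles` (named list of `meta_profile`s,
#'   `toward_subdomain` / `toward_gap`) and `traversing` (named numeric:
#'   mean traversing genes per boundary per orientation).
#' @export
oriented_gene_metaplot <- function(genes, boundaries,
                                   params = analysis_params(),
                                   flank_bp = 10e3) {
  genes <- nonredundant_genes(genes)
  # for a gap-left boundary the subdomain lies at higher coordinates, so a
  # plus-strand gene transcribes toward the subdomain; mirrored otherwise
  orient_of <- function(strand, gap_side) {
    ifelse((strand == "+") == (gap_side == "left"),
           "toward_subdomain", "toward_gap")
  }
  profiles <- list()
  for (ori in c("toward_subdomain", "toward_gap")) {
    per_b <- lapply(seq_len(nrow(boundaries)), function(i) {
      b <- boundaries[i, ]
      sel <- genes$chrom == b$chrom &
        orient_of(genes$strand, b$gap_side) == ori
      genes$tstart[sel]
    })
    # orientation depends on the boundary, so build the matrix directly
    offsets <- profile_offsets(flank_bp, params$count_window,
                               params$count_offset)
    m <- matrix(NA_real_, nrow(boundaries), length(offsets))
    for (i in seq_len(nrow(boundaries))) {
      b <- boundaries[i, ]
      rel <- sort(boundary_rel(per_b[[i]], b$pos, b$gap_side))
      ok <- offsets - params$count_window / 2 >= -b$gap_flank &
        offsets + params$count_window / 2 <= b$sub_flank
      lo <- findInterval(offsets - params$count_window / 2 - 1e-9, rel)
      hi <- findInterval(offsets + params$count_window / 2 - 1e-9, rel)
      m[i, ok] <- (hi - lo)[ok]
    }
    profiles[[ori]] <- profile_from_matrix(m, offsets)
  }
  trav <- c(toward_subdomain = 0, toward_gap = 0)
  if (nrow(boundaries)) {
    counts <- sapply(seq_len(nrow(boundaries)), function(i) {
      b <- boundaries[i, ]
      cross <- genes$chrom == b$chrom & genes$start < b$pos &
        genes$end > b$pos
      ori <- orient_of(genes$strand, b$gap_side)
      c(sum(cross & ori == "toward_subdomain"),
        sum(cross & ori == "toward_gap"))
    })
    trav <- c(toward_subdomain = mean(counts[1, ]),
              toward_gap = mean(counts[2, ]))
  }
  list(profiles = profiles, traversing = trav)
}

#' Gene-body signal metaprofiles by expression class
#'
#' Filters to non-redundant genes at least `min_gene_length` long whose
#' expanded footprint (transcript start minus 1 kb to end plus 1 kb) does
#' not overlap another gene, forms genome-wide top and bottom expression
#' quantile classes, and computes strand-aware windowed signal means
#' anchored at the transcript start (TSS) and end (TES), with 95%
#' confidence half-widths of 1.96 x SEM across genes.
#'
#' @param track a [signal_track()].
#' @param genes a `gene_table`.
#' @param expression per-gene expression values aligned with `genes` rows
#'   (defaults to `genes$expression`).
#' @param params an [analysis_params()].
#' @param flank_bp profile flank around each anchor (bp).
#' @return nested list: `$TSS` and `$TES`, each with `$top` and `$bottom`
#'   `meta_profile`s; attribute `genes_used` gives class sizes.
#' @export
gene_body_metaplot <- function(track, genes, expression = genes$expression,
                               params = analysis_params(), flank_bp = 2000) {
  stopifnot(length(expression) == nrow(genes))
  genes$.expr <- expression
  genes <- nonredundant_genes(genes)
  genes <- genes[genes$end - genes$start >= params$min_gene_length, ,
                 drop = FALSE]
  if (nrow(genes) > 1) {
    gexp <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(pmax(1, genes$start + 1 - 1000),
                                    genes$end + 1000))
    gbody <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
    nov <- GenomicRanges::countOverlaps(gexp, gbody)
    genes <- genes[nov <= 1, , drop = FALSE]  # self only
  }
  qs <- stats::quantile(genes$.expr, c(params$expr_quantile,
                                       1 - params$expr_quantile),
                        names = FALSE)
  classes <- list(top = genes[genes$.expr >= qs[2], , drop = FALSE],
                  bottom = genes[genes$.expr <= qs[1], , drop = FALSE])
  for (nm in names(classes))
    if (nrow(classes[[nm]]) < 2)
      stop("fewer than 2 genes in the ", nm, " expression class")
  offsets <- profile_offsets(flank_bp, params$signal_window,
                             params$signal_offset)
  idx <- split(seq_len(nrow(track)), track$chrom)
  one <- function(g, anchor) {
    m <- matrix(NA_real_, nrow(g), length(offsets))
    for (i in seq_len(nrow(g))) {
      ii <- idx[[g$chrom[i]]]
      if (is.null(ii)) next
      plus <- g$strand[i] == "+"
      a <- if (anchor == "TSS") (if (plus) g$start[i] else g$end[i])
      else (if (plus) g$end[i] else g$start[i])
      centers <- if (plus) a + offsets else a - offsets
      m[i, ] <- cpp_window_mean(track$pos[ii], track$score[ii], centers,
                                params$signal_window / 2)
    }
    profile_from_matrix(m, offsets)
  }
  out <- list(TSS = lapply(classes, one, anchor = "TSS"),
              TES = lapply(classes, one, anchor = "TES"))
  attr(out, "genes_used") <- vapply(classes, nrow, integer(1))
  attr(out, "n_analyzed") <- nrow(genes)
  out
}
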