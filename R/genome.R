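#' Build a genome model from a simulation configuration
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_model`: a data frame with columns
#'   `chrom` and `length` (bp), plus a `provenance` attribute recording
#'   fusion history (empty for a freshly built genome). All coordinates in
#'   the package are 0-based half-open.
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  n <- length(config$chrom_lengths)
  gm <- data.frame(chrom = paste0("chr", utils::as.roman(seq_len(n))),
                   length = as.numeric(config$chrom_lengths),
                   stringsAsFactors = FALSE)
  class(gm) <- c("genome_model", "data.frame")
  attr(gm, "provenance") <- list()
  gm
}

genome_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]])
  genome$length[i]
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.2f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, ...)
  prov <- attr(x, "provenance")
  if (length(prov)) cat("fusion provenance recorded for:",
                        paste(names(prov), collapse = ", "), "\n")
  invisible(x)
}

# Plant one arm's domains, working in local coordinates that run from the
# chromosome end (x = 0) inward. Returns data.frame(start, end) in local
# coordinates. Domain and gap sizes are drawn until per-arm quotas (set by
# the target occupancy) are exhausted; the final draw is trimmed, so the
# realized occupancy equals the target up to integer rounding.
plant_arm <- function(arm_len, cfg) {
  quota_dom <- round(cfg$arm_occupancy * arm_len)
  if (quota_dom == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (quota_dom < cfg$min_domain || arm_len < cfg$min_domain) {
    warning("arm too small to hold a minimum-size subdomain; left empty")
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  quota_gap <- arm_len - quota_dom
  w <- cfg$gap_weights / sum(cfg$gap_weights)
  # draw alternating gap/domain sizes until both quotas are reached, then
  # rescale gaps and domains separately so they exhaust their quotas
  # exactly: occupancy hits the target and the domains span the whole arm
  gsz <- dsz <- numeric(0)
  cur <- 0
  while (sum(dsz) < quota_dom || sum(gsz) < quota_gap) {
    comp <- sample.int(3, 1, prob = w)
    pos <- min(cur, arm_len)  # nominal position, capped at the arm extent
    # arm gaps stay within the L size class (< 500 kb): the only XL gap of
    # a chromosome is its center, as the arm/center architecture promises
    g <- min(5e5, stats::rlnorm(1, log(cfg$gap_medians[comp]), cfg$gap_sdlog) *
               exp(cfg$gap_grow * pos / 1e6))
    med <- cfg$size_median * exp(-cfg$size_decay * min(pos + g, arm_len) / 1e6)
    d <- max(cfg$min_domain, stats::rlnorm(1, log(med), cfg$size_sdlog))
    gsz <- c(gsz, g); dsz <- c(dsz, d)
    cur <- cur + g + d
  }
  gsz <- gsz * quota_gap / sum(gsz)
  dsz <- dsz * quota_dom / sum(dsz)
  starts <- round(cumsum(gsz) + c(0, cumsum(dsz)[-length(dsz)]))
  ends <- round(cumsum(gsz) + cumsum(dsz))
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Plant ground-truth membrane-association domains
#'
#' Domains are confined to the configured arm regions of each chromosome.
#' Sizes are log-normal with a median that decays with distance from the
#' nearest chromosome end (larger domains sit closer to the ends); gaps
#' between them come from a three-component size mixture. Per-interval
#' association strength decays linearly with distance from the nearest end
#' and gains an additive bonus inside the terminal bonus window. Realized
#' arm occupancy matches the target up to the trimming of the final draw.
#'
#' @param genome a [build_genome()] result.
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return an object of class `truth_model`: a data frame with columns
#'   `chrom`, `start`, `end`, `strength`, `bonus`, `near_end`, and an `arms`
#'   attribute holding the arm/center partition as an interval data frame.
#' @export
plant_truth <- function(genome, config, seed = 1L) {
  validate_sim_config(config)
  set.seed(seed)
  out <- list(); arms <- list()
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]; chrom <- genome$chrom[i]
    arm_len <- floor(L * config$arm_fraction)
    left <- plant_arm(arm_len, config)
    right <- plant_arm(arm_len, config)
    iv <- rbind(
      data.frame(start = left$start, end = left$end),
      data.frame(start = L - right$end, end = L - right$start)
    )
    if (nrow(iv)) {
      iv <- iv[order(iv$start), , drop = FALSE]
      # split intervals at the terminal bonus-window boundaries so the
      # end-proximity bonus has a sharp per-base edge
      cuts <- c(config$end_bonus_window, L - config$end_bonus_window)
      for (cut in cuts) {
        hit <- iv$start < cut & iv$end > cut
        if (any(hit)) {
          iv <- rbind(iv[!hit, ],
                      data.frame(start = iv$start[hit], end = cut),
                      data.frame(start = cut, end = iv$end[hit]))
          iv <- iv[order(iv$start), , drop = FALSE]
        }
      }
      mid <- (iv$start + iv$end) / 2
      dist_end <- pmin(mid, L - mid)
      s <- pmax(config$min_strength,
                config$strength_end - config$strength_decay * dist_end / 1e6)
      near <- ifelse(mid < config$end_bonus_window, "left",
                     ifelse(L - mid < config$end_bonus_window, "right", NA))
      bonus <- ifelse(is.na(near), 0, config$end_bonus)
      out[[chrom]] <- data.frame(chrom = chrom, start = iv$start, end = iv$end,
                                 strength = s + bonus, bonus = bonus,
                                 near_end = near, stringsAsFactors = FALSE)
    }
    arms[[chrom]] <- data.frame(
      chrom = chrom,
      start = c(0, arm_len, L - arm_len),
      end = c(arm_len, L - arm_len, L),
      part = c("arm", "center", "arm"), stringsAsFactors = FALSE)
  }
  tm <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strength = numeric(0), bonus = numeric(0),
               near_end = character(0))
  class(tm) <- c("truth_model", "data.frame")
  attr(tm, "arms") <- do.call(rbind, c(arms, make.row.names = FALSE))
  tm
}

#' Fuse two chromosome ends into a single chromosome
#'
#' Joins `endA` of `chromA` to `endB` of `chromB`, reversing segment
#' orientation where needed so the named ends meet at the junction. Truth
#' intervals are remapped to fused coordinates; intervals whose strength
#' included the terminal end-proximity bonus lose it if their source end is
#' no longer a physical chromosome end. Fusion provenance (source
#' chromosome, source interval, orientation) is recorded on the genome.
#'
#' @param genome,truth models built on the unfused genome.
#' @param chromA,chromB chromosome names (must differ).
#' @param endA,endB `"left"` or `"right"`: which end of each chromosome
#'   meets the junction.
#' @param config the [sim_config()] used to build the truth.
#' @return list with elements `genome` and `truth` on the fused layout.
#' @export
fuse <- function(genome, truth, chromA, endA = c("right", "left"),
                 chromB, endB = c("left", "right"), config) {
  endA <- match.arg(endA); endB <- match.arg(endB)
  if (identical(chromA, chromB)) stop("cannot fuse a chromosome with itself")
  LA <- genome_length(genome, chromA)
  LB <- genome_length(genome, chromB)
  revA <- endA == "left"   # segment A must end (rightmost) at the junction
  revB <- endB == "right"  # segment B must start (leftmost) at the junction
  fused_name <- paste(chromA, chromB, sep = "-")
  remap <- function(df, src, L, rev, offset) {
    sel <- df$chrom == src
    if (!any(sel)) return(df)
    s <- df$start[sel]; e <- df$end[sel]
    if (rev) { ns <- L - e; ne <- L - s } else { ns <- s; ne <- e }
    df$start[sel] <- ns + offset
    df$end[sel] <- ne + offset
    df$chrom[sel] <- fused_name
    df
  }
  keep <- genome[!(genome$chrom %in% c(chromA, chromB)), , drop = FALSE]
  gm <- rbind(keep, data.frame(chrom = fused_name, length = LA + LB))
  class(gm) <- c("genome_model", "data.frame")
  prov <- attr(genome, "provenance")
  prov[[fused_name]] <- data.frame(
    source = c(chromA, chromB),
    src_start = c(0, 0), src_end = c(LA, LB),
    strand = c(ifelse(revA, "-", "+"), ifelse(revB, "-", "+")),
    start = c(0, LA), end = c(LA, LA + LB), stringsAsFactors = FALSE)
  attr(gm, "provenance") <- prov

  tm <- as.data.frame(truth)
  # the fused ends stop being physical chromosome ends: drop their bonus
  lost <- (tm$chrom == chromA & !is.na(tm$near_end) & tm$near_end == endA) |
          (tm$chrom == chromB & !is.na(tm$near_end) & tm$near_end == endB)
  tm$strength[lost] <- tm$strength[lost] - tm$bonus[lost]
  tm$bonus[lost] <- 0
  tm$near_end[lost] <- NA
  tm <- remap(tm, chromA, LA, revA, 0)
  tm <- remap(tm, chromB, LB, revB, LA)
  tm <- tm[order(tm$chrom, tm$start), , drop = FALSE]
  rownames(tm) <- NULL
  class(tm) <- c("truth_model", "data.frame")
  arms <- attr(truth, "arms")
  if (!is.null(arms)) {
    arms <- remap(arms, chromA, LA, revA, 0)
    arms <- remap(arms, chromB, LB, revB, LA)
    arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  }
  attr(tm, "arms") <- arms
  list(genome = gm, truth = tm)
}
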