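# Brute-force oracles and small fixture builders. Every oracle is a direct,
# unoptimized restatement of the operation's definition, independent of the
# implementation path it checks.

# median over the pooled finite values of all columns of x at positions
# within +/- half of each position
oracle_window_median <- function(pos, x, half) {
  x <- as.matrix(x)
  vapply(seq_along(pos), function(i) {
    sel <- abs(pos - pos[i]) <= half
    v <- as.vector(x[sel, , drop = FALSE])
    v <- v[is.finite(v)]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
}

# mean of finite values at positions in [q - half, q + half)
oracle_window_mean <- function(pos, val, q, half) {
  vapply(q, function(qq) {
    v <- val[pos >= qq - half & pos < qq + half]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

# per-base coverage of stranded fragments extended ext bp
oracle_coverage <- function(frag, ext, L) {
  cov <- integer(L)
  for (i in seq_len(nrow(frag))) {
    p <- frag$pos[i]
    if (frag$strand[i] == "+") { s <- p; e <- p + ext } else {
      s <- p - ext + 1; e <- p + 1
    }
    s <- max(0, s); e <- min(L, e)
    if (e > s) cov[(s + 1):e] <- cov[(s + 1):e] + 1L
  }
  cov
}

# transitive merge of intervals sharing >= min_overlap bp, quadratic
oracle_merge <- function(df, min_overlap = 1) {
  n <- nrow(df)
  if (n == 0) return(df[0, c("chrom", "start", "end")])
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] && df$chrom[i] == df$chrom[j] &&
          min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) >=
            min_overlap) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    data.frame(chrom = df$chrom[grp == g][1],
               start = min(df$start[grp == g]),
               end = max(df$end[grp == g]))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# fraction of [start, end) bases covered by the union of features, per base
oracle_coverage_fraction <- function(region, features) {
  base <- rep(FALSE, region$end - region$start)
  f <- features[features$chrom == region$chrom, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    s <- max(f$start[i], region$start); e <- min(f$end[i], region$end)
    if (e > s) base[(s - region$start + 1):(e - region$start)] <- TRUE
  }
  mean(base)
}

# per-boundary windowed point counting, direct loops
oracle_count_profile <- function(points, boundaries, window, offset, flank) {
  offsets <- seq(-flank + window / 2, flank - window / 2, by = offset)
  m <- matrix(NA_real_, nrow(boundaries), length(offsets))
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i, ]
    for (j in seq_along(offsets)) {
      o <- offsets[j]
      if (o - window / 2 < -b$gap_flank || o + window / 2 > b$sub_flank) next
      sel <- points$chrom == b$chrom
      rel <- points$pos[sel] - b$pos
      if (b$gap_side != "left") rel <- -rel
      m[i, j] <- sum(rel >= o - window / 2 & rel < o + window / 2)
    }
  }
  mu <- suppressWarnings(colMeans(m, na.rm = TRUE))
  mu[colSums(!is.na(m)) == 0] <- NA_real_
  data.frame(offset = offsets, mean = mu, n = colSums(!is.na(m)))
}

# total bases of `a` covered by `b` (summed over rows of a)
covered_sum <- function(a, b) sum(nmadomains:::covered_bases(a, b))

# TRUE for rows of a overlapping (>= 1 bp) any row of b, quadratic
overlaps_any_df <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(b$end, a$end[i]) - pmax(b$start, a$start[i]) >= 1)
  }, logical(1))
}

# random probe-style track on one chromosome
rand_track <- function(n = 200, L = 10e3, chrom = "chrT", step = 50,
                       na_frac = 0) {
  pos <- sort(sample.int(L, n)) - 1
  score <- rnorm(n)
  if (na_frac > 0) score[sample.int(n, round(n * na_frac))] <- NA
  signal_track(rep(chrom, n), pos, score, kind = "log-ratio", step = step)
}

rand_intervals <- function(n = 10, L = 50e3, chrom = "chrT") {
  s <- sort(sample.int(L - 100, n))
  w <- sample.int(2000, n)
  data.frame(chrom = chrom, start = s, end = pmin(L, s + w))
}

# small, fast simulation settings for unit tests
tiny_config <- function(...) {
  sim_config(chrom_lengths = c(2e6, 2e6), ...)
}

# every simulated effect switched off: the null world
null_config <- function(len = c(10e6, 10e6), ...) {
  fams <- nmadomains::repeat_families()
  one <- stats::setNames(rep(1, length(fams)), fams)
  sim_config(chrom_lengths = len,
             gene_density_gap = 140, gene_density_domain = 140,
             tss_edge_fraction = 0,
             repeat_contrast = one,
             expr_class_shift = c(subdomain = 0, S = 0, M = 0, L = 0, XL = 0),
             silent_prob = c(subdomain = 0.3, gap = 0.3),
             persistence = c(subdomain = 0.7, gap = 0.7),
             phenotype_domain_factor = 1,
             k27_effect = 0, k9_effect = 0, active_effect = 0, ...)
}

# default-conditions end-to-end run shared by recovery-style tests
run_caller <- function(cfg, seed) {
  genome <- build_genome(cfg)
  truth <- plant_truth(genome, cfg, seed = seed)
  frags <- simulate_seq(truth, genome, cfg, seed = seed + 100L)
  sq <- seq_pipeline(frags, genome, seed = seed + 200L)
  arr <- simulate_array(truth, genome, cfg, seed = seed + 300L)
  ap <- array_pipeline(arr)
  calls <- call_subdomains(ap$regions, sq$regions, genome)
  list(genome = genome, truth = truth, array = ap, seq = sq, calls = calls)
}
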