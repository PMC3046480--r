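# ---- shared lookup helpers ----------------------------------------------

# index of the half-open truth/interval row containing each point (NA if none);
# intervals must be sorted and disjoint per chromosome
interval_index_of <- function(chrom, pos, intervals) {
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    iv <- which(intervals$chrom == cc)
    if (!length(iv)) next
    k <- findInterval(pos[sel], intervals$start[iv])
    hit <- k >= 1 & pos[sel] < intervals$end[iv][pmax(k, 1)]
    out[sel][hit] <- iv[k[hit]]
  }
  out
}

# region class of points against a subdomain/gap tiling: "subdomain" or the
# gap size class of the containing gap
region_class_of_points <- function(chrom, pos, subdomains, gaps) {
  cls <- rep(NA_character_, length(pos))
  i <- interval_index_of(chrom, pos, subdomains)
  cls[!is.na(i)] <- "subdomain"
  j <- interval_index_of(chrom, pos, gaps)
  cls[is.na(i) & !is.na(j)] <- gaps$size_class[j[is.na(i) & !is.na(j)]]
  cls
}

# complement of truth intervals with size classes, used by the simulator to
# define the gap classes its effects are conditioned on
truth_gaps <- function(truth, genome, cutoffs = c(10e3, 100e3, 1e6)) {
  sub <- interval_set(truth$chrom, truth$start, truth$end, label = "subdomain")
  classify_gaps(derive_gaps(sub, genome),
                analysis_params(gap_cutoffs = cutoffs))
}

# ---- annotations ---------------------------------------------------------

#' Generate synthetic gene and repeat annotations
#'
#' Gene density is higher outside the planted domains and repeat density
#' higher inside, with family-specific contrasts (helitron and satellite
#' strongest by default). A configured fraction of gap genes has its
#' translation start placed within 2 kb outside a domain edge, mirroring the
#' preference of gene starts for positions just outside membrane-associated
#' regions. Mixed-stage expression (dcpm) and optional phenotype labels are
#' drawn per gene conditional on its region class.
#'
#' @param genome,truth,config simulator objects; `seed` an integer seed.
#' @param seed integer RNG seed.
#' @return list with elements `genes` (class `gene_table`) and `repeats`
#'   (class `repeat_table`).
#' @export
annotate_genome <- function(genome, truth, config, seed = 1L) {
  validate_sim_config(config)
  set.seed(seed)
  gaps <- truth_gaps(truth, genome)
  sub <- data.frame(chrom = truth$chrom, start = truth$start, end = truth$end)

  regions <- rbind(
    cbind(sub, inside = TRUE),
    data.frame(chrom = gaps$chrom, start = gaps$start, end = gaps$end,
               inside = FALSE))

  # genes -------------------------------------------------------------
  dens <- ifelse(regions$inside, config$gene_density_domain,
                 config$gene_density_gap)
  ngene <- stats::rpois(nrow(regions), dens * (regions$end - regions$start) / 1e6)
  gchrom <- rep(regions$chrom, ngene)
  glen <- pmax(200, round(stats::rlnorm(sum(ngene),
                                        log(config$gene_length_median),
                                        config$gene_length_sdlog)))
  rs <- rep(regions$start, ngene); re <- rep(regions$end, ngene)
  gstart <- floor(rs + stats::runif(sum(ngene)) * pmax(1, re - rs - glen))
  Lof <- genome$length[match(gchrom, genome$chrom)]
  gstart <- pmax(0, pmin(gstart, Lof - glen - 1))
  gend <- gstart + glen
  strand <- sample(c("+", "-"), sum(ngene), replace = TRUE)
  inside <- rep(regions$inside, ngene)

  # relocate a fraction of gap genes so translation starts sit just outside
  # domain edges (within 2 kb on the gap side)
  if (nrow(sub) && config$tss_edge_fraction > 0) {
    cand <- which(!inside)
    nmove <- round(length(cand) * config$tss_edge_fraction)
    if (nmove > 0) {
      mv <- sample(cand, nmove)
      ei <- sample(nrow(sub), nmove, replace = TRUE)
      left_edge <- sample(c(TRUE, FALSE), nmove, replace = TRUE)
      edge <- ifelse(left_edge, sub$start[ei], sub$end[ei])
      u <- 1 + floor(stats::runif(nmove) * 1999)
      tpos <- ifelse(left_edge, edge - u, edge + u - 1)
      L2 <- genome$length[match(sub$chrom[ei], genome$chrom)]
      tpos <- pmax(1, pmin(tpos, L2 - 2))
      gchrom[mv] <- sub$chrom[ei]
      # transcripts anchored so the (strand-aware) translation start is tpos
      gstart[mv] <- pmax(0, ifelse(strand[mv] == "+", tpos - 100,
                                   tpos + 100 - glen[mv]))
      gstart[mv] <- pmin(gstart[mv], L2 - glen[mv] - 1)
      gend[mv] <- gstart[mv] + glen[mv]
    }
  }
  off <- pmin(round(stats::rexp(length(gstart), 1 / 200)),
              floor(glen / 3))
  tstart <- ifelse(strand == "+", gstart + off, gend - 1 - off)

  subiv <- interval_set(sub$chrom, sub$start, sub$end)
  cls <- region_class_of_points(gchrom, tstart, subiv, gaps)
  grp <- ifelse(!is.na(cls) & cls == "subdomain", "subdomain", "gap")
  silent <- stats::runif(length(gstart)) < config$silent_prob[grp]
  shift <- config$expr_class_shift[ifelse(is.na(cls), "XL", cls)]
  expr <- ifelse(silent, 0,
                 stats::rlnorm(length(gstart),
                               config$expr_meanlog + shift, config$expr_sdlog))

  pheno <- rep(NA_character_, length(gstart))
  pp <- config$phenotype_base_prob
  for (g in c("subdomain", "gap")) {
    selg <- grp == g
    p <- if (g == "subdomain") pp * config$phenotype_domain_factor else pp
    draw <- stats::runif(sum(selg))
    cp <- cumsum(p)
    k <- findInterval(draw, c(0, cp))
    lab <- c(config$phenotypes, NA_character_)[pmin(k, length(cp) + 1)]
    pheno[selg] <- lab
  }

  genes <- data.frame(gene_id = sprintf("gene%05d", seq_along(gstart)),
                      chrom = gchrom, strand = strand,
                      start = gstart, end = gend, tstart = tstart,
                      expression = expr, phenotype = pheno,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_table", "data.frame")

  # repeats -----------------------------------------------------------
  fams <- repeat_families()
  maxf <- max(1, config$repeat_terminal_factor)
  rl <- list()
  for (fam in fams) {
    base <- config$repeat_density_gap[[fam]]
    dens <- ifelse(regions$inside, base * config$repeat_contrast[[fam]], base)
    term_fam <- fam %in% c("helitron", "satellite") &&
      config$repeat_terminal_factor != 1
    nrep <- stats::rpois(nrow(regions),
                         dens * (regions$end - regions$start) / 1e6 *
                           (if (term_fam) maxf else 1))
    rchrom <- rep(regions$chrom, nrep)
    rs <- rep(regions$start, nrep); re <- rep(regions$end, nrep)
    center <- floor(rs + stats::runif(sum(nrep)) * (re - rs))
    if (term_fam && sum(nrep)) {
      Lr <- genome$length[match(rchrom, genome$chrom)]
      in_term <- center < config$end_bonus_window |
        center >= Lr - config$end_bonus_window
      keepp <- ifelse(in_term, config$repeat_terminal_factor, 1) / maxf
      keep <- stats::runif(length(center)) < keepp
      rchrom <- rchrom[keep]; center <- center[keep]
    }
    if (!length(center)) next
    len <- pmax(20, round(stats::rlnorm(length(center),
                                        log(config$repeat_length_median),
                                        config$repeat_length_sdlog)))
    Lr <- genome$length[match(rchrom, genome$chrom)]
    s <- pmax(0, center - floor(len / 2))
    e <- pmin(Lr, s + len)
    s <- pmin(s, pmax(0, e - 1))
    rl[[fam]] <- data.frame(family = fam, chrom = rchrom, start = s, end = e,
                            center = pmin(pmax(center, s), e - 1),
                            stringsAsFactors = FALSE)
  }
  repeats <- if (length(rl)) do.call(rbind, c(rl, make.row.names = FALSE)) else
    data.frame(family = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), center = numeric(0))
  repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL
  class(repeats) <- c("repeat_table", "data.frame")

  list(genes = genes, repeats = repeats)
}

# ---- signal simulators ---------------------------------------------------

#' Simulate tiling-array log-ratio replicates
#'
#' Probes sit on a regular grid at the configured spacing and carry Beta-
#' distributed GC fractions. The IP log-ratio mean equals the planted
#' strength inside subdomains and 0 outside, plus an additive GC-linear
#' probe bias and Gaussian noise; control replicates are drawn from the same
#' null (zero-strength) model with the same probe bias, giving the caller a
#' matched empirical-FDR control.
#'
#' @param truth,genome,config simulator objects.
#' @param n_replicates number of IP replicates (>= 1).
#' @param n_control number of control-antibody replicates.
#' @param seed integer RNG seed.
#' @return list with `probes` (a [probe_set()]), `ip` and `control` (lists of
#'   log-ratio [signal_track()]s sharing the probe layout).
#' @export
simulate_array <- function(truth, genome, config, n_replicates = 3,
                           n_control = 1, seed = 1L) {
  stopifnot(n_replicates >= 1, n_control >= 1)
  set.seed(seed)
  step <- config$probe_spacing
  pos <- chrom <- list()
  for (i in seq_len(nrow(genome))) {
    p <- seq(step / 2, genome$length[i] - 1, by = step)
    if (!length(p)) stop("zero probes on chromosome ", genome$chrom[i])
    pos[[i]] <- p
    chrom[[i]] <- rep(genome$chrom[i], length(p))
  }
  pos <- unlist(pos); chrom <- unlist(chrom)
  gc <- stats::rbeta(length(pos), config$gc_shape1, config$gc_shape2)
  uniq <- stats::runif(length(pos)) >= config$nonunique_prob
  probes <- probe_set(chrom, pos, gc, uniq)
  # probe_set sorts; regenerate in sorted order reference
  mean_gc <- config$gc_shape1 / (config$gc_shape1 + config$gc_shape2)
  bias <- config$gc_bias_slope * (probes$gc - mean_gc)
  ti <- interval_index_of(probes$chrom, probes$pos, truth)
  mu <- ifelse(is.na(ti), 0, truth$strength[ti])
  mk <- function(m) {
    signal_track(probes$chrom, probes$pos,
                 m + bias + stats::rnorm(nrow(probes), 0, config$array_noise_sd),
                 kind = "log-ratio", step = step)
  }
  list(probes = probes,
       ip = lapply(seq_len(n_replicates), function(i) mk(mu)),
       control = lapply(seq_len(n_control), function(i) mk(0)))
}

new_fragment_set <- function(chrom, pos, strand) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("fragment_set", "data.frame"))
}

#' Simulate sequencing fragment starts
#'
#' Fragment counts are Poisson with a uniform background rate set by the
#' configured mean depth per read-extension window. Inside planted domains
#' the IP rate is multiplied by `1 + (seq_fold_ref - 1) * strength /
#' strength_end`, so a domain at the reference chromosome-end strength is
#' enriched `seq_fold_ref`-fold. Control and input rates are uniform.
#' Strand is uniform; plus-strand fragments extend rightward from `pos` and
#' minus-strand fragments leftward (see [coverage_from_fragments()]).
#'
#' @param truth,genome,config simulator objects; `seed` an integer seed.
#' @param seed integer RNG seed.
#' @return list of three `fragment_set` data frames: `ip`, `control`, `input`.
#' @export
simulate_seq <- function(truth, genome, config, seed = 1L) {
  set.seed(seed)
  lam <- config$seq_depth / config$read_extension        # fragments per bp
  lam_in <- config$seq_input_depth / config$read_extension
  draw_uniform <- function(rate) {
    ch <- ps <- list()
    for (i in seq_len(nrow(genome))) {
      n <- stats::rpois(1, rate * genome$length[i])
      ps[[i]] <- floor(stats::runif(n) * genome$length[i])
      ch[[i]] <- rep(genome$chrom[i], n)
    }
    list(chrom = unlist(ch), pos = unlist(ps))
  }
  bg <- draw_uniform(lam)
  extra_ch <- extra_pos <- list()
  if (nrow(truth) && lam > 0) {
    fold <- 1 + (config$seq_fold_ref - 1) * truth$strength / config$strength_end
    nx <- stats::rpois(nrow(truth), lam * pmax(0, fold - 1) *
                         (truth$end - truth$start))
    extra_ch <- rep(truth$chrom, nx)
    extra_pos <- floor(rep(truth$start, nx) +
                         stats::runif(sum(nx)) *
                         rep(truth$end - truth$start, nx))
  }
  ip_ch <- c(bg$chrom, extra_ch); ip_pos <- c(bg$pos, extra_pos)
  ip <- new_fragment_set(ip_ch, ip_pos,
                         sample(c("+", "-"), length(ip_pos), replace = TRUE))
  ctl <- draw_uniform(lam)
  control <- new_fragment_set(ctl$chrom, ctl$pos,
                              sample(c("+", "-"), length(ctl$pos), replace = TRUE))
  inp <- draw_uniform(lam_in)
  input <- new_fragment_set(inp$chrom, inp$pos,
                            sample(c("+", "-"), length(inp$pos), replace = TRUE))
  list(ip = ip, control = control, input = input)
}

#' Simulate chromatin-mark score tracks
#'
#' Produces z-score-like tracks on the probe grid for six factors:
#' H3K27me3 elevated over planted domains except over active genes;
#' H3K9me2/H3K9me3 near-flat with a slight domain elevation; and
#' H3K4me3/RNAPII/HTZ-1 elevated over the bodies of expressed genes in gaps.
#'
#' @param truth,genes,genome,config simulator objects; `seed` an integer seed.
#' @param seed integer RNG seed.
#' @return named list of [signal_track()]s (`H3K27me3`, `H3K9me2`,
#'   `H3K9me3`, `H3K4me3`, `RNAPII`, `HTZ-1`).
#' @export
simulate_marks <- function(truth, genes, genome, config, seed = 1L) {
  set.seed(seed)
  step <- config$probe_spacing
  pos <- chrom <- list()
  for (i in seq_len(nrow(genome))) {
    pos[[i]] <- seq(step / 2, genome$length[i] - 1, by = step)
    chrom[[i]] <- rep(genome$chrom[i], length(pos[[i]]))
  }
  pos <- unlist(pos); chrom <- unlist(chrom)
  in_domain <- !is.na(interval_index_of(chrom, pos, truth))

  active_cut <- stats::quantile(genes$expression, 0.8, names = FALSE)
  active <- genes$expression > active_cut
  gi <- interval_index_of(chrom, pos,
                          data.frame(chrom = genes$chrom, start = genes$start,
                                     end = genes$end)[order(genes$chrom,
                                                            genes$start), ])
  og <- genes[order(genes$chrom, genes$start), ]
  in_active_gene <- !is.na(gi) & active[order(genes$chrom, genes$start)][gi]
  sub_cls <- !is.na(interval_index_of(og$chrom, og$tstart, truth))
  in_active_gap_gene <- !is.na(gi) & in_active_gene & !sub_cls[gi]

  noise <- function() stats::rnorm(length(pos), 0, config$mark_noise_sd)
  mk <- function(mu) signal_track(chrom, pos, mu + noise(), kind = "mark",
                                  step = step)
  list(
    H3K27me3 = mk(config$k27_effect * (in_domain & !in_active_gene)),
    H3K9me2 = mk(config$k9_effect * in_domain),
    H3K9me3 = mk(config$k9_effect * in_domain),
    H3K4me3 = mk(config$active_effect * in_active_gap_gene),
    RNAPII = mk(config$active_effect * in_active_gap_gene),
    `HTZ-1` = mk(config$active_effect * in_active_gap_gene))
}

#' Simulate staged expression (dcpm) for every gene
#'
#' The first stage (early embryo) draws expression from the class-shifted
#' log-normal model with class-dependent silencing. Genes silent at the
#' first stage stay silent stage-to-stage with the configured persistence
#' probability (higher for subdomain genes); once activated they stay
#' expressed. dcpm of exactly 0 encodes "undetectable".
#'
#' @param genes,truth,genome,config simulator objects; `seed` an integer seed.
#' @param seed integer RNG seed.
#' @return numeric matrix, stages in rows (named), genes in columns.
#' @export
simulate_expression_stages <- function(genes, truth, genome, config,
                                       seed = 1L) {
  set.seed(seed)
  gaps <- truth_gaps(truth, genome)
  subiv <- interval_set(truth$chrom, truth$start, truth$end)
  cls <- region_class_of_points(genes$chrom, genes$tstart, subiv, gaps)
  grp <- ifelse(!is.na(cls) & cls == "subdomain", "subdomain", "gap")
  shift <- config$expr_class_shift[ifelse(is.na(cls), "XL", cls)]
  n <- nrow(genes)
  stage_names <- c("early_embryo", "late_embryo", "L2", "L3", "L4",
                   "young_adult")
  ns <- config$n_stages
  if (ns > length(stage_names))
    stage_names <- c(stage_names, paste0("stage", seq_len(ns - length(stage_names)) +
                                           length(stage_names)))
  stage_names <- stage_names[seq_len(ns)]
  draw_expr <- function(idx) stats::rlnorm(length(idx),
                                           config$expr_meanlog + shift[idx],
                                           config$expr_sdlog)
  m <- matrix(0, nrow = ns, ncol = n,
              dimnames = list(stage_names, genes$gene_id))
  silent <- stats::runif(n) < config$silent_prob[grp]
  m[1, !silent] <- draw_expr(which(!silent))
  still_silent <- silent
  for (s in seq_len(ns)[-1]) {
    persist <- config$persistence[grp]
    wake <- still_silent & stats::runif(n) >= persist
    still_silent <- still_silent & !wake
    on <- !still_silent
    m[s, on] <- draw_expr(which(on))
  }
  m
}
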