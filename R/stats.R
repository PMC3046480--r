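# rank-sum with exact enumeration for small groups, normal approximation
# (with tie correction) otherwise
ranksum <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)  # identical groups
  ex <- length(x) <= 20 && length(y) <= 20 && !any(duplicated(c(x, y)))
  suppressWarnings(stats::wilcox.test(x, y, exact = ex))$p.value
}

region_frame <- function(subdomains, gaps, arm_restrict = TRUE) {
  sub <- as.data.frame(subdomains)[, c("chrom", "start", "end")]
  sub$group <- "subdomain"; sub$size_class <- NA_character_
  g <- as.data.frame(gaps)
  if (arm_restrict)
    g <- g[is.na(g$size_class) | g$size_class != "XL", , drop = FALSE]
  if (arm_restrict && "terminal" %in% names(g))
    g <- g[!g$terminal, , drop = FALSE]
  g <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                  group = "gap", size_class = g$size_class)
  rbind(sub, g)
}

#' Feature-coverage contrast between subdomains and gaps
#'
#' Computes, per region, the fraction of bases covered by the union of the
#' features (no double counting of overlapping features), and contrasts
#' subdomains against gaps with a two-sided Wilcoxon rank-sum test per
#' chromosome and overall. With `arm_restrict` the XL (central) and
#' terminal gaps are excluded, confining the contrast to the subdomain-gap
#' structure within the large membrane-associated domains.
#'
#' @param features data frame with `chrom`, `start`, `end` (repeats or gene
#'   bodies).
#' @param subdomains,gaps tiling [interval_set()]s.
#' @param arm_restrict drop XL and terminal gaps (default `TRUE`).
#' @return list with `regions` (per-region coverage fractions) and `tests`
#'   (per-chromosome and overall rank-sum p-values with group medians in %).
#' @export
coverage_contrast <- function(features, subdomains, gaps,
                              arm_restrict = TRUE) {
  reg <- region_frame(subdomains, gaps, arm_restrict)
  if (!nrow(reg) || !all(c("subdomain", "gap") %in% reg$group))
    stop("both subdomain and gap regions are required")
  reg$fraction <- covered_bases(reg, features) / (reg$end - reg$start)
  test_one <- function(df) {
    x <- df$fraction[df$group == "subdomain"]
    y <- df$fraction[df$group == "gap"]
    data.frame(n_subdomain = length(x), n_gap = length(y),
               median_subdomain_pct = 100 * stats::median(x),
               median_gap_pct = 100 * stats::median(y),
               p = if (length(x) && length(y)) ranksum(x, y) else NA_real_)
  }
  per_chrom <- do.call(rbind, lapply(split(reg, reg$chrom), test_one))
  per_chrom <- cbind(chrom = rownames(per_chrom), per_chrom)
  all_t <- cbind(chrom = "all", test_one(reg))
  tests <- rbind(per_chrom, all_t)
  rownames(tests) <- NULL
  list(regions = reg, tests = tests)
}

#' Per-family repeat-coverage contrast
#'
#' Runs [coverage_contrast()] separately for each repeat family and reports
#' the subdomain/gap mean-coverage ratio and rank-sum p-value. Families
#' absent from the data are flagged rather than divided by zero.
#'
#' @param repeats a `repeat_table`.
#' @param subdomains,gaps tiling [interval_set()]s.
#' @param arm_restrict drop XL and terminal gaps.
#' @return data frame, one row per family: `family`, `n`, `mean_subdomain`,
#'   `mean_gap`, `ratio`, `p`, `absent`.
#' @export
family_enrichment <- function(repeats, subdomains, gaps,
                              arm_restrict = TRUE) {
  reg <- region_frame(subdomains, gaps, arm_restrict)
  out <- lapply(repeat_families(), function(fam) {
    f <- repeats[repeats$family == fam, , drop = FALSE]
    if (!nrow(f))
      return(data.frame(family = fam, n = 0L, mean_subdomain = NA_real_,
                        mean_gap = NA_real_, ratio = NA_real_, p = NA_real_,
                        absent = TRUE))
    fr <- covered_bases(reg, f) / (reg$end - reg$start)
    x <- fr[reg$group == "subdomain"]; y <- fr[reg$group == "gap"]
    data.frame(family = fam, n = nrow(f), mean_subdomain = mean(x),
               mean_gap = mean(y),
               ratio = if (mean(y) > 0) mean(x) / mean(y) else NA_real_,
               p = ranksum(x, y), absent = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$p_bh <- ifelse(res$absent, NA, stats::p.adjust(res$p, "BH"))
  res
}

#' Assign genes to region classes by transcript-start containment
#'
#' Half-open containment of the transcript start: a start exactly at a
#' subdomain's start coordinate belongs to the subdomain.
#'
#' @param genes a `gene_table`.
#' @param subdomains,gaps tiling [interval_set()]s (gaps classified).
#' @return character vector of classes (`"subdomain"`, `"S"`, `"M"`, `"L"`,
#'   `"XL"`) aligned with `genes` rows.
#' @export
gene_region_class <- function(genes, subdomains, gaps) {
  region_class_of_points(genes$chrom, genes$tstart, subdomains, gaps)
}

#' Expression distributions by gap size class
#'
#' Genes are assigned to the subdomain or to the size class of the gap
#' containing their transcript start; per-class expression distributions
#' and pairwise two-sided rank-sum tests are returned.
#'
#' @param genes a `gene_table` with an `expression` column.
#' @param subdomains,gaps tiling [interval_set()]s.
#' @return list with `class` (per-gene class), `summary` (per-class n and
#'   median), `pairwise` (pairwise rank-sum p-values, BH-flagged).
#' @export
expression_by_gap_class <- function(genes, subdomains, gaps) {
  cls <- gene_region_class(genes, subdomains, gaps)
  lv <- c("subdomain", "S", "M", "L", "XL")
  cls <- factor(cls, levels = lv)
  byc <- split(genes$expression, cls)
  summary <- data.frame(class = lv,
                        n = vapply(byc, length, integer(1)),
                        median = vapply(byc, function(v)
                          if (length(v)) stats::median(v) else NA_real_,
                          numeric(1)))
  pairs <- utils::combn(lv, 2)
  pw <- apply(pairs, 2, function(pr) {
    x <- byc[[pr[1]]]; y <- byc[[pr[2]]]
    data.frame(class1 = pr[1], class2 = pr[2],
               p = if (length(x) > 1 && length(y) > 1) ranksum(x, y)
               else NA_real_)
  })
  pw <- do.call(rbind, c(pw, make.row.names = FALSE))
  pw$p_bh <- stats::p.adjust(pw$p, "BH")
  list(class = as.character(cls), summary = summary, pairwise = pw)
}

#' Expression versus distance from the nearest boundary
#'
#' For each gene, the signed distance of its transcript start from the
#' nearest boundary (gap side negative, half-open rule: distance 0 is the
#' subdomain side), plus median expression within the first 5-kb and 10-kb
#' flanks on each side, split by the adjoining gap's class (small versus
#' medium). Flanks with no genes give a missing median, not 0.
#'
#' @param genes a `gene_table` with expression.
#' @param boundaries a [select_boundaries()] result.
#' @param params an [analysis_params()].
#' @return list with `scatter` (per-gene distance, expression, boundary gap
#'   class) and `medians` (per gap class, side and flank).
#' @export
expression_vs_distance <- function(genes, boundaries,
                                   params = analysis_params()) {
  gc_cut <- params$gap_cutoffs
  bclass <- c("S", "M", "L", "XL")[findInterval(boundaries$gap_len, gc_cut) + 1]
  sc <- lapply(unique(genes$chrom), function(cc) {
    b <- which(boundaries$chrom == cc)
    g <- which(genes$chrom == cc)
    if (!length(b) || !length(g)) return(NULL)
    bp <- boundaries$pos[b]
    o <- order(bp); b <- b[o]; bp <- bp[o]
    k <- findInterval(genes$tstart[g], bp)
    lo <- pmax(k, 1); hi <- pmin(k + 1, length(bp))
    dlo <- abs(genes$tstart[g] - bp[lo]); dhi <- abs(genes$tstart[g] - bp[hi])
    near <- ifelse(k == 0, hi, ifelse(k == length(bp), lo,
                                      ifelse(dlo <= dhi, lo, hi)))
    bi <- b[near]
    data.frame(gene_id = genes$gene_id[g],
               distance = boundary_rel(genes$tstart[g], boundaries$pos[bi],
                                       boundaries$gap_side[bi]),
               expression = genes$expression[g],
               gap_class = bclass[bi], stringsAsFactors = FALSE)
  })
  scatter <- do.call(rbind, c(sc, make.row.names = FALSE))
  med <- expand.grid(gap_class = c("S", "M"), side = c("gap", "subdomain"),
                     flank = c(5e3, 10e3), stringsAsFactors = FALSE)
  med$median <- med$n <- NA_real_
  for (i in seq_len(nrow(med))) {
    sel <- scatter$gap_class == med$gap_class[i] &
      (if (med$side[i] == "gap") scatter$distance < 0 else
        scatter$distance >= 0) &
      abs(scatter$distance) <= med$flank[i]
    med$n[i] <- sum(sel)
    if (any(sel)) med$median[i] <- stats::median(scatter$expression[sel])
  }
  list(scatter = scatter, medians = med)
}

#' Developmental fate of genes silent in early embryos
#'
#' Restricts to genes with dcpm exactly 0 at the first stage and reports,
#' per region class and later stage, the fraction that have become
#' detectable (dcpm > 0).
#'
#' @param stage_matrix stages x genes dcpm matrix (first row = early embryo).
#' @param classes per-gene class labels aligned with the matrix columns.
#' @return data frame with `class`, `stage`, `n_silent_early`,
#'   `frac_active`.
#' @export
silent_gene_fate <- function(stage_matrix, classes) {
  stopifnot(ncol(stage_matrix) == length(classes))
  silent <- stage_matrix[1, ] == 0
  stages <- rownames(stage_matrix)[-1]
  out <- list()
  for (cl in unique(classes[!is.na(classes)])) {
    sel <- silent & classes == cl & !is.na(classes)
    n <- sum(sel)
    for (s in stages) {
      out[[length(out) + 1]] <- data.frame(
        class = cl, stage = s, n_silent_early = n,
        frac_active = if (n) mean(stage_matrix[s, sel] > 0) else NA_real_)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Phenotype enrichment by region class
#'
#' Chi-square goodness-of-fit of the observed phenotype counts within each
#' region class against the phenotype distribution of all annotated genes
#' (the background). Phenotypes annotated for fewer than `min_genes` genes
#' are excluded; categories with zero expected count are dropped with a
#' warning; classes with no annotated genes are flagged untested.
#'
#' @param genes a `gene_table` with a `phenotype` column (`NA` =
#'   unannotated).
#' @param classes per-gene class labels aligned with `genes` rows.
#' @param min_genes minimum genome-wide annotation count for a phenotype.
#' @return list with `tests` (per-class chi-square statistic, df, p) and
#'   `cells` (per class x phenotype observed, expected and direction).
#' @export
phenotype_enrichment <- function(genes, classes, min_genes = 500) {
  stopifnot(nrow(genes) == length(classes))
  ann <- !is.na(genes$phenotype)
  tab <- table(genes$phenotype[ann])
  keep <- names(tab)[tab >= min_genes]
  if (length(keep) < 2)
    stop("at least two phenotypes must pass the annotation minimum")
  bg <- tab[keep] / sum(tab[keep])
  tests <- cells <- list()
  for (cl in unique(classes[!is.na(classes)])) {
    sel <- ann & classes == cl & !is.na(classes) &
      genes$phenotype %in% keep
    n <- sum(sel)
    if (n == 0) {
      tests[[cl]] <- data.frame(class = cl, n = 0L, chisq = NA_real_,
                                df = NA_integer_, p = NA_real_,
                                tested = FALSE)
      next
    }
    obs <- table(factor(genes$phenotype[sel], levels = keep))
    p <- as.numeric(bg)
    drop <- p == 0
    if (any(drop)) {
      warning("dropping zero-expected phenotype categories")
      obs <- obs[!drop]; p <- p[!drop] / sum(p[!drop])
    }
    ct <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p))
    tests[[cl]] <- data.frame(class = cl, n = n,
                              chisq = unname(ct$statistic),
                              df = unname(ct$parameter),
                              p = ct$p.value, tested = TRUE)
    cells[[cl]] <- data.frame(class = cl, phenotype = names(obs),
                              observed = as.numeric(obs),
                              expected = n * p,
                              direction = ifelse(as.numeric(obs) >= n * p,
                                                 "over", "under"))
  }
  list(tests = do.call(rbind, c(unname(tests), make.row.names = FALSE)),
       cells = do.call(rbind, c(unname(cells), make.row.names = FALSE)))
}

#' Occupancy versus chromosome size: correlation and least-squares fit
#'
#' Pearson product-moment correlation (two-sided) and the ordinary
#' least-squares line of occupancy (%) on chromosome size (Mb).
#'
#' @param occ either the [occupancy()] data frame or a numeric vector of
#'   per-chromosome occupancy percentages.
#' @param sizes chromosome sizes in Mb (ignored when `occ` is a data frame).
#' @param exclude chromosome names to drop before fitting (e.g. a sex
#'   chromosome when fitting autosomes only).
#' @return list with `r`, `p`, `intercept`, `slope`, `n`, and `constant`
#'   (TRUE when a zero-variance input made the correlation undefined).
#' @export
size_occupancy_fit <- function(occ, sizes = NULL, exclude = character(0)) {
  if (is.data.frame(occ)) {
    occ <- occ[!(occ$chrom %in% exclude), , drop = FALSE]
    y <- occ$occupancy_pct; x <- occ$size_mb
  } else {
    y <- occ; x <- sizes
  }
  if (length(x) < 3) stop("at least 3 chromosomes are required")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    fit <- stats::lm(y ~ x)
    return(list(r = NA_real_, p = NA_real_,
                intercept = unname(coef(fit)[1]),
                slope = unname(coef(fit)[2]), n = length(x),
                constant = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       n = length(x), constant = FALSE)
}

#' Repeat-family coverage of subdomains by distance to the chromosome end
#'
#' Bins subdomains by the distance of their nearest edge to the nearest
#' chromosome end and reports the mean per-subdomain coverage fraction of
#' each repeat family per bin.
#'
#' @param repeats a `repeat_table`.
#' @param subdomains an [interval_set()].
#' @param genome a [build_genome()] result.
#' @param bin_bp distance bin width in bp.
#' @param families families to profile (default helitron and satellite).
#' @return data frame with `family`, `bin_start`, `mean_coverage`, `n`.
#' @export
end_distance_repeat_profile <- function(repeats, subdomains, genome,
                                        bin_bp = 500e3,
                                        families = c("helitron",
                                                     "satellite")) {
  sub <- as.data.frame(subdomains)
  L <- genome_length(genome, sub$chrom)
  d <- pmin(sub$start, L - sub$end)
  bin <- floor(d / bin_bp)
  out <- list()
  for (fam in families) {
    f <- repeats[repeats$family == fam, , drop = FALSE]
    fr <- covered_bases(sub, f) / (sub$end - sub$start)
    agg <- tapply(fr, bin, mean)
    out[[fam]] <- data.frame(family = fam,
                             bin_start = as.numeric(names(agg)) * bin_bp,
                             mean_coverage = as.numeric(agg),
                             n = as.numeric(table(bin)))
  }
  do.call(rbind, c(unname(out), make.row.names = FALSE))
}

#' Fusion-versus-wild-type association difference along source coordinates
#'
#' Maps a fused-chromosome signal track back to its source chromosomes via
#' the fusion provenance, computes windowed mean differences (fused minus
#' wild type) in non-overlapping windows along each source chromosome, and
#' measures the attenuation extent: the distance from the fusion junction
#' to the far edge of the farthest attenuated window (difference below the
#' negative threshold) reachable through near-zero windows; a clearly
#' positive window ends the walk. Near-zero windows bridge the walk because
#' windows dominated by unassociated gaps dilute the per-base difference
#' toward zero without interrupting the attenuated region.
#'
#' @param profile_wt a [signal_track()] on wild-type (source) coordinates.
#' @param profile_fused a [signal_track()] on fused coordinates.
#' @param genome_fused the fused [build_genome()] result carrying
#'   provenance.
#' @param window_bp analysis window in bp.
#' @param attenuation_threshold differences below this (negative) value
#'   count as attenuated.
#' @return list with `delta` (per source chromosome and window start, the
#'   windowed difference), `extent` (named bp extents per source
#'   chromosome, measured from the junction), and `junction` (fused-genome
#'   coordinate of the fusion point).
#' @export
fusion_delta <- function(profile_wt, profile_fused, genome_fused,
                         window_bp = 100e3, attenuation_threshold = -0.1) {
  prov <- attr(genome_fused, "provenance")
  if (is.null(prov) || !length(prov)) stop("fusion provenance missing")
  fused_name <- names(prov)[length(prov)]
  pv <- prov[[fused_name]]
  fp <- profile_fused[profile_fused$chrom == fused_name, , drop = FALSE]
  if (!nrow(fp)) stop("fused profile has no data on ", fused_name)
  delta <- list(); extent <- numeric(0)
  for (seg in seq_len(nrow(pv))) {
    src <- pv$source[seg]
    wt <- profile_wt[profile_wt$chrom == src, , drop = FALSE]
    if (!nrow(wt)) stop("wild-type profile has no data on source ", src)
    sel <- fp$pos >= pv$start[seg] & fp$pos < pv$end[seg]
    lp <- fp$pos[sel] - pv$start[seg]
    src_pos <- if (pv$strand[seg] == "+") pv$src_start[seg] + lp else
      pv$src_end[seg] - 1 - lp
    bin_f <- floor(src_pos / window_bp)
    mf <- tapply(fp$score[sel], bin_f, mean, na.rm = TRUE)
    bin_w <- floor(wt$pos / window_bp)
    mw <- tapply(wt$score, bin_w, mean, na.rm = TRUE)
    common <- intersect(names(mf), names(mw))
    common <- common[order(as.numeric(common))]
    d <- as.numeric(mf[common]) - as.numeric(mw[common])
    starts <- as.numeric(common) * window_bp
    delta[[src]] <- data.frame(source_chrom = src, bin_start = starts,
                               diff = d)
    # junction sits at the source right end for segment 1 on "+" strand
    # (or segment 2 on "-"), else at the source left end
    at_right <- (seg == 1) == (pv$strand[seg] == "+")
    ord <- if (at_right) rev(seq_along(d)) else seq_along(d)
    # walk from the junction: windows below the threshold are attenuated;
    # near-zero windows (gap-dominated, diluting the per-base difference
    # toward 0) bridge the walk; a clearly positive window ends it. The
    # extent reaches the far edge of the last attenuated window.
    run <- 0; steps <- 0
    for (i in ord) {
      if (is.na(d[i]) || d[i] > -attenuation_threshold) break
      steps <- steps + 1
      if (d[i] < attenuation_threshold) run <- steps
    }
    extent[[src]] <- run * window_bp
  }
  list(delta = do.call(rbind, c(unname(delta), make.row.names = FALSE)),
       extent = extent, junction = pv$end[1])
}

#' Nuclear depth reached by a chromatin loop, as percent of the nuclear
#' diameter
#'
#' Worked geometric example: DNA organized as a 30-nm chromatin fiber spans
#' about 10 nm per kb, so a loop of `loop_bp` reaches at most
#' `loop_bp / 1000 * nm_per_kb` nm from the nuclear membrane, expressed as
#' a percentage of the internal nuclear diameter. With the defaults a
#' 10-kb loop is about 100 nm, i.e. within 5% of a 2-um embryonic nucleus.
#'
#' @param loop_bp loop (gap) size in bp.
#' @param nm_per_kb fiber length per kb of DNA (nm).
#' @param nucleus_diameter_um internal nuclear diameter (um).
#' @return depth as percent of the nuclear diameter.
#' @export
loop_nuclear_depth <- function(loop_bp = 10e3, nm_per_kb = 10,
                               nucleus_diameter_um = 2) {
  fiber_nm <- loop_bp / 1000 * nm_per_kb
  100 * fiber_nm / (nucleus_diameter_um * 1000)
}
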