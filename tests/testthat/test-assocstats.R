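test_that("coverage fractions use interval union, not sums", {
  gm <- build_genome(sim_config(chrom_lengths = 100e3))
  sub <- interval_set("chrI", 10e3, 20e3)
  gaps <- classify_gaps(derive_gaps(sub, gm), analysis_params())
  # a feature covering a region entirely -> fraction 1
  full <- data.frame(chrom = "chrI", start = 0, end = 100e3)
  cc <- coverage_contrast(full, sub, gaps, arm_restrict = FALSE)
  expect_true(all(cc$regions$fraction == 1))
  # overlapping features are unioned
  ovl <- data.frame(chrom = "chrI", start = c(10e3, 12e3), end = c(15e3, 15e3))
  cc2 <- coverage_contrast(ovl, sub, gaps, arm_restrict = FALSE)
  subrow <- cc2$regions[cc2$regions$group == "subdomain", ]
  expect_equal(subrow$fraction, 0.5)
  # union fractions equal per-base counting on random instances
  set.seed(17)
  for (rep in 1:20) {
    feats <- rand_intervals(n = 8, L = 100e3, chrom = "chrI")
    cc3 <- coverage_contrast(feats, sub, gaps, arm_restrict = FALSE)
    for (i in seq_len(nrow(cc3$regions))) {
      expect_equal(cc3$regions$fraction[i],
                   oracle_coverage_fraction(cc3$regions[i, ], feats))
    }
  }
})

test_that("identical coverage distributions give a null rank-sum test", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  sub <- interval_set("chrI", seq(0, 9e5, 1e5), seq(5e4, 9.5e5, 1e5))
  gaps <- classify_gaps(derive_gaps(sub, gm), analysis_params())
  # same uniform feature everywhere -> identical group distributions
  feats <- data.frame(chrom = "chrI", start = seq(0, 999e3, 1e3),
                      end = seq(500, 999500, 1e3))
  cc <- coverage_contrast(feats, sub, gaps, arm_restrict = FALSE)
  expect_gt(cc$tests$p[cc$tests$chrom == "all"], 0.9)
})

test_that("family enrichment flags absent families instead of dividing", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  sub <- interval_set("chrI", 100e3, 300e3)
  gaps <- classify_gaps(derive_gaps(sub, gm), analysis_params())
  reps <- data.frame(family = "helitron", chrom = "chrI",
                     start = c(150e3, 250e3), end = c(151e3, 251e3),
                     center = c(150500, 250500), stringsAsFactors = FALSE)
  class(reps) <- c("repeat_table", "data.frame")
  fe <- family_enrichment(reps, sub, gaps, arm_restrict = FALSE)
  expect_true(fe$absent[fe$family == "LINE"])
  expect_false(fe$absent[fe$family == "helitron"])
  expect_true(is.na(fe$ratio[fe$family == "SINE"]))
})

test_that("permuted region labels null out every family contrast", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  ann <- annotate_genome(gm, tt, cfg, seed = 2)
  sub <- interval_set(tt$chrom, tt$start, tt$end)
  gaps <- classify_gaps(derive_gaps(sub, gm))
  reg <- nmadomains:::region_frame(sub, gaps, arm_restrict = FALSE)
  set.seed(21)
  perm <- sample(reg$group)
  for (fam in c("helitron", "satellite", "simple", "LINE")) {
    f <- ann$repeats[ann$repeats$family == fam, ]
    fr <- nmadomains:::covered_bases(reg, f) / (reg$end - reg$start)
    p <- suppressWarnings(wilcox.test(fr[perm == "subdomain"],
                                      fr[perm == "gap"]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("gene class assignment follows half-open containment", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  sub <- interval_set("chrI", 100e3, 200e3)
  gaps <- classify_gaps(derive_gaps(sub, gm), analysis_params())
  genes <- data.frame(gene_id = c("a", "b", "c"), chrom = "chrI",
                      strand = "+", start = c(99e3, 199e3, 210e3),
                      end = c(102e3, 202e3, 213e3),
                      tstart = c(100e3, 200e3, 210e3),
                      expression = c(1, 2, 3), stringsAsFactors = FALSE)
  cls <- gene_region_class(genes, sub, gaps)
  expect_equal(cls[1], "subdomain")   # start exactly at subdomain start
  expect_false(cls[2] == "subdomain") # end coordinate is outside
  ebc <- expression_by_gap_class(genes, sub, gaps)
  expect_equal(ebc$class[1], "subdomain")
  # all-equal expression -> no significant pairwise test
  genes$expression <- 5
  ebc2 <- expression_by_gap_class(rbind(genes, genes, genes), sub, gaps)
  expect_true(all(ebc2$pairwise$p > 0.9, na.rm = TRUE))
})

test_that("expression-vs-distance medians are missing when flanks are empty", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  sub <- interval_set("chrI", c(50e3, 300e3), c(200e3, 400e3))
  gaps <- classify_gaps(derive_gaps(sub, gm), analysis_params())
  b <- select_boundaries(sub, gaps)  # first boundary adjoins a 50-kb M gap
  genes <- data.frame(gene_id = "g", chrom = "chrI", strand = "+",
                      start = 50e3, end = 53e3, tstart = 50e3,
                      expression = 7, stringsAsFactors = FALSE)
  ev <- expression_vs_distance(genes, b)
  # gene exactly at a boundary: distance 0, subdomain side
  expect_equal(ev$scatter$distance, 0)
  sub_5k <- ev$medians[ev$medians$side == "subdomain" &
                         ev$medians$flank == 5e3, ]
  expect_true(any(sub_5k$median == 7, na.rm = TRUE))
  gap_5k <- ev$medians[ev$medians$side == "gap" & ev$medians$flank == 5e3, ]
  expect_true(all(is.na(gap_5k$median)))
})

test_that("silent-gene fate counts activation from zero dcpm only", {
  m <- rbind(early = c(0, 0, 5, 0), L3 = c(0, 5, 6, 0), adult = c(0, 7, 6, 0))
  colnames(m) <- paste0("g", 1:4)
  cls <- c("subdomain", "gap", "gap", "gap")
  sf <- silent_gene_fate(m, cls)
  # the always-expressed gene g3 is never part of the silent set
  expect_equal(unique(sf$n_silent_early[sf$class == "gap"]), 2)
  expect_equal(sf$frac_active[sf$class == "gap" & sf$stage == "L3"], 0.5)
  expect_equal(sf$frac_active[sf$class == "subdomain" & sf$stage == "adult"], 0)
})

test_that("phenotype enrichment reproduces the chi-square by hand", {
  genes <- data.frame(gene_id = paste0("g", 1:140), chrom = "c", strand = "+",
                      start = 1:140, end = 2:141, tstart = 1:140,
                      expression = 1,
                      phenotype = c(rep("A", 70), rep("B", 70)),
                      stringsAsFactors = FALSE)
  classes <- c(rep("S", 40), rep("XL", 30), rep("S", 10), rep("XL", 60))
  # class S observes 40 A vs 10 B against a 50/50 background:
  # (30-20)^2/20 + ... computed on the toy scale below
  toy <- phenotype_enrichment(genes, classes, min_genes = 50)
  srow <- toy$tests[toy$tests$class == "S", ]
  # observed 40/10, expected 25/25 -> chi2 = 2 * 15^2 / 25 = 18
  expect_equal(srow$chisq, 18)
  # observed == expected gives statistic 0
  genes2 <- genes; genes2$phenotype <- rep(c("A", "B"), 70)
  t2 <- phenotype_enrichment(genes2, rep("S", 140), min_genes = 50)
  expect_equal(t2$tests$chisq, 0)
  # a class with no annotated genes is flagged untested
  genes3 <- genes; genes3$phenotype[classes == "XL"] <- NA
  t3 <- phenotype_enrichment(genes3, classes, min_genes = 10)
  expect_false(t3$tests$tested[t3$tests$class == "XL"])
})

test_that("hand toy chi-square: 30/10 against 50/50 gives 10", {
  genes <- data.frame(gene_id = paste0("g", 1:840), chrom = "c", strand = "+",
                      start = 1:840, end = 2:841, tstart = 1:840,
                      expression = 1,
                      phenotype = c(rep("A", 30 + 390), rep("B", 10 + 410)),
                      stringsAsFactors = FALSE)
  classes <- c(rep("S", 30), rep("bg", 390), rep("S", 10), rep("bg", 410))
  pe <- phenotype_enrichment(genes, classes, min_genes = 400)
  expect_equal(pe$tests$chisq[pe$tests$class == "S"], 10)
})

test_that("occupancy-size fit recovers exact lines and flags degeneracy", {
  fit <- size_occupancy_fit(c(33, 36, 39), c(1, 3, 5))
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$intercept, 31.5)
  set.seed(18)
  x <- runif(5, 10, 21); y <- runif(5, 20, 65)
  f2 <- size_occupancy_fit(y, x)
  bx <- cov(x, y) / var(x)
  expect_equal(f2$slope, bx)
  expect_equal(f2$intercept, mean(y) - bx * mean(x))
  expect_equal(f2$r, cor(x, y))
  f3 <- size_occupancy_fit(c(50, 50, 50), c(10, 12, 14))
  expect_true(f3$constant)
  expect_true(is.na(f3$r))
  expect_error(size_occupancy_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("end-distance repeat profiles bin subdomains by terminal distance", {
  gm <- build_genome(sim_config(chrom_lengths = 10e6))
  sub <- interval_set("chrI", c(0, 2e6), c(100e3, 2.2e6))
  reps <- data.frame(family = "helitron", chrom = "chrI",
                     start = c(10e3, 2.05e6), end = c(20e3, 2.06e6),
                     center = c(15e3, 2055000), stringsAsFactors = FALSE)
  class(reps) <- c("repeat_table", "data.frame")
  pr <- end_distance_repeat_profile(reps, sub, gm, bin_bp = 500e3,
                                    families = "helitron")
  expect_equal(sort(pr$bin_start), c(0, 2e6))
  expect_equal(pr$mean_coverage[pr$bin_start == 0], 0.1)
  # uniform repeats across all subdomains give a flat profile
  sub2 <- interval_set("chrI", seq(0, 4e6, 1e6), seq(0, 4e6, 1e6) + 1e5)
  reps2 <- do.call(rbind, lapply(seq(0, 4e6, 1e6), function(s)
    data.frame(family = "satellite", chrom = "chrI", start = s,
               end = s + 1e4, center = s + 5e3)))
  class(reps2) <- c("repeat_table", "data.frame")
  pr2 <- end_distance_repeat_profile(reps2, sub2, gm, bin_bp = 500e3,
                                     families = "satellite")
  expect_true(all(abs(pr2$mean_coverage - 0.1) < 1e-12))
})

test_that("fusion deltas are zero for identical profiles and error without provenance", {
  cfg <- sim_config(chrom_lengths = c(2e6, 2e6))
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  fz <- fuse(gm, tt, "chrI", "right", "chrII", "left", cfg)
  pos <- seq(25, by = 50, length.out = 4e6 / 50)
  fused_tr <- signal_track(rep("chrI-chrII", length(pos)), pos,
                           rep(1, length(pos)), step = 50)
  wt_pos <- seq(25, by = 50, length.out = 2e6 / 50)
  wt_tr <- signal_track(rep(c("chrI", "chrII"), each = length(wt_pos)),
                        rep(wt_pos, 2), rep(1, 2 * length(wt_pos)), step = 50)
  fd <- fusion_delta(wt_tr, fused_tr, fz$genome, window_bp = 1e5)
  expect_true(all(fd$delta$diff == 0))
  expect_true(all(fd$extent == 0))
  expect_error(fusion_delta(wt_tr, fused_tr, gm), "provenance")
  other <- signal_track("chrZ", 25, 1, step = 50)
  expect_error(fusion_delta(other, fused_tr, fz$genome), "no data")
})

test_that("a 10-kb loop reaches five percent of the nuclear diameter", {
  expect_equal(loop_nuclear_depth(10e3), 5)
  expect_equal(loop_nuclear_depth(20e3), 10)
  expect_equal(loop_nuclear_depth(10e3, nucleus_diameter_um = 4), 2.5)
})
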