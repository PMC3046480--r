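test_that("genome construction respects lengths and rejects degenerate input", {
  cfg <- sim_config(chrom_lengths = c(10e6, 8e6))
  gm <- build_genome(cfg)
  expect_equal(nrow(gm), 2)
  expect_equal(sum(gm$length), 18e6)
  expect_identical(gm, build_genome(cfg))
  expect_error(sim_config(chrom_lengths = numeric(0)), "at least one")
  expect_error(sim_config(chrom_lengths = c(1e6, -5)), "positive")
})

test_that("planted domains sit in arms with occupancy at target", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  # zero target -> nothing planted
  t0 <- plant_truth(gm, sim_config(chrom_lengths = 2e6, arm_occupancy = 0),
                    seed = 1)
  expect_equal(nrow(t0), 0)
  occs <- vapply(1:200, function(s) {
    tt <- plant_truth(gm, cfg, seed = s)
    arm_len <- floor(2e6 * cfg$arm_fraction)
    arms <- attr(tt, "arms")
    arm_bp <- sum((arms$end - arms$start)[arms$part == "arm"])
    # all intervals inside arm regions
    for (i in seq_len(nrow(tt))) {
      a <- arms[arms$chrom == tt$chrom[i] & arms$part == "arm", ]
      expect_true(any(tt$start[i] >= a$start & tt$end[i] <= a$end))
    }
    sum(tt$end - tt$start) / arm_bp
  }, numeric(1))
  expect_lt(abs(mean(occs) - cfg$arm_occupancy), 0.03)
})

test_that("planted sizes shrink and strengths decay away from chromosome ends", {
  cfg <- sim_config(chrom_lengths = 10e6)
  gm <- build_genome(cfg)
  outer <- inner <- strengths_outer <- strengths_inner <- c()
  for (s in 1:40) {
    tt <- plant_truth(gm, cfg, seed = s)
    mid <- (tt$start + tt$end) / 2
    d <- pmin(mid, 10e6 - mid)          # distance to nearest end
    arm <- floor(10e6 * cfg$arm_fraction)
    sz <- tt$end - tt$start
    outer <- c(outer, sz[d < arm / 3])
    inner <- c(inner, sz[d > 2 * arm / 3])
    strengths_outer <- c(strengths_outer, tt$strength[d < arm / 3])
    strengths_inner <- c(strengths_inner, tt$strength[d > 2 * arm / 3])
  }
  expect_gt(median(outer), median(inner))
  expect_gt(mean(strengths_outer), mean(strengths_inner))
})

test_that("annotations carry the configured repeat and gene biases", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  hel_ratio <- line_ratio <- gene_sub <- gene_gap <- c()
  for (s in 1:5) {
    tt <- plant_truth(gm, cfg, seed = s)
    ann <- annotate_genome(gm, tt, cfg, seed = s + 50)
    sub <- interval_set(tt$chrom, tt$start, tt$end)
    gaps <- classify_gaps(derive_gaps(sub, gm))
    fe <- family_enrichment(ann$repeats, sub, gaps, arm_restrict = FALSE)
    hel_ratio <- c(hel_ratio, fe$ratio[fe$family == "helitron"])
    line_ratio <- c(line_ratio, fe$ratio[fe$family == "LINE"])
    cc <- coverage_contrast(ann$genes, sub, gaps, arm_restrict = FALSE)
    ov <- cc$tests[cc$tests$chrom == "all", ]
    gene_sub <- c(gene_sub, ov$median_subdomain_pct)
    gene_gap <- c(gene_gap, ov$median_gap_pct)
  }
  expect_gt(mean(hel_ratio), mean(line_ratio))
  expect_gt(mean(gene_gap), mean(gene_sub))
})

test_that("null repeat contrast shows no subdomain/gap difference", {
  cfg <- null_config(len = c(2e6, 2e6))
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  ann <- annotate_genome(gm, tt, cfg, seed = 2)
  sub <- interval_set(tt$chrom, tt$start, tt$end)
  gaps <- classify_gaps(derive_gaps(sub, gm))
  cc <- coverage_contrast(ann$repeats, sub, gaps, arm_restrict = FALSE)
  expect_gt(cc$tests$p[cc$tests$chrom == "all"], 0.01)
})

test_that("array simulation separates planted from background and is seeded", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  a1 <- simulate_array(tt, gm, cfg, n_replicates = 2, seed = 7)
  a2 <- simulate_array(tt, gm, cfg, n_replicates = 2, seed = 7)
  expect_identical(a1, a2)
  ip <- a1$ip[[1]]
  inside <- !is.na(nmadomains:::interval_index_of(ip$chrom, ip$pos, tt))
  expect_gt(mean(ip$score[inside]), mean(ip$score[!inside]))
  # null: IP and control indistinguishable when nothing is planted
  t0 <- plant_truth(gm, tiny_config(arm_occupancy = 0), seed = 1)
  a0 <- simulate_array(t0, gm, cfg, n_replicates = 1, seed = 7)
  p <- wilcox.test(a0$ip[[1]]$score, a0$control[[1]]$score)$p.value
  expect_gt(p, 0.01)
})

test_that("fragment simulation has Poisson mass and seed determinism", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  f1 <- simulate_seq(tt, gm, cfg, seed = 5)
  f2 <- simulate_seq(tt, gm, cfg, seed = 5)
  expect_identical(f1, f2)
  # expected background fragments: depth / extension * genome length
  lam <- cfg$seq_depth / cfg$read_extension * sum(gm$length)
  expect_lt(abs(nrow(f1$control) - lam) / lam, 0.05)
  # zero depth -> empty lists
  f0 <- simulate_seq(tt, gm, tiny_config(seq_depth = 0, seq_input_depth = 0),
                     seed = 5)
  expect_equal(nrow(f0$ip) + nrow(f0$control) + nrow(f0$input), 0)
})

test_that("mark tracks follow their configured geography", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  ann <- annotate_genome(gm, tt, cfg, seed = 2)
  mk <- simulate_marks(tt, ann$genes, gm, cfg, seed = 3)
  k27 <- mk$H3K27me3
  inside <- !is.na(nmadomains:::interval_index_of(k27$chrom, k27$pos, tt))
  expect_gt(mean(k27$score[inside]), mean(k27$score[!inside]))
  k4 <- mk$H3K4me3
  expect_gt(max(tapply(k4$score, inside, mean)) -
              min(tapply(k4$score, inside, mean)), 0)
  # null effects -> no contrast
  mk0 <- simulate_marks(tt, ann$genes, gm,
                        tiny_config(k27_effect = 0, k9_effect = 0,
                                    active_effect = 0), seed = 3)
  p <- wilcox.test(mk0$H3K27me3$score[inside],
                   mk0$H3K27me3$score[!inside])$p.value
  expect_gt(p, 0.01)
})

test_that("staged expression orders classes and honors persistence", {
  cfg <- tiny_config()
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  ann <- annotate_genome(gm, tt, cfg, seed = 2)
  sm <- simulate_expression_stages(ann$genes, tt, gm, cfg, seed = 3)
  expect_equal(nrow(sm), cfg$n_stages)
  cls <- gene_region_class(ann$genes,
                           interval_set(tt$chrom, tt$start, tt$end),
                           classify_gaps(derive_gaps(
                             interval_set(tt$chrom, tt$start, tt$end), gm)))
  med <- tapply(sm[1, ], cls, function(v) median(v[v > 0]))
  expect_gt(med[["S"]], med[["M"]])
  expect_gt(med[["M"]], med[["L"]])
  expect_true(all(med[["subdomain"]] < med[c("S", "M", "L")]))
  # full persistence -> early-silent subdomain genes stay silent
  cfgp <- tiny_config(persistence = c(subdomain = 1, gap = 0.7))
  smp <- simulate_expression_stages(ann$genes, tt, gm, cfgp, seed = 3)
  silent_sub <- smp[1, ] == 0 & cls == "subdomain" & !is.na(cls)
  expect_true(all(smp[, silent_sub] == 0))
})

test_that("fusion remaps coordinates, provenance and strengths exactly", {
  cfg <- sim_config(chrom_lengths = c(10e6, 8e6), end_bonus = 0.5)
  gm <- build_genome(cfg)
  tt <- plant_truth(gm, cfg, seed = 1)
  fz <- fuse(gm, tt, "chrI", "right", "chrII", "left", cfg)
  expect_equal(sum(fz$genome$length), 18e6)
  # multiset of interval lengths is preserved
  expect_equal(sort(fz$truth$end - fz$truth$start),
               sort(tt$end - tt$start))
  # an interval at [1 Mb, 2 Mb) on the second segment maps to [11, 12) Mb
  i2 <- which(tt$chrom == "chrII")[1]
  j <- which(fz$truth$start == tt$start[i2] + 10e6)
  expect_equal(fz$truth$end[j], tt$end[i2] + 10e6)
  # order preserved on both segments for a right-left fusion
  expect_false(is.unsorted(fz$truth$start))
  # strengths near the junction drop by exactly the bonus
  lost <- tt$chrom == "chrI" & !is.na(tt$near_end) & tt$near_end == "right"
  mapped <- fz$truth[match(tt$start[lost], fz$truth$start), ]
  expect_equal(mapped$strength, tt$strength[lost] - 0.5)
  # untouched ends keep their bonus
  keep <- tt$chrom == "chrI" & !is.na(tt$near_end) & tt$near_end == "left"
  expect_equal(fz$truth$strength[match(tt$start[keep], fz$truth$start)],
               tt$strength[keep])
  expect_error(fuse(gm, tt, "chrI", "right", "chrI", "left", cfg), "itself")
  expect_error(fuse(gm, tt, "chrZ", "right", "chrII", "left", cfg), "unknown")
})
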