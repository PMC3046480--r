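mk_tiling <- function(gm, sub_df) {
  sub <- interval_set(sub_df$chrom, sub_df$start, sub_df$end)
  gaps <- classify_gaps(derive_gaps(sub, gm), analysis_params())
  list(sub = sub, gaps = gaps)
}

test_that("boundary selection excludes chromosome starts and caps small-gap flanks", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  tl <- mk_tiling(gm, data.frame(chrom = "chrI",
                                 start = c(0, 100e3, 203e3),
                                 end = c(50e3, 200e3, 300e3)))
  b <- select_boundaries(tl$sub, tl$gaps)
  # the subdomain starting at 0 contributes no boundary
  expect_equal(nrow(b), 2)
  expect_equal(b$pos, c(100e3, 203e3))
  # a 3-kb gap limits the gap-side flank to the gap size
  expect_equal(b$gap_flank[b$pos == 203e3], 3e3)
  expect_equal(b$gap_flank[b$pos == 100e3], 10e3)
  # ten interior subdomains give ten boundaries
  tl2 <- mk_tiling(gm, data.frame(chrom = "chrI",
                                  start = seq(50e3, 950e3, 100e3),
                                  end = seq(80e3, 980e3, 100e3)))
  expect_equal(nrow(select_boundaries(tl2$sub, tl2$gaps)), 10)
})

test_that("count metaplots match the per-boundary oracle", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  tl <- mk_tiling(gm, data.frame(chrom = "chrI", start = c(100e3, 300e3),
                                 end = c(200e3, 400e3)))
  b <- select_boundaries(tl$sub, tl$gaps)
  # single feature at +1.2 kb: counted only in windows covering +1.2 kb
  one <- data.frame(chrom = "chrI", pos = 101200)
  pr <- count_metaplot(one, b[1, ], 1000, 500, 10e3)
  hit <- pr$offset - 500 <= 1200 & pr$offset + 500 > 1200
  expect_true(all(pr$mean[hit] == 1))
  expect_true(all(pr$mean[!hit] == 0))
  # no features: all-zero profile with full boundary counts
  pr0 <- count_metaplot(data.frame(chrom = character(0), pos = numeric(0)),
                        b, 1000, 500, 10e3)
  expect_true(all(pr0$mean == 0))
  expect_true(all(pr0$n == nrow(b)))
  # random points vs oracle
  set.seed(13)
  for (rep in 1:20) {
    pts <- data.frame(chrom = "chrI", pos = sample.int(500e3, 50))
    got <- count_metaplot(pts, b, 1000, 500, 8e3)
    want <- oracle_count_profile(pts, b, 1000, 500, 8e3)
    expect_equal(got$mean, want$mean)
    expect_equal(got$n, want$n)
  }
  expect_error(count_metaplot(one, b, 1000, 500, 0), "positive")
})

test_that("signal metaplots average windows with orientation contract", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  tl <- mk_tiling(gm, data.frame(chrom = "chrI", start = 100e3, end = 200e3))
  b <- select_boundaries(tl$sub, tl$gaps)
  n <- 500
  pos <- seq(90e3, by = 50, length.out = n)
  # constant track -> constant profile
  cons <- signal_track(rep("chrI", n), pos, rep(3.3, n), step = 50)
  pc <- signal_metaplot(cons, b, 100, 50, 5e3)
  expect_true(all(abs(pc$mean[!is.na(pc$mean)] - 3.3) < 1e-12))
  # random track vs windowed-mean oracle at each offset
  set.seed(14)
  tr <- signal_track(rep("chrI", n), pos, rnorm(n), step = 50)
  pr <- signal_metaplot(tr, b, 100, 50, 5e3)
  want <- oracle_window_mean(tr$pos, tr$score, 100e3 + pr$offset, 50)
  expect_equal(pr$mean, want)
  # mirrored data with flipped orientation reverses the profile
  b_flip <- b; b_flip$gap_side <- "right"
  pf <- signal_metaplot(tr, b_flip, 100, 50, 5e3)
  want_f <- oracle_window_mean(tr$pos, tr$score, 100e3 - pf$offset, 50)
  expect_equal(pf$mean, want_f)
})

test_that("oriented gene metaplots split by transcription direction", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  tl <- mk_tiling(gm, data.frame(chrom = "chrI", start = 100e3, end = 200e3))
  b <- select_boundaries(tl$sub, tl$gaps)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chrI",
                      strand = c("+", "-", "+"),
                      start = c(95e3, 96e3, 99e3), end = c(98e3, 99e3, 103e3),
                      tstart = c(95200, 98800, 99100),
                      expression = c(1, 2, 3), stringsAsFactors = FALSE)
  class(genes) <- c("gene_table", "data.frame")
  om <- oriented_gene_metaplot(genes, b, analysis_params(), flank_bp = 10e3)
  # g1 (+, gap-left boundary) points toward the subdomain; g2 (-) toward gap
  expect_equal(sum(om$profiles$toward_subdomain$mean, na.rm = TRUE) > 0, TRUE)
  expect_equal(sum(om$profiles$toward_gap$mean, na.rm = TRUE) > 0, TRUE)
  # only g3 spans the boundary, on the toward-subdomain side
  expect_equal(unname(om$traversing["toward_subdomain"]), 1)
  expect_equal(unname(om$traversing["toward_gap"]), 0)
  # all genes one strand + one orientation -> the other profile is empty
  g_plus <- genes[genes$strand == "+", ]
  om2 <- oriented_gene_metaplot(g_plus, b, analysis_params(), flank_bp = 10e3)
  expect_equal(sum(om2$profiles$toward_gap$mean, na.rm = TRUE), 0)
})

test_that("gene-body profiles filter, orient by strand, and shrink CIs", {
  gm <- build_genome(sim_config(chrom_lengths = 1e6))
  set.seed(15)
  n <- 40
  starts <- seq(20e3, by = 20e3, length.out = n)
  genes <- data.frame(gene_id = paste0("g", 1:n), chrom = "chrI",
                      strand = rep(c("+", "-"), n / 2),
                      start = starts, end = starts + 5000,
                      tstart = starts + 100,
                      expression = seq_len(n), stringsAsFactors = FALSE)
  class(genes) <- c("gene_table", "data.frame")
  pos <- seq(25, by = 50, length.out = 20e3)
  cons <- signal_track(rep("chrI", length(pos)), pos, rep(2, length(pos)),
                       step = 50)
  gb <- gene_body_metaplot(cons, genes, params = analysis_params(),
                           flank_bp = 1000)
  # constant track -> flat profiles with CI ~ 1/sqrt(n) (zero here: sd = 0)
  expect_true(all(abs(gb$TSS$top$mean - 2) < 1e-12, na.rm = TRUE))
  expect_true(all(gb$TSS$top$ci[!is.na(gb$TSS$top$ci)] < 1e-12))
  # a 1.5-kb gene is excluded from the analysis set
  short <- genes; short$end[1] <- short$start[1] + 1500
  gb2 <- gene_body_metaplot(cons, short, params = analysis_params(),
                            flank_bp = 1000)
  expect_equal(attr(gb2, "n_analyzed"), attr(gb, "n_analyzed") - 1)
  # minus-strand genes are profiled on reversed coordinates
  ramp <- signal_track(rep("chrI", length(pos)), pos, pos / 1e6, step = 50)
  g1 <- genes[1, ]; g1$strand <- "+"
  g2 <- genes[1, ]; g2$strand <- "-"
  two <- rbind(g1, g1, g2, g2)
  two$gene_id <- paste0("g", 1:4)
  two$start <- two$start + c(0, 40e3, 80e3, 120e3)
  two$end <- two$end + c(0, 40e3, 80e3, 120e3)
  two$expression <- c(10, 10, 1, 1)
  class(two) <- c("gene_table", "data.frame")
  gbr <- gene_body_metaplot(ramp, two, params = analysis_params(),
                            flank_bp = 500)
  slope_plus <- diff(gbr$TSS$top$mean)
  slope_minus <- diff(gbr$TSS$bottom$mean)
  expect_true(all(slope_plus > 0))
  expect_true(all(slope_minus < 0))
  expect_error(gene_body_metaplot(cons, genes[1, ],
                                  params = analysis_params()), "fewer than 2")
})

test_that("uniform features converge to density times window size", {
  gm <- build_genome(sim_config(chrom_lengths = 2e6))
  tl <- mk_tiling(gm, data.frame(chrom = "chrI",
                                 start = seq(100e3, 1.9e6, 200e3),
                                 end = seq(180e3, 1.98e6, 200e3)))
  b <- select_boundaries(tl$sub, tl$gaps)
  set.seed(16)
  rho <- 0.005  # points per bp
  pts <- data.frame(chrom = "chrI", pos = sample.int(2e6, 2e6 * rho))
  pr <- count_metaplot(pts, b, 1000, 500, 8e3)
  expect_lt(max(abs(pr$mean - rho * 1000), na.rm = TRUE), 2.5)
  expect_lt(abs(mean(pr$mean, na.rm = TRUE) - rho * 1000), 0.5)
})
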