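#' Simulation configuration
#'
#' Collects every tunable of the synthetic-genome simulator: chromosome
#' layout, planted-subdomain geometry, association-strength model, probe and
#' fragment noise models, and the effect sizes used for annotations, chromatin
#' marks and staged expression. Defaults emulate the architecture of a
#' holocentric genome whose chromosome arms carry nuclear-membrane-association
#' domains punctuated by gaps: domains are confined to terminal arm regions,
#' larger and stronger near the physical chromosome ends, with repeat families
#' (helitron and satellite strongest) enriched inside domains and genes,
#' expression and active marks enriched in the gaps.
#'
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param probe_spacing probe/grid spacing in bp.
#' @param arm_fraction fraction of each chromosome length, at each end,
#'   treated as arm and eligible for domain planting (in (0, 0.5]).
#' @param arm_occupancy target fraction of arm bases inside planted domains.
#' @param size_median log-normal median of planted-domain size (bp) for a
#'   domain at a chromosome end.
#' @param size_sdlog log-normal shape (sdlog) of domain sizes.
#' @param size_decay multiplicative decay rate of the size median per Mb of
#'   distance from the nearest chromosome end.
#' @param gap_weights mixture weights of the small/medium/large gap-size
#'   components (normalized internally). The default weights and medians are
#'   set so the expected gap size balances the expected domain size at the
#'   default occupancy, letting planted domains span the whole arm.
#' @param gap_medians log-normal medians (bp) of the three gap components.
#' @param gap_sdlog log-normal shape shared by the gap components.
#' @param gap_grow multiplicative growth rate of gap sizes per Mb of
#'   distance from the nearest chromosome end: gaps are small near the ends
#'   and widen toward the chromosome center, mirroring the observed
#'   arm architecture.
#' @param min_domain minimum planted-domain size in bp.
#' @param strength_end association strength (score units, i.e. units of the
#'   array noise SD) of a domain at a chromosome end.
#' @param strength_decay linear strength decay in score units per Mb of
#'   distance from the nearest end.
#' @param end_bonus additive strength bonus for domains whose midpoint lies
#'   within `end_bonus_window` of a physical chromosome end.
#' @param end_bonus_window width of the terminal bonus window in bp.
#' @param min_strength floor applied to planted strengths.
#' @param array_noise_sd per-probe log-ratio noise SD.
#' @param gc_shape1,gc_shape2 Beta parameters of the per-probe GC fraction.
#' @param gc_bias_slope additive probe bias per unit of (GC - mean GC).
#' @param nonunique_prob probability that a probe is flagged non-unique.
#' @param seq_depth expected fragments per read-extension-length window for
#'   the IP and control sequencing libraries.
#' @param seq_input_depth expected fragments per extension window for the
#'   input library (downsampled to match IP at normalization time).
#' @param read_extension computational read extension in bp.
#' @param seq_fold_ref fold-enrichment of the IP fragment rate inside a
#'   domain at the reference (chromosome-end) strength; enrichment scales
#'   linearly with strength, so fold = 1 + (seq_fold_ref - 1) * s / strength_end.
#' @param gene_density_gap,gene_density_domain genes per Mb outside/inside
#'   planted domains.
#' @param gene_length_median,gene_length_sdlog log-normal gene length (bp).
#' @param tss_edge_fraction fraction of gap genes whose translation start is
#'   placed within 2 kb outside a domain edge.
#' @param repeat_density_gap named numeric: repeats per Mb, per family, in
#'   gaps. Families are fixed: helitron, satellite, simple, DNA-transposon,
#'   low-complexity, LINE, SINE, LTR.
#' @param repeat_contrast named numeric: multiplicative density contrast
#'   (domain over gap) per family.
#' @param repeat_length_median,repeat_length_sdlog log-normal repeat length.
#' @param repeat_terminal_factor multiplier on helitron/satellite density for
#'   repeats within `end_bonus_window` of a chromosome end (1 = none).
#' @param mark_noise_sd noise SD of simulated chromatin-mark z-score tracks.
#' @param k27_effect,k9_effect,active_effect effect sizes (score units) for
#'   H3K27me3 over domains, H3K9me2/me3 over domains, and active marks
#'   (H3K4me3/RNAPII/HTZ-1) over expressed gap genes.
#' @param expr_meanlog baseline log expression (dcpm scale) of an active gene.
#' @param expr_sdlog log-scale expression spread.
#' @param expr_class_shift named numeric log-scale shifts by region class
#'   (subdomain, S, M, L, XL).
#' @param silent_prob named numeric: probability a gene is silent (dcpm 0) in
#'   the first stage, for subdomain vs gap genes.
#' @param persistence named numeric: per-stage probability that an
#'   early-silent gene stays silent at the next stage, subdomain vs gap.
#' @param n_stages number of developmental stages (>= 2; the first is the
#'   early-embryo reference).
#' @param phenotypes character vector of phenotype labels assignable to genes.
#' @param phenotype_base_prob baseline probability that a gene carries each
#'   phenotype (background multinomial over `phenotypes` plus unannotated).
#' @param phenotype_domain_factor multiplier on essential-phenotype
#'   probabilities for subdomain genes (< 1 depletes them at the membrane).
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(chrom_lengths = c(10e6, 10e6),
                       probe_spacing = 50,
                       arm_fraction = 0.3,
                       arm_occupancy = 0.5,
                       size_median = 1e5,
                       size_sdlog = 0.8,
                       size_decay = 0.4,
                       gap_weights = c(S = 0.42, M = 0.38, L = 0.20),
                       gap_medians = c(S = 6e3, M = 3e4, L = 2.8e5),
                       gap_sdlog = 0.6,
                       gap_grow = 0.8,
                       min_domain = 11e3,
                       strength_end = 0.6,
                       strength_decay = 0.05,
                       end_bonus = 0.2,
                       end_bonus_window = 1e6,
                       min_strength = 0.05,
                       array_noise_sd = 1,
                       gc_shape1 = 10,
                       gc_shape2 = 17,
                       gc_bias_slope = 1,
                       nonunique_prob = 0.03,
                       seq_depth = 3,
                       seq_input_depth = 6,
                       read_extension = 300,
                       seq_fold_ref = 2,
                       gene_density_gap = 180,
                       gene_density_domain = 100,
                       gene_length_median = 2500,
                       gene_length_sdlog = 0.6,
                       tss_edge_fraction = 0.25,
                       repeat_density_gap = c(
                         helitron = 30, satellite = 30, simple = 150,
                         `DNA-transposon` = 60, `low-complexity` = 100,
                         LINE = 20, SINE = 20, LTR = 20),
                       repeat_contrast = c(
                         helitron = 8, satellite = 8, simple = 1.5,
                         `DNA-transposon` = 1.5, `low-complexity` = 1.3,
                         LINE = 1.5, SINE = 1.5, LTR = 1.5),
                       repeat_length_median = 300,
                       repeat_length_sdlog = 0.7,
                       repeat_terminal_factor = 1,
                       mark_noise_sd = 1,
                       k27_effect = 1,
                       k9_effect = 0.2,
                       active_effect = 1.5,
                       expr_meanlog = 1,
                       expr_sdlog = 1,
                       expr_class_shift = c(subdomain = -1, S = 3, M = 2,
                                            L = 1, XL = 1.5),
                       silent_prob = c(subdomain = 0.6, gap = 0.3),
                       persistence = c(subdomain = 0.95, gap = 0.7),
                       n_stages = 6,
                       phenotypes = c("embryonic lethal", "slow growth",
                                      "protruding vulva", "maternal sterile"),
                       phenotype_base_prob = c(0.12, 0.08, 0.05, 0.05),
                       phenotype_domain_factor = 0.5) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$chrom_lengths) < 1)
    stop("at least one chromosome length is required")
  if (any(cfg$chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  if (cfg$probe_spacing <= 0) stop("probe_spacing must be positive")
  if (cfg$arm_fraction <= 0 || cfg$arm_fraction > 0.5)
    stop("arm_fraction must be in (0, 0.5]")
  if (cfg$arm_occupancy < 0 || cfg$arm_occupancy > 1)
    stop("arm_occupancy must be in [0, 1]")
  if (cfg$seq_depth < 0 || cfg$seq_input_depth < 0)
    stop("sequencing depths must be non-negative")
  if (cfg$read_extension < 1) stop("read_extension must be >= 1")
  if (cfg$n_stages < 2) stop("n_stages must be >= 2")
  stopifnot(length(cfg$gap_weights) == 3, length(cfg$gap_medians) == 3)
  fams <- repeat_families()
  if (!all(fams %in% names(cfg$repeat_density_gap)) ||
      !all(fams %in% names(cfg$repeat_contrast)))
    stop("repeat_density_gap and repeat_contrast must cover all families")
  invisible(cfg)
}

#' The fixed repeat-family vocabulary
#' @return character vector of the eight repeat family names.
#' @export
repeat_families <- function() {
  c("helitron", "satellite", "simple", "DNA-transposon",
    "low-complexity", "LINE", "SINE", "LTR")
}

#' Analysis parameters of the subdomain caller and downstream statistics
#'
#' Holds every numeric constant of the calling and sliding-window procedures:
#' a 200-probe (about 10 kb) array window sliding one probe, a 10-kb
#' sequencing window at 50-bp offsets, strict binary-mean thresholds of 0.8
#' (array) and 0.4 (sequencing) with empirical false-discovery ceilings of
#' 2.5% and 2.4%, merging of positive windows overlapping by at least 1 bp,
#' gap size classes at 10 kb / 100 kb / 1 Mb, the 5-kb small-gap flank rule
#' for boundary analyses, metaplot windows (1 kb / 500 bp for feature counts,
#' 100 bp / 50 bp for signal), the 20% expression quantile and 2-kb minimum
#' gene length for gene-body profiles, read extensions, and the 5-kb
#' visualization bin.
#'
#' @param array_window array window size in probes.
#' @param array_offset array window offset in probes.
#' @param seq_window sequencing window size in bp.
#' @param seq_offset sequencing window offset in bp.
#' @param array_threshold strict (>) binary-mean threshold, array platform.
#' @param seq_threshold strict (>) binary-mean threshold, sequencing platform.
#' @param fdr_ceiling_array,fdr_ceiling_seq empirical false-discovery-ratio
#'   ceilings (fractions).
#' @param min_overlap minimum genuine overlap in bp when merging windows.
#' @param gap_cutoffs strictly increasing length cutoffs (bp) separating the
#'   S/M/L/XL gap classes.
#' @param small_gap_flank gaps shorter than this (bp) limit the gap-side
#'   boundary flank to the gap size.
#' @param boundary_flank default metaplot flank on each side of a boundary (bp).
#' @param count_window,count_offset feature-count metaplot window/offset (bp).
#' @param signal_window,signal_offset signal metaplot window/offset (bp).
#' @param expr_quantile expression quantile defining top/bottom gene classes.
#' @param min_gene_length minimum gene length (bp) for gene-body profiles.
#' @param extension_ip,extension_marks read extensions (bp) for the
#'   membrane-protein/control/input libraries and for active-mark libraries.
#' @param viz_bin non-overlapping visualization bin (bp).
#' @param max_missing maximum fraction of missing values tolerated in a
#'   calling window before it is flagged and excluded.
#'
#' @return an object of class `analysis_params`.
#' @export
analysis_params <- function(array_window = 200,
                            array_offset = 1,
                            seq_window = 10e3,
                            seq_offset = 50,
                            array_threshold = 0.8,
                            seq_threshold = 0.4,
                            fdr_ceiling_array = 0.025,
                            fdr_ceiling_seq = 0.024,
                            min_overlap = 1,
                            gap_cutoffs = c(10e3, 100e3, 1e6),
                            small_gap_flank = 5e3,
                            boundary_flank = 10e3,
                            count_window = 1000,
                            count_offset = 500,
                            signal_window = 100,
                            signal_offset = 50,
                            expr_quantile = 0.2,
                            min_gene_length = 2000,
                            extension_ip = 300,
                            extension_marks = 200,
                            viz_bin = 5000,
                            max_missing = 0.5) {
  p <- as.list(environment())
  if (p$array_threshold <= -1 || p$array_threshold >= 1 ||
      p$seq_threshold <= -1 || p$seq_threshold >= 1)
    stop("thresholds must be in (-1, 1)")
  if (is.unsorted(p$gap_cutoffs, strictly = TRUE))
    stop("gap_cutoffs must be strictly increasing")
  if (p$array_offset > p$array_window || p$seq_offset > p$seq_window)
    stop("window offsets must not exceed window sizes")
  class(p) <- "analysis_params"
  p
}
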