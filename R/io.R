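# ---- interval / annotation IO -------------------------------------------

#' Read intervals or annotations from BED or GFF3
#'
#' BED is parsed as 0-based half-open; GFF3 as 1-based closed and converted
#' to the package's 0-based half-open convention. Strand and attribute
#' columns are preserved.
#'
#' @param path input file.
#' @param format `"BED"` or `"GFF3"`.
#' @param genome optional [build_genome()] result; when given, coordinates
#'   outside the declared chromosomes are an error.
#' @return a data frame with `chrom`, `start`, `end` plus `name`/`score`/
#'   `strand` (BED) or `strand`/`type`/attribute columns (GFF3).
#' @export
read_intervals <- function(path, format = c("BED", "GFF3"), genome = NULL) {
  format <- match.arg(format)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "BED") "BED" else "GFF3"),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e)))
  df <- from_granges0(gr)
  md <- as.data.frame(S4Vectors::mcols(gr))
  df$strand <- as.character(GenomicRanges::strand(gr))
  if (ncol(md)) df <- cbind(df, md)
  if (!is.null(genome)) {
    L <- genome_length(genome, df$chrom)
    bad <- which(df$start < 0 | df$end > L)
    if (length(bad))
      stop("coordinate outside declared chromosome at record ", bad[1])
  }
  df
}

#' Write an interval set as BED
#'
#' Labels and gap size classes go in the name field; the terminal flag in
#' the score field (1 = terminal).
#'
#' @param x an [interval_set()] (or any `chrom`/`start`/`end` frame).
#' @param path output file.
#' @export
write_intervals <- function(x, path) {
  df <- as.data.frame(x)
  name <- if (!is.null(df$label)) {
    ifelse(is.na(df$size_class), df$label,
           paste(df$label, df$size_class, sep = "_"))
  } else "."
  score <- if (!is.null(df$terminal)) as.integer(df$terminal) else 0L
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE,
                                     trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    name, score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' Grid points become `[pos, pos + step)` intervals; adjacent equal-value
#' runs are merged and missing positions are omitted.
#'
#' @param track a [signal_track()] with a grid step.
#' @param path output file.
#' @export
write_track <- function(track, path) {
  step <- track_step(track)
  if (is.null(step)) stop("track must carry a grid step to be exported")
  for (cc in split(track$pos, track$chrom))
    if (is.unsorted(cc, strictly = TRUE)) stop("unsorted track rejected")
  ok <- !is.na(track$score)
  df <- track[ok, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos + 1, df$pos + step),
                               score = df$score)
  gr <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(gr, paste0(GenomicRanges::seqnames(gr), "\r",
                                    df$score))))
  # restore scores after the per-value reduce, then sort
  sc <- as.numeric(sub(".*\r", "", names(gr)))
  names(gr) <- NULL
  gr$score <- sc
  gr <- GenomicRanges::sort(gr)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track back as intervals
#'
#' @param path bedGraph file.
#' @return data frame with `chrom`, `start`, `end`, `score` (0-based
#'   half-open).
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- from_granges0(gr)
  df$score <- gr$score
  df
}

#' Write chromosome sizes as a two-column TSV
#' @param genome a [build_genome()] result.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  utils::write.table(data.frame(genome$chrom,
                                format(genome$length, scientific = FALSE,
                                       trim = TRUE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write genes as GFF3 (plus a TSV with expression columns)
#'
#' @param genes a `gene_table`.
#' @param path output GFF3 file; a sibling `.tsv` carries the full table.
#' @export
write_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end),
                               strand = genes$strand)
  gr$ID <- genes$gene_id
  gr$type <- "gene"
  gr$translation_start <- genes$tstart
  rtracklayer::export(gr, path, format = "GFF3")
  utils::write.table(as.data.frame(genes), sub("\\.gff3?$", ".tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write repeats (family in the name field) or fragments as BED6
#'
#' @param x a `repeat_table` or `fragment_set`.
#' @param path output file.
#' @param extension_bp fragment extension used to give fragments an
#'   interval extent (fragments only).
#' @export
write_features <- function(x, path, extension_bp = 1) {
  if (inherits(x, "repeat_table")) {
    out <- data.frame(x$chrom, x$start, x$end, x$family, 0L, ".")
  } else {
    s <- ifelse(x$strand == "+", x$pos, x$pos - extension_bp + 1)
    out <- data.frame(x$chrom, pmax(0, s), pmax(0, s) + extension_bp,
                      "fragment", 0L, x$strand)
  }
  out[[2]] <- format(out[[2]], scientific = FALSE, trim = TRUE)
  out[[3]] <- format(out[[3]], scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- pipeline driver -----------------------------------------------------

write_provenance <- function(outdir, stage, seed, params, counts) {
  jsonlite::write_json(
    list(tool = "nmadomains",
         version = as.character(utils::packageVersion("nmadomains")),
         stage = stage, seed = seed,
         params = params[!vapply(params, is.function, logical(1))],
         counts = counts),
    file.path(outdir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run the analysis stages end to end, writing artifacts
#'
#' Executes the requested stages in dependency order against one synthetic
#' dataset: `simulate` (genome, truth, annotations, signal), `normalize`
#' (combined array track and sequencing z track), `call` (subdomains and
#' gaps on both platforms with empirical FDR), `boundaries` (boundary set
#' and metaprofiles), `stats` (coverage/expression contrasts and the
#' occupancy fit). Every stage writes a provenance JSON (tool version,
#' seed, parameters, stage counts). Requesting a stage whose inputs were
#' not produced raises an error naming the stage to run first.
#'
#' @param config a [sim_config()].
#' @param params an [analysis_params()].
#' @param seed integer seed controlling all randomness.
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @param quiet suppress progress messages.
#' @return invisibly, the in-memory state list of all stage results.
#' @export
run_pipeline <- function(config = sim_config(), params = analysis_params(),
                         seed = 1L, outdir = "nmadomains_out",
                         stages = "all", quiet = FALSE) {
  all_stages <- c("simulate", "normalize", "call", "boundaries", "stats")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  st <- list()
  need <- function(what, producer) {
    if (is.null(st[[what]]))
      stop("missing upstream result '", what, "': run stage '", producer,
           "' first")
  }
  for (stage in all_stages[all_stages %in% stages]) {
    if (stage == "simulate") {
      st$data <- simulate_dataset(config, seed, include_marks = FALSE,
                                  include_stages = TRUE)
      write_genome(st$data$genome, file.path(outdir, "genome.tsv"))
      write_intervals(interval_set(st$data$truth$chrom, st$data$truth$start,
                                   st$data$truth$end),
                      file.path(outdir, "truth_subdomains.bed"))
      write_genes(st$data$genes, file.path(outdir, "genes.gff3"))
      write_features(st$data$repeats, file.path(outdir, "repeats.bed"))
      write_provenance(outdir, stage, seed, unclass(config),
                       list(chromosomes = nrow(st$data$genome),
                            truth_intervals = nrow(st$data$truth),
                            genes = nrow(st$data$genes),
                            repeats = nrow(st$data$repeats)))
      say("simulate: ", nrow(st$data$truth), " planted subdomains, ",
          nrow(st$data$genes), " genes, ", nrow(st$data$repeats), " repeats")
    } else if (stage == "normalize") {
      need("data", "simulate")
      st$array <- array_pipeline(st$data$array, params)
      st$seq <- seq_pipeline(st$data$seq, st$data$genome, params,
                             seed = seed + 10L)
      write_track(bin_mean(st$array$ip_track, params$viz_bin),
                  file.path(outdir, "array_score_5kb.bedgraph"))
      write_track(bin_mean(st$seq$ip_track, params$viz_bin),
                  file.path(outdir, "seq_zscore_5kb.bedgraph"))
      write_provenance(outdir, stage, seed, unclass(params),
                       list(array_windows = nrow(st$array$windows_ip),
                            seq_windows = nrow(st$seq$windows_ip)))
      say("normalize: ", nrow(st$array$windows_ip), " array windows, ",
          nrow(st$seq$windows_ip), " seq windows")
    } else if (stage == "call") {
      need("array", "normalize")
      st$calls <- call_subdomains(st$array$regions, st$seq$regions,
                                  st$data$genome, params)
      write_intervals(st$calls$subdomains,
                      file.path(outdir, "subdomains.bed"))
      write_intervals(st$calls$gaps, file.path(outdir, "gaps.bed"))
      fdr <- data.frame(platform = c("array", "seq"),
                        fdr = c(st$array$fdr, st$seq$fdr))
      utils::write.table(fdr, file.path(outdir, "fdr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_provenance(outdir, stage, seed, unclass(params),
                       list(array_regions = nrow(st$array$regions),
                            seq_regions = nrow(st$seq$regions),
                            subdomains = nrow(st$calls$subdomains),
                            gaps = nrow(st$calls$gaps)))
      say("call: ", nrow(st$calls$subdomains), " subdomains, ",
          nrow(st$calls$gaps), " gaps; FDR array ",
          signif(st$array$fdr, 3), ", seq ", signif(st$seq$fdr, 3))
    } else if (stage == "boundaries") {
      need("calls", "call")
      st$boundaries <- select_boundaries(st$calls$subdomains,
                                         st$calls$gaps, params)
      st$profiles <- list(
        repeats = count_metaplot(
          data.frame(chrom = st$data$repeats$chrom,
                     pos = st$data$repeats$center),
          st$boundaries, params$count_window, params$count_offset,
          params$boundary_flank),
        gene_starts = count_metaplot(
          data.frame(chrom = st$data$genes$chrom,
                     pos = st$data$genes$tstart),
          st$boundaries, params$count_window, params$count_offset,
          params$boundary_flank),
        signal = signal_metaplot(
          mask_nonunique(st$array$ip_track, st$data$array$probes),
          st$boundaries, params$signal_window, params$signal_offset,
          params$boundary_flank))
      bt <- as.data.frame(st$boundaries)
      utils::write.table(bt, file.path(outdir, "boundaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in names(st$profiles))
        utils::write.table(as.data.frame(st$profiles[[nm]]),
                           file.path(outdir, paste0("profile_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      write_provenance(outdir, stage, seed, unclass(params),
                       list(boundaries = nrow(st$boundaries)))
      say("boundaries: ", nrow(st$boundaries), " boundaries profiled")
    } else if (stage == "stats") {
      need("calls", "call")
      genes <- st$data$genes
      st$stats <- list(
        gene_coverage = coverage_contrast(genes, st$calls$subdomains,
                                          st$calls$gaps),
        repeat_families = family_enrichment(st$data$repeats,
                                            st$calls$subdomains,
                                            st$calls$gaps),
        expression = expression_by_gap_class(genes, st$calls$subdomains,
                                             st$calls$gaps),
        occupancy_fit = tryCatch(
          size_occupancy_fit(st$calls$occupancy),
          error = function(e) NULL))
      utils::write.table(st$stats$gene_coverage$tests,
                         file.path(outdir, "gene_coverage_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(st$stats$repeat_families,
                         file.path(outdir, "repeat_family_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(st$stats$expression$summary,
                         file.path(outdir, "expression_by_class.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_provenance(outdir, stage, seed, unclass(params),
                       list(tests = nrow(st$stats$gene_coverage$tests)))
      say("stats: contrasts written")
    }
  }
  invisible(st)
}
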