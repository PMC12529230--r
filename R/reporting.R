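#' Characterize genome-wide binding from a peak table
#'
#' Runs the full occupancy characterization: summit windows, genic
#' context classification, fold-enrichment category report, AT
#' enrichment versus genomic backgrounds, width/enrichment correlation,
#' subpeak merging and gene annotation.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param genes Gene `GRanges` (see [read_annotation()]).
#' @param peaks Peak `GRanges` (see [read_peaks()] / [peak_table()]).
#' @param flank Summit-window flank, bp (default 30).
#' @param fe_threshold Fold-enrichment category cutoff (default 2).
#' @param k Top/bottom category size (default 20).
#' @param t_variant t-test variant (default `"welch"`).
#' @param background Background construction for [at_report()].
#' @param merge_gap_bp Subpeak merge gap (default 200).
#' @param alpha Significance threshold (default 0.001).
#' @param seed Seed for background window sampling.
#' @return List with `contexts`, `window_at`, `categories`,
#'   `at_comparisons`, `correlation` (`NULL` when undefined, with
#'   `correlation_note`), `parent_regions`, `region_members`,
#'   `peak_genes`, `backgrounds` (pooled AT of each background), and the
#'   parameter set used.
#' @export
characterize_peaks <- function(genome, genes, peaks, flank = 30L,
                               fe_threshold = 2.0, k = 20L,
                               t_variant = "welch",
                               background = "per-region",
                               merge_gap_bp = 200L, alpha = 0.001, seed = 1L) {
  if (length(peaks) == 0L) stop("empty peak table")
  sets <- derive_intergenic(genes, genome)
  windows <- summit_window(peaks, flank = flank, genome = genome)
  contexts <- classify_context(windows, sets$intergenic)
  atv <- collect_at(windows, contexts, genome)
  categories <- category_report(peaks, contexts, k = k,
                                fe_threshold = fe_threshold,
                                window_at = atv$at)
  at_cmp <- at_report(categories, contexts, atv$at, genome,
                      sets$intergenic, sets$coding,
                      variant = t_variant, background = background,
                      alpha = alpha, seed = seed)
  correlation <- NULL
  correlation_note <- NA_character_
  corr_try <- tryCatch(width_fe_correlation(peaks), error = function(e) e)
  if (inherits(corr_try, "error")) {
    correlation_note <- conditionMessage(corr_try)
  } else {
    correlation <- corr_try
  }
  merged <- merge_subpeaks(peaks, max_gap_bp = merge_gap_bp)
  peak_genes <- annotate_genes(peaks, genes)
  backgrounds <- c(
    intergenic_at = if (length(sets$intergenic) > 0)
      pooled_at(genome, sets$intergenic) else NA_real_,
    coding_at = if (length(sets$coding) > 0)
      pooled_at(genome, sets$coding) else NA_real_)
  list(contexts = contexts, window_at = atv$at, categories = categories,
       at_comparisons = at_cmp, correlation = correlation,
       correlation_note = correlation_note,
       parent_regions = merged$regions, region_members = merged$members,
       peak_genes = peak_genes, backgrounds = backgrounds,
       params = list(flank = flank, fe_threshold = fe_threshold, k = k,
                     t_variant = t_variant, background = background,
                     merge_gap_bp = merge_gap_bp, alpha = alpha, seed = seed))
}

#' Run the characterization pipeline from input files
#'
#' File-based wrapper around [characterize_peaks()]: reads genome,
#' annotation and peak table, runs the analysis and (optionally) writes
#' every figure-equivalent table as TSV plus a JSON report.
#'
#' @param genome_path FASTA path.
#' @param annotation_path GFF3 path.
#' @param peaks_path Peak-table path.
#' @param dialect Peak dialect, see [read_peaks()].
#' @param out_dir Output directory (`NULL` = no files written).
#' @param ... Further parameters passed to [characterize_peaks()].
#' @return The [characterize_peaks()] result, invisibly when writing.
#' @export
run_characterize <- function(genome_path, annotation_path, peaks_path,
                             dialect = "summary-tsv", out_dir = NULL, ...) {
  genome <- read_genome(genome_path)
  genes <- read_annotation(annotation_path, genome)
  peaks <- read_peaks(peaks_path, dialect = dialect, genome = genome)
  res <- characterize_peaks(genome, genes, peaks, ...)
  if (!is.null(out_dir)) {
    write_characterization(res, out_dir)
    invisible(res)
  } else {
    res
  }
}

#' Write a characterization result to disk
#'
#' Writes `contexts.tsv`, `categories.tsv`, `at_comparisons.tsv`,
#' `parent_regions.tsv`, `region_members.tsv`, `peak_genes.tsv` and a
#' JSON `report.json` (schema-versioned) under `out_dir`.
#'
#' @param res Result of [characterize_peaks()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_characterization <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  cats <- res$categories
  cats$members <- vapply(cats$members, paste, character(1), collapse = ",")
  regions_df <- data.frame(
    region_id = res$parent_regions$region_id,
    contig = as.character(GenomeInfoDb::seqnames(res$parent_regions)),
    start = GenomicRanges::start(res$parent_regions),
    end = GenomicRanges::end(res$parent_regions),
    n_members = res$parent_regions$n_members,
    max_fold_enrichment = res$parent_regions$max_fold_enrichment)
  paths <- c(wt(res$contexts, "contexts.tsv"),
             wt(cats, "categories.tsv"),
             wt(res$at_comparisons, "at_comparisons.tsv"),
             wt(regions_df, "parent_regions.tsv"),
             wt(res$region_members, "region_members.tsv"),
             wt(res$peak_genes, "peak_genes.tsv"))
  report <- list(schema_version = "1.0",
                 params = res$params,
                 backgrounds = as.list(res$backgrounds),
                 correlation = res$correlation,
                 correlation_note = res$correlation_note,
                 n_peaks = nrow(res$contexts),
                 percent_intergenic_all =
                   res$categories$percent_intergenic[res$categories$category == "all"])
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}

#' Simulate a complete input bundle on disk
#'
#' Generates a genome, annotation, AT-biased occupancy, replicated
#' coverage, toy peak calls, an EMSA titration and an AFM topograph, and
#' writes them in standard formats (FASTA, GFF3, bedGraph, narrowPeak +
#' summary TSV, TSV, matrix text) together with a JSON ground-truth
#' sidecar and a checksum manifest.
#'
#' @param out_dir Output directory.
#' @param gspec A [genome_spec()].
#' @param ospec An [occupancy_spec()].
#' @param depth Coverage depth (default 30).
#' @param n_replicates Replicates (default 3).
#' @param emsa_kd_nM True KD of the simulated titration (default 300).
#' @param afm_n Complexes in the simulated topograph (default 8).
#' @param seed Master seed applied to every stream.
#' @return Invisibly, a manifest data frame (`file`, `md5`).
#' @export
run_simulate <- function(out_dir, gspec = genome_spec(), ospec = occupancy_spec(),
                         depth = 30, n_replicates = 3L, emsa_kd_nM = 300,
                         afm_n = 8L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gspec$seed <- as.integer(seed)
  ospec$seed <- as.integer(seed)
  sim <- simulate_genome(gspec)
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gff <- file.path(out_dir, "genes.gff3")
  if (length(sim$genes) > 0L) {
    genes_out <- sim$genes
    genes_out$type <- "gene"
    genes_out$ID <- genes_out$locus_tag
    rtracklayer::export(genes_out, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  expected <- occupancy_track(sim$genome, ospec)
  cov <- sample_coverage(expected, depth = depth, n_replicates = n_replicates,
                         seed = seed)
  bg_paths <- character(0)
  for (r in seq_len(n_replicates)) {
    for (kind in c("ip", "input")) {
      p <- file.path(out_dir, sprintf("coverage_%s_rep%d.bedGraph", kind, r))
      .write_bedgraph(cov[[kind]][[r]], names(sim$genome)[1], p)
      bg_paths <- c(bg_paths, p)
    }
  }
  peaks <- call_toy_peaks(cov, sim$genome)
  np <- file.path(out_dir, "peaks.narrowPeak")
  ts <- file.path(out_dir, "peaks.tsv")
  write_peaks(peaks, np, "narrowPeak")
  write_peaks(peaks, ts, "summary-tsv")
  emsa <- simulate_emsa(emsa_kd_nM, c(25, 50, 100, 200, 400, 800, 1600, 3200),
                        noise_sd = 0.03, seed = seed)
  ep <- file.path(out_dir, "emsa.tsv")
  utils::write.table(data.frame(probe_id = emsa$probe_id,
                                concentration_nM = emsa$concentration_nM,
                                free_signal = 1 - emsa$fraction_bound,
                                total_signal = 1),
                     ep, sep = "\t", quote = FALSE, row.names = FALSE)
  afm <- simulate_afm(afm_n, heights_nm = rep(c(1.5, 3, 5, 8), length.out = afm_n),
                      foci = rep(c(1L, 2L, 3L), length.out = afm_n), seed = seed)
  ap <- file.path(out_dir, "afm_map.txt")
  utils::write.table(afm$map$z, ap, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- list(seed = seed,
                genome = list(contig_length_bp = gspec$contig_length_bp,
                              n_genes = gspec$n_genes,
                              coding_at_target = gspec$coding_at,
                              intergenic_at_target = gspec$intergenic_at),
                occupancy = ospec[c("window_w", "bias_alpha", "baseline",
                                    "at_midpoint", "at_scale")],
                emsa_kd_nM = emsa_kd_nM,
                afm_truth = afm$truth,
                n_peaks_called = length(peaks))
  tp <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(fa, gff, bg_paths, np, ts, ep, ap, tp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# run-length-encoded bedGraph of a per-bp integer vector
.write_bedgraph <- function(x, contig, path) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  start0 <- end - r$lengths
  utils::write.table(data.frame(contig, start0, end, r$values),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
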