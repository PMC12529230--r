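#' Construct a peak table
#'
#' Validates a data frame of enrichment peaks and returns the internal
#' `GRanges` representation used by all downstream analyses. Coordinates
#' are 1-based closed; `summit` must satisfy `start <= summit <= end`.
#'
#' @param df Data frame with columns `peak_id`, `contig`, `start`, `end`,
#'   `fold_enrichment` and optionally `summit` (defaults to the span
#'   midpoint), `q_value`, `replicate_support`.
#' @param genome Optional `DNAStringSet`; when given, peaks are
#'   bounds-checked against it and the seqinfo is attached.
#' @return A `GRanges` with metadata columns `peak_id`, `summit`,
#'   `fold_enrichment`, `q_value`, `replicate_support`.
#' @export
peak_table <- function(df, genome = NULL) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges(peak_id = character(), summit = integer(),
                                  fold_enrichment = numeric(),
                                  q_value = numeric(), replicate_support = integer()))
  }
  req <- c("peak_id", "contig", "start", "end", "fold_enrichment")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"summit" %in% names(df) || all(is.na(df$summit))) {
    df$summit <- floor((df$start + df$end) / 2)
  }
  if (any(!is.finite(df$fold_enrichment)) || any(df$fold_enrichment < 0)) {
    stop("fold_enrichment must be finite and >= 0 for every peak")
  }
  if (any(df$start > df$summit | df$summit > df$end)) {
    bad <- df$peak_id[df$start > df$summit | df$summit > df$end]
    stop("summit outside peak span for: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(df$start < 1L | df$start > df$end)) stop("invalid peak span (need 1 <= start <= end)")
  if (anyDuplicated(df$peak_id)) {
    stop("duplicate peak_id(s): ",
         paste(unique(df$peak_id[duplicated(df$peak_id)]), collapse = ", "))
  }
  si <- NULL
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$contig), names(genome))
    if (length(unknown) > 0L) stop("peak on unknown contig: ", paste(unknown, collapse = ", "))
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    if (any(df$end > lens[df$contig])) {
      stop("peak(s) beyond contig end: ",
           paste(utils::head(df$peak_id[df$end > lens[df$contig]], 5), collapse = ", "))
    }
    si <- genome_seqinfo(genome)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(as.integer(df$start), as.integer(df$end)),
    peak_id = as.character(df$peak_id),
    summit = as.integer(df$summit),
    fold_enrichment = as.numeric(df$fold_enrichment),
    q_value = if ("q_value" %in% names(df)) as.numeric(df$q_value) else NA_real_,
    replicate_support = if ("replicate_support" %in% names(df))
      as.integer(df$replicate_support) else 1L)
  if (!is.null(si)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}

#' Read a peak table from disk
#'
#' Two dialects are supported. `"narrowPeak"` is MACS-style BED6+4
#' (0-based half-open on disk; column 10 is the summit offset from the
#' peak start, with -1 meaning no summit, replaced by the midpoint).
#' `"summary-tsv"` is a headered TSV with 1-based columns `peak_id`,
#' `contig`, `start`, `end`, `summit`, `width`, `fold_enrichment`,
#' `q_value`.
#'
#' @param path Input file.
#' @param dialect `"narrowPeak"` or `"summary-tsv"`.
#' @param genome Optional `DNAStringSet` for bounds checking.
#' @return A peak `GRanges` as from [peak_table()]. An empty file (or
#'   header-only TSV) yields an empty table.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "summary-tsv"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (dialect == "narrowPeak") {
    if (file.size(path) == 0L) return(peak_table(data.frame()))
    np <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("contig", "start0", "end", "name", "score",
                                          "strand", "signalValue", "pValue", "qValue",
                                          "peak"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "numeric", "character",
                                           "numeric", "numeric", "numeric", "integer"))
    df <- data.frame(peak_id = np$name, contig = np$contig,
                     start = np$start0 + 1L, end = np$end,
                     summit = ifelse(np$peak >= 0L, np$start0 + np$peak + 1L,
                                     floor((np$start0 + 1L + np$end) / 2)),
                     fold_enrichment = np$signalValue,
                     q_value = ifelse(np$qValue >= 0, 10^(-np$qValue), NA_real_),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    req <- c("peak_id", "contig", "start", "end", "summit", "fold_enrichment")
    miss <- setdiff(req, names(df))
    if (length(miss) > 0L) stop("summary TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  peak_table(df, genome = genome)
}

#' Write a peak table to disk
#'
#' Inverse of [read_peaks()]: `"summary-tsv"` round-trips all fields
#' bit-exactly; `"narrowPeak"` writes BED6+4 with the summit as a 0-based
#' offset in column 10.
#'
#' @param peaks Peak `GRanges`.
#' @param path Output file.
#' @param dialect `"narrowPeak"` or `"summary-tsv"`.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "summary-tsv")) {
  dialect <- match.arg(dialect)
  start <- GenomicRanges::start(peaks)
  end <- GenomicRanges::end(peaks)
  if (dialect == "narrowPeak") {
    n <- length(peaks)
    df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(peaks)),
                     start0 = start - 1L, end = end,
                     name = peaks$peak_id, score = rep(0L, n),
                     strand = rep(".", n),
                     signalValue = peaks$fold_enrichment,
                     pValue = rep(-1, n),
                     qValue = ifelse(is.na(peaks$q_value), -1,
                                     -log10(peaks$q_value)),
                     peak = peaks$summit - start)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(peak_id = peaks$peak_id,
                     contig = as.character(GenomeInfoDb::seqnames(peaks)),
                     start = start, end = end, summit = peaks$summit,
                     width = end - start + 1L,
                     fold_enrichment = peaks$fold_enrichment,
                     q_value = peaks$q_value)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Summit windows of peaks
#'
#' Extracts the region from `flank` bp upstream through `flank` bp
#' downstream of each peak summit (60 bp total at the default
#' `flank = 30`, the summit base counted as the first downstream base),
#' truncated at contig edges.
#'
#' @param peaks Peak `GRanges` with a `summit` column.
#' @param flank Flank size in bp on each side (default 30).
#' @param genome Optional `DNAStringSet` supplying contig ends for
#'   clipping (otherwise seqinfo on `peaks` is used; if neither carries
#'   lengths only the left edge is clipped).
#' @return A `GRanges` of windows with `peak_id`, same order as `peaks`.
#' @export
summit_window <- function(peaks, flank = 30L, genome = NULL) {
  if (length(peaks) == 0L) {
    return(GenomicRanges::GRanges(peak_id = character()))
  }
  s <- peaks$summit
  start <- pmax(1L, s - as.integer(flank))
  end <- s + as.integer(flank) - 1L
  lens <- NULL
  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
  } else if (!all(is.na(GenomeInfoDb::seqlengths(peaks)))) {
    lens <- GenomeInfoDb::seqlengths(peaks)
  }
  contig <- as.character(GenomeInfoDb::seqnames(peaks))
  if (!is.null(lens)) end <- pmin(end, lens[contig])
  gr <- GenomicRanges::GRanges(seqnames = contig,
                               ranges = IRanges::IRanges(start, end),
                               peak_id = peaks$peak_id)
  if (!is.null(lens)) {
    GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Classify summit windows as intergenic or coding
#'
#' A window is called intergenic when strictly more than `min_overlap_bp`
#' of it lies inside the intergenic interval set, otherwise coding. A
#' window is "fully in context" when it lies entirely in intergenic
#' sequence (intergenic call) or contains no intergenic base (coding
#' call).
#'
#' @param windows Summit-window `GRanges` from [summit_window()].
#' @param intergenic Normalized intergenic `GRanges` (see
#'   [derive_intergenic()]).
#' @param min_overlap_bp Overlap threshold in bp; the rule is strict
#'   (`> min_overlap_bp`), default 30.
#' @return Data frame with `peak_id`, `context` (`"intergenic"` /
#'   `"coding"`), `intergenic_overlap_bp`, `window_fully_in_context`.
#' @export
classify_context <- function(windows, intergenic, min_overlap_bp = 30L) {
  n <- length(windows)
  if (n == 0L) {
    return(data.frame(peak_id = character(), context = character(),
                      intergenic_overlap_bp = integer(),
                      window_fully_in_context = logical()))
  }
  ov <- rep(0L, n)
  hits <- GenomicRanges::findOverlaps(windows, intergenic, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    inter <- IRanges::pintersect(
      IRanges::ranges(windows)[S4Vectors::queryHits(hits)],
      IRanges::ranges(intergenic)[S4Vectors::subjectHits(hits)])
    bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(hits), sum)
    ov[as.integer(names(bp))] <- as.integer(bp)
  }
  w <- GenomicRanges::width(windows)
  ctx <- ifelse(ov > min_overlap_bp, "intergenic", "coding")
  fully <- ifelse(ctx == "intergenic", ov == w, ov == 0L)
  data.frame(peak_id = windows$peak_id, context = ctx,
             intergenic_overlap_bp = ov,
             window_fully_in_context = fully,
             stringsAsFactors = FALSE)
}

#' Filter peaks by fold enrichment
#'
#' Keeps peaks with `fold_enrichment >= threshold` (the boundary value is
#' included), preserving input order.
#'
#' @param peaks Peak `GRanges`.
#' @param threshold Fold-enrichment cutoff, default 2.
#' @return Filtered peak `GRanges`.
#' @export
filter_fe <- function(peaks, threshold = 2.0) {
  peaks[peaks$fold_enrichment >= threshold]
}

#' Top- and bottom-k peaks by fold enrichment
#'
#' Sorts by fold enrichment (descending), breaking ties by contig then
#' start for determinism, and returns the first and last `k` peaks. When
#' `k >= n` both equal the whole (sorted) table.
#'
#' @param peaks Peak `GRanges`.
#' @param k Category size, default 20.
#' @return List with elements `top` and `bottom`.
#' @export
top_bottom <- function(peaks, k = 20L) {
  o <- order(-peaks$fold_enrichment,
             as.character(GenomeInfoDb::seqnames(peaks)),
             GenomicRanges::start(peaks))
  sorted <- peaks[o]
  n <- length(sorted)
  k <- min(as.integer(k), n)
  list(top = sorted[seq_len(k)],
       bottom = if (n == 0L) sorted else sorted[seq(n - k + 1L, n)])
}

#' Category report: context proportions per fold-enrichment category
#'
#' Builds the four standard categories -- all peaks, peaks with
#' `fold_enrichment >= fe_threshold`, the top-k and the bottom-k by fold
#' enrichment -- and reports for each the members, the percentage of
#' intergenic context calls, the mean peak width, and (when per-peak AT
#' fractions are supplied) the mean summit-window AT.
#'
#' @param peaks Peak `GRanges`.
#' @param contexts Context calls from [classify_context()] (matched by
#'   `peak_id`; every peak must have one).
#' @param k Size of the top/bottom categories (default 20).
#' @param fe_threshold Fold-enrichment cutoff (default 2).
#' @param window_at Optional named numeric vector of per-peak summit
#'   window AT fractions (names = `peak_id`).
#' @return Data frame with one row per category: `category`, `n`,
#'   `percent_intergenic`, `mean_width_bp`, `mean_at`, and a list column
#'   `members` of peak IDs.
#' @export
category_report <- function(peaks, contexts, k = 20L, fe_threshold = 2.0,
                            window_at = NULL) {
  if (length(peaks) == 0L) stop("empty peak table")
  ctx <- stats::setNames(contexts$context, contexts$peak_id)
  if (any(!peaks$peak_id %in% names(ctx))) {
    stop("missing context call for peak(s): ",
         paste(utils::head(setdiff(peaks$peak_id, names(ctx)), 5), collapse = ", "))
  }
  tb <- top_bottom(peaks, k)
  cats <- list(all = peaks,
               "FE>=2" = filter_fe(peaks, fe_threshold),
               "top-k" = tb$top, "bottom-k" = tb$bottom)
  names(cats)[2] <- sprintf("FE>=%g", fe_threshold)
  names(cats)[3] <- sprintf("top-%d", as.integer(k))
  names(cats)[4] <- sprintf("bottom-%d", as.integer(k))
  rows <- lapply(names(cats), function(nm) {
    p <- cats[[nm]]
    ids <- p$peak_id
    n <- length(ids)
    pct <- if (n > 0) 100 * mean(ctx[ids] == "intergenic") else NA_real_
    mw <- if (n > 0) mean(GenomicRanges::width(p)) else NA_real_
    mat <- if (!is.null(window_at) && n > 0) mean(window_at[ids], na.rm = TRUE) else NA_real_
    data.frame(category = nm, n = n, percent_intergenic = pct,
               mean_width_bp = mw, mean_at = mat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- I(lapply(cats, function(p) p$peak_id))
  out
}

# letters a..z, then aa, ab, ... for >26 members
.subpeak_letters <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  two <- as.vector(t(outer(letters, letters, paste0)))
  c(letters, two)[seq_len(n)]
}

#' Merge subpeaks into parent regions
#'
#' Peaks on the same contig whose spans are separated by at most
#' `max_gap_bp` are merged into one parent region. Members are lettered
#' a, b, c, ... in start order; a single-member region keeps its peak
#' un-suffixed. The parent fold enrichment is the maximum over members.
#'
#' @param peaks Peak `GRanges`.
#' @param max_gap_bp Maximum allowed gap between member spans (default
#'   200).
#' @return List with `regions` (a `GRanges` with `region_id`,
#'   `n_members`, `max_fold_enrichment`) and `members` (data frame
#'   `peak_id`, `region_id`, `subpeak_id`).
#' @export
merge_subpeaks <- function(peaks, max_gap_bp = 200L) {
  if (length(peaks) == 0L) {
    return(list(regions = GenomicRanges::GRanges(region_id = character(),
                                                 n_members = integer(),
                                                 max_fold_enrichment = numeric()),
                members = data.frame(peak_id = character(), region_id = character(),
                                     subpeak_id = character())))
  }
  regions <- GenomicRanges::reduce(sort(GenomicRanges::granges(peaks)),
                                   min.gapwidth = as.integer(max_gap_bp) + 1L,
                                   ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(peaks, regions, ignore.strand = TRUE)
  stopifnot(length(hits) == length(peaks))  # every peak in exactly one region
  region_of <- S4Vectors::subjectHits(hits)
  regions$region_id <- sprintf("R%03d", seq_along(regions))
  counts <- tabulate(region_of, nbins = length(regions))
  regions$n_members <- counts
  fe_max <- tapply(peaks$fold_enrichment, region_of, max)
  regions$max_fold_enrichment <- as.numeric(fe_max[as.character(seq_along(regions))])
  o <- order(region_of, GenomicRanges::start(peaks))
  m_region <- region_of[o]
  pos_in_region <- sequence(counts)  # 1..c1, 1..c2, ... matches the (region, start) order
  letters_pool <- .subpeak_letters(max(counts))
  members <- data.frame(peak_id = peaks$peak_id[o],
                        region_id = regions$region_id[m_region],
                        subpeak_id = ifelse(counts[m_region] == 1L,
                                            regions$region_id[m_region],
                                            paste0(regions$region_id[m_region],
                                                   letters_pool[pos_in_region])),
                        stringsAsFactors = FALSE)
  list(regions = regions, members = members)
}

#' Annotate peaks or regions with covered genes
#'
#' Lists every gene overlapping each query span by at least one bp, in
#' genomic order.
#'
#' @param query Peak or region `GRanges`; its `peak_id` (or `region_id`)
#'   column labels the output.
#' @param genes Gene `GRanges` with `locus_tag` and `product`.
#' @return Data frame `query_id`, `locus_tag`, `product`; queries
#'   covering no gene are absent.
#' @export
annotate_genes <- function(query, genes) {
  id_col <- if (!is.null(query$peak_id)) query$peak_id else query$region_id
  if (is.null(id_col)) id_col <- as.character(seq_along(query))
  genes <- sort(genes, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, genes, ignore.strand = TRUE)
  data.frame(query_id = id_col[S4Vectors::queryHits(hits)],
             locus_tag = genes$locus_tag[S4Vectors::subjectHits(hits)],
             product = genes$product[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Correlation of fold enrichment with peak width
#'
#' Pearson correlation of (width, fold enrichment) with the least-squares
#' regression line of fold enrichment on width.
#'
#' @param peaks Peak `GRanges`, at least 3 rows with non-constant widths
#'   and fold enrichments.
#' @return List with `r`, `slope`, `intercept`, `n`, `p_value`.
#' @export
width_fe_correlation <- function(peaks) {
  w <- GenomicRanges::width(peaks)
  fe <- peaks$fold_enrichment
  if (length(w) < 3L) stop("need at least 3 peaks for a correlation")
  if (stats::var(w) == 0 || stats::var(fe) == 0) {
    stop("undefined correlation: constant widths or fold enrichments")
  }
  ct <- stats::cor.test(w, fe, method = "pearson")
  fit <- stats::lm(fe ~ w)
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(w),
       p_value = ct$p.value)
}

#' Reproducible peaks across replicate peak tables
#'
#' A peak from the first replicate is kept when it overlaps at least one
#' called peak in every other replicate; its fold enrichment is averaged
#' over the overlapping peaks of all replicates and `replicate_support`
#' records the replicate count.
#'
#' @param tables List of peak `GRanges`, one per replicate.
#' @return Peak `GRanges` of reproducible peaks.
#' @export
reproducible_peaks <- function(tables) {
  if (length(tables) == 0L) stop("no replicate tables given")
  base <- tables[[1]]
  if (length(tables) == 1L) return(base)
  keep <- rep(TRUE, length(base))
  fe_sum <- base$fold_enrichment
  fe_n <- rep(1L, length(base))
  for (i in seq_along(tables)[-1]) {
    hits <- GenomicRanges::findOverlaps(base, tables[[i]], ignore.strand = TRUE)
    keep <- keep & seq_along(base) %in% S4Vectors::queryHits(hits)
    fe_i <- tapply(tables[[i]]$fold_enrichment[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), mean)
    ix <- as.integer(names(fe_i))
    fe_sum[ix] <- fe_sum[ix] + as.numeric(fe_i)
    fe_n[ix] <- fe_n[ix] + 1L
  }
  out <- base[keep]
  out$fold_enrichment <- (fe_sum / fe_n)[keep]
  out$replicate_support <- length(tables)
  out
}
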