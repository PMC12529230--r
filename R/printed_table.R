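#' Read a printed peak-summary table
#'
#' Reads the compact summary dialect used for published per-peak tables:
#' TSV columns `peak_id`, `length_bp`, `summit_region` (`"Intergenic"` /
#' `"ORF"`, a trailing `*` marking a summit window entirely inside its
#' region), `fold_enrichment` and `covered_genes`
#' (`tag:product` pairs joined by `|`). Since such tables print widths
#' rather than coordinates, peaks are laid head-to-tail with 1-kb
#' spacers on a placeholder contig, preserving widths.
#'
#' @param path Input TSV.
#' @return List with `peaks` (peak `GRanges`), `contexts` (a context
#'   data frame as from [classify_context()], built from the printed
#'   labels) and `genes` (data frame `query_id`, `locus_tag`,
#'   `product`).
#' @export
read_printed_peak_summary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          quote = "", stringsAsFactors = FALSE)
  req <- c("peak_id", "length_bp", "summit_region", "fold_enrichment")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("printed table lacks column(s): ",
                              paste(miss, collapse = ", "))
  spacer <- 1000L
  start <- cumsum(c(1L, utils::head(df$length_bp + spacer, -1)))
  peaks <- peak_table(data.frame(peak_id = df$peak_id, contig = "tbl",
                                 start = start, end = start + df$length_bp - 1L,
                                 fold_enrichment = df$fold_enrichment))
  fully <- grepl("\\*$", df$summit_region)
  ctx <- ifelse(grepl("^Intergenic", df$summit_region), "intergenic", "coding")
  contexts <- data.frame(peak_id = df$peak_id, context = ctx,
                         intergenic_overlap_bp = NA_integer_,
                         window_fully_in_context = fully,
                         stringsAsFactors = FALSE)
  genes <- NULL
  if ("covered_genes" %in% names(df)) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      entries <- strsplit(df$covered_genes[i], "|", fixed = TRUE)[[1]]
      tag <- sub(":.*$", "", entries)
      prod <- sub("^[^:]*:", "", entries)
      data.frame(query_id = df$peak_id[i], locus_tag = tag, product = prod,
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, rows)
  }
  list(peaks = peaks, contexts = contexts, genes = genes)
}
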