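# in-memory fixtures and brute-force oracles shared across test files

make_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

make_genes <- function(contig, starts, ends, tags = NULL, genome = NULL) {
  if (is.null(tags)) tags <- sprintf("g%03d", seq_along(starts))
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends),
                               locus_tag = tags, product = "protein")
  if (!is.null(genome)) {
    si <- GenomeInfoDb::Seqinfo(names(genome), Biostrings::width(genome))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}

random_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# per-bp boolean membership oracle: TRUE where any interval covers the base
bp_mask <- function(starts, ends, L) {
  m <- rep(FALSE, L)
  for (i in seq_along(starts)) {
    m[max(1L, starts[i]):min(L, ends[i])] <- TRUE
  }
  m
}

# mask -> intervals (runs of TRUE), as a two-column matrix
mask_to_intervals <- function(m) {
  r <- rle(m)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  cbind(start = start[r$values], end = end[r$values])
}

# closed-form two-sample t statistics (textbook formulas, independent of stats::t.test)
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# AT fraction by direct character counting
at_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n_at <- sum(ch %in% c("A", "T"))
  n_ok <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_ok == 0) NA_real_ else n_at / n_ok
}

top20_fixture_path <- function() {
  system.file("extdata", "top20_peaks_table.tsv", package = "napbind",
              mustWork = TRUE)
}
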