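#' Read a genome assembly from FASTA
#'
#' Reads a multi-record (possibly line-wrapped) FASTA file into a
#' [Biostrings::DNAStringSet]. Sequences are uppercased and any IUPAC
#' ambiguity code other than A/C/G/T is mapped to N, so downstream
#' composition statistics operate on a clean \{A,C,G,T,N\} alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per record, named by the first
#'   whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtn"), fa)
#' g <- read_genome(fa)
#' as.character(g$c1)  # "ACGTN"
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set))) {
    dup <- unique(names(set)[duplicated(names(set))])
    stop("duplicate contig ID(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(names(set)[Biostrings::width(set) == 0L], collapse = ", "))
  }
  # uppercase, then collapse every non-ACGT code to N
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(set)
  out
}

#' Read gene annotations from GFF3
#'
#' Imports features of the requested types into a `GRanges` carrying
#' `locus_tag` and `product` metadata columns. Features on contigs absent
#' from `genome` or extending beyond contig bounds are rejected; features
#' without a locus tag receive a synthetic one with a warning.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param feature_types Character vector of GFF3 `type` values to keep
#'   (default `"gene"`).
#' @return A `GRanges` of genes with unique `locus_tag` values; seqinfo
#'   carries the contig lengths of `genome`.
#' @export
read_annotation <- function(path, genome, feature_types = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[as.character(gr$type) %in% feature_types]
  unknown <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(genome))
  if (length(unknown) > 0L) {
    stop("annotation references contig(s) absent from the genome: ",
         paste(unknown, collapse = ", "))
  }
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  oob <- GenomicRanges::start(gr) < 1L |
    GenomicRanges::end(gr) > lens[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(oob)) {
    id <- if (!is.null(gr$locus_tag)) gr$locus_tag[oob] else which(oob)
    stop("feature(s) outside contig bounds: ",
         paste(utils::head(stats::na.omit(id), 5), collapse = ", "))
  }
  tags <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else
    rep(NA_character_, length(gr))
  missing_tag <- is.na(tags) | tags == ""
  if (any(missing_tag)) {
    warning(sum(missing_tag), " feature(s) lack a locus_tag; synthetic IDs assigned")
    tags[missing_tag] <- sprintf("feature_%05d", which(missing_tag))
  }
  if (anyDuplicated(tags)) {
    stop("duplicate locus tag(s): ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "))
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    locus_tag = tags,
    product = if (!is.null(gr$product)) as.character(gr$product) else NA_character_,
    seqinfo = genome_seqinfo(genome)
  )
  sort(out, ignore.strand = TRUE)
}

#' Seqinfo for a genome
#' @param genome A `DNAStringSet`.
#' @return A `Seqinfo` with the contig names and lengths.
#' @keywords internal
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = Biostrings::width(genome))
}

#' Derive intergenic and merged coding interval sets
#'
#' Builds the strand-agnostic complement of the merged gene set on every
#' contig. Overlapping or book-ended genes are merged first, so on each
#' contig coding length plus intergenic length equals contig length.
#'
#' @param genes `GRanges` of genes (e.g. from [read_annotation()]). May be
#'   empty, in which case whole contigs are intergenic.
#' @param genome A `DNAStringSet` providing contig bounds.
#' @return A list with `intergenic` and `coding`, both sorted, strand-free,
#'   non-overlapping `GRanges` spanning the genome between them.
#' @export
derive_intergenic <- function(genes, genome) {
  si <- genome_seqinfo(genome)
  whole <- GenomicRanges::GRanges(
    seqnames = names(genome),
    ranges = IRanges::IRanges(1L, Biostrings::width(genome)),
    seqinfo = si)
  if (length(genes) == 0L) {
    coding <- GenomicRanges::GRanges(seqinfo = si)
    return(list(intergenic = whole, coding = coding))
  }
  g <- GenomicRanges::granges(genes)
  GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevels(si)
  GenomeInfoDb::seqinfo(g) <- si
  GenomicRanges::strand(g) <- "*"
  coding <- GenomicRanges::reduce(sort(g))
  intergenic <- GenomicRanges::setdiff(whole, coding, ignore.strand = TRUE)
  list(intergenic = sort(intergenic), coding = sort(coding))
}

# base counts over a set of intervals, N excluded from AT denominator
.at_counts <- function(genome, gr) {
  if (length(gr) == 0L) stop("empty interval set")
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  contig <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- !(contig %in% names(genome))
  if (any(bad)) stop("interval on unknown contig: ", paste(unique(contig[bad]), collapse = ", "))
  oob <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens[contig]
  if (any(oob)) stop("interval out of contig bounds at index ",
                     paste(utils::head(which(oob), 5), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(genome[contig],
                                   start = GenomicRanges::start(gr),
                                   end = GenomicRanges::end(gr))
  Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
}

#' AT fraction of genomic intervals
#'
#' Fraction (#A + #T) / (#A + #C + #G + #T) per interval; N bases do not
#' enter the denominator. An interval consisting entirely of N yields `NA`.
#'
#' @param genome A `DNAStringSet`.
#' @param gr A `GRanges` of intervals within contig bounds.
#' @return Numeric vector of AT fractions in `[0, 1]`, one per interval
#'   (`NA` for all-N intervals).
#' @export
at_fraction <- function(genome, gr) {
  cts <- .at_counts(genome, gr)
  denom <- rowSums(cts)
  out <- (cts[, "A"] + cts[, "T"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Pooled (length-weighted) AT fraction of an interval set
#'
#' Base counts are summed over all intervals before dividing, which equals
#' the AT fraction of the concatenated sequence.
#'
#' @inheritParams at_fraction
#' @return A single AT fraction (`NA` if every base is N).
#' @export
pooled_at <- function(genome, gr) {
  cts <- colSums(.at_counts(genome, gr))
  denom <- sum(cts)
  if (denom == 0) return(NA_real_)
  unname((cts[["A"]] + cts[["T"]]) / denom)
}

#' Per-region AT fractions of an interval set
#'
#' One AT fraction per interval, order preserved. Unlike [pooled_at()],
#' the mean of this vector weights every region equally regardless of its
#' length.
#'
#' @inheritParams at_fraction
#' @return Numeric vector, same length and order as `gr`.
#' @export
per_region_at <- function(genome, gr) {
  at_fraction(genome, gr)
}

#' Default amino-acid similarity groups
#'
#' Five classes partitioning the 20 standard residues: basic (K, R, H),
#' acidic (D, E), polar uncharged (S, T, N, Q), hydrophobic
#' (A, V, I, L, M, F, Y, W) and special cases (C, G, P).
#'
#' @return Named list of character vectors partitioning the 20 letters.
#' @export
similarity_groups <- function() {
  list(basic       = c("K", "R", "H"),
       acidic      = c("D", "E"),
       polar       = c("S", "T", "N", "Q"),
       hydrophobic = c("A", "V", "I", "L", "M", "F", "Y", "W"),
       special     = c("C", "G", "P"))
}

.check_groups <- function(groups) {
  all20 <- sort(unlist(groups, use.names = FALSE))
  if (any(duplicated(all20))) stop("similarity groups are not disjoint")
  expected <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!identical(all20, expected)) {
    stop("similarity groups must partition the 20 standard amino acids")
  }
  invisible(groups)
}

#' Percent identity and similarity of a pairwise protein alignment
#'
#' Identity is the percentage of alignment columns where both rows carry
#' the same residue; similarity additionally counts columns whose residues
#' fall in the same similarity group. By default the denominator is the
#' full number of alignment columns, so gap columns count as
#' mismatched/dissimilar; `denominator = "ungapped"` restricts to columns
#' with a residue in both rows. The choice is recorded in the result.
#'
#' @param a,b Aligned sequences of equal length (single strings or
#'   character vectors of residues); gap character `"-"`.
#' @param groups Similarity groups as from [similarity_groups()].
#' @param denominator `"columns"` (default) or `"ungapped"`.
#' @return List with `identity`, `similarity` (percent), `n_columns`,
#'   `denominator`.
#' @examples
#' identity_similarity("KAD", "RAD")  # identity 66.67, similarity 100
#' @export
identity_similarity <- function(a, b, groups = similarity_groups(),
                                denominator = c("columns", "ungapped")) {
  denominator <- match.arg(denominator)
  .check_groups(groups)
  to_chars <- function(x) {
    x <- toupper(as.character(x))
    if (length(x) == 1L) x <- strsplit(x, "")[[1]]
    x
  }
  a <- to_chars(a); b <- to_chars(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty alignment")
  if (length(a) != length(b)) {
    stop("aligned sequences differ in length (", length(a), " vs ", length(b), ")")
  }
  group_of <- rep(names(groups), lengths(groups))
  names(group_of) <- unlist(groups, use.names = FALSE)
  resid <- a != "-" & b != "-"
  ident <- resid & a == b
  same_group <- resid & !is.na(group_of[a]) & !is.na(group_of[b]) &
    group_of[a] == group_of[b]
  denom <- if (denominator == "columns") length(a) else sum(resid)
  if (denom == 0L) stop("alignment has no ungapped columns")
  list(identity = 100 * sum(ident) / denom,
       similarity = 100 * sum(same_group | ident) / denom,
       n_columns = length(a),
       denominator = denominator)
}

#' Read a pairwise alignment from aligned FASTA
#'
#' @param path Aligned FASTA with at least two records of equal length.
#' @return List of two uppercase character strings named by record.
#' @export
read_pairwise_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("pairwise alignment needs two records, found ", length(set))
  if (length(unique(Biostrings::width(set)[1:2])) != 1L) {
    stop("aligned records differ in length")
  }
  stats::setNames(as.list(toupper(as.character(set[1:2]))),
                  sub("\\s.*$", "", names(set)[1:2]))
}

#' Write an interval set as BED
#'
#' @param gr A `GRanges`.
#' @param path Output path; standard 0-based half-open BED is produced.
#' @param names Optional name column.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, names = NULL) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(names)) df$name <- names
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
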