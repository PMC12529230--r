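test_that("narrowPeak summit offset arithmetic and round-trips", {
  g <- make_genome(chr = random_seq(1000))
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr\t100\t200\tpk1\t0\t.\t3.5\t-1\t2\t40", np)
  pk <- read_peaks(np, "narrowPeak", g)
  expect_identical(GenomicRanges::start(pk), 101L)
  expect_identical(GenomicRanges::end(pk), 200L)
  expect_identical(pk$summit, 141L)   # 0-based 100 + offset 40 -> 1-based 141
  expect_equal(pk$fold_enrichment, 3.5)

  # empty file is a valid empty table
  empty <- withr::local_tempfile(fileext = ".narrowPeak")
  file.create(empty)
  expect_length(read_peaks(empty, "narrowPeak", g), 0L)

  # negative fold enrichment rejected
  writeLines("chr\t100\t200\tpk1\t0\t.\t-1\t-1\t2\t40", np)
  expect_error(read_peaks(np, "narrowPeak", g), "fold_enrichment")

  # summary-tsv round-trip is bit-exact on coordinates and FE
  pk2 <- peak_table(data.frame(peak_id = c("a", "b"), contig = "chr",
                               start = c(10L, 500L), end = c(60L, 700L),
                               summit = c(30L, 600L),
                               fold_enrichment = c(1.25, 3.75)), g)
  ts <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(pk2, ts, "summary-tsv")
  back <- read_peaks(ts, "summary-tsv", g)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(pk2))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(pk2))
  expect_identical(back$summit, pk2$summit)
  expect_identical(back$fold_enrichment, pk2$fold_enrichment)
  # narrowPeak round-trip preserves span and summit too
  np2 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(pk2, np2, "narrowPeak")
  back2 <- read_peaks(np2, "narrowPeak", g)
  expect_identical(GenomicRanges::start(back2), GenomicRanges::start(pk2))
  expect_identical(back2$summit, pk2$summit)
})

test_that("peak_table validates summits, spans and contigs", {
  g <- make_genome(chr = random_seq(300))
  df <- data.frame(peak_id = "p", contig = "chr", start = 10, end = 50,
                   summit = 60, fold_enrichment = 2)
  expect_error(peak_table(df, g), "summit")
  df$summit <- 30; df$contig <- "nope"
  expect_error(peak_table(df, g), "unknown contig")
  df$contig <- "chr"; df$end <- 400; df$summit <- 200
  expect_error(peak_table(df, g), "contig end")
})

test_that("summit_window spans flank bp each side and clips at edges", {
  g <- make_genome(chr = random_seq(1000))
  pk <- peak_table(data.frame(peak_id = c("mid", "left", "right"),
                              contig = "chr",
                              start = c(400, 1, 900), end = c(600, 40, 1000),
                              summit = c(500, 10, 995),
                              fold_enrichment = 1), g)
  w <- summit_window(pk, flank = 30, genome = g)
  expect_identical(GenomicRanges::start(w), c(470L, 1L, 965L))
  expect_identical(GenomicRanges::end(w), c(529L, 39L, 1000L))
  expect_identical(GenomicRanges::width(w), c(60L, 39L, 36L))
})

test_that("classify_context applies the strict >30 bp rule", {
  g <- make_genome(chr = random_seq(2000))
  genes <- make_genes("chr", 501, 1500, genome = g)   # intergenic: 1-500, 1501-2000
  inter <- derive_intergenic(genes, g)$intergenic
  pk <- peak_table(data.frame(
    peak_id = c("inORF", "exact30", "just31", "fullInter"),
    contig = "chr", start = c(900, 400, 400, 100), end = c(1100, 600, 600, 300),
    # summit 1000 -> window [970,1029], all coding; summit 501 -> [471,530],
    # 30 intergenic bp (471..500); summit 500 -> [470,529], 31 bp; summit 200 ->
    # [170,229], all intergenic
    summit = c(1000, 501, 500, 200), fold_enrichment = 1), g)
  w <- summit_window(pk, genome = g)
  ctx <- classify_context(w, inter)
  expect_identical(ctx$context, c("coding", "coding", "intergenic", "intergenic"))
  expect_identical(ctx$intergenic_overlap_bp, c(0L, 30L, 31L, 60L))
  expect_identical(ctx$window_fully_in_context, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("classify_context agrees with a per-base membership oracle", {
  set.seed(23)
  for (rep in 1:40) {
    L <- 3000L
    g <- make_genome(chr = random_seq(L))
    n <- sample(1:10, 1)
    s <- sort(sample.int(L - 100, n))
    e <- pmin(L, s + sample(20:400, n, replace = TRUE))
    genes <- make_genes("chr", s, e, tags = sprintf("t%02d", 1:n), genome = g)
    inter <- derive_intergenic(genes, g)$intergenic
    inter_mask <- !bp_mask(s, e, L)
    m <- 25L
    summits <- sample(1:L, m)
    pk <- peak_table(data.frame(peak_id = sprintf("p%02d", 1:m), contig = "chr",
                                start = pmax(1L, summits - 50L),
                                end = pmin(L, summits + 50L),
                                summit = summits, fold_enrichment = 1), g)
    w <- summit_window(pk, genome = g)
    ctx <- classify_context(w, inter)
    for (i in seq_len(m)) {
      ov <- sum(inter_mask[GenomicRanges::start(w)[i]:GenomicRanges::end(w)[i]])
      expect_identical(ctx$intergenic_overlap_bp[i], ov)
      expect_identical(ctx$context[i], if (ov > 30) "intergenic" else "coding")
    }
  }
})

test_that("filter_fe includes the boundary and preserves order", {
  pk <- peak_table(data.frame(peak_id = letters[1:5], contig = "c",
                              start = seq(1, 401, 100), end = seq(50, 450, 100),
                              fold_enrichment = c(1.5, 2.0, 2.1, 3.0, 0.9)))
  kept <- filter_fe(pk, 2.0)
  expect_identical(kept$peak_id, c("b", "c", "d"))
  expect_length(filter_fe(pk, 0), 5L)
  expect_length(filter_fe(pk[0], 2), 0L)
})

test_that("top_bottom sorts deterministically and handles k >= n", {
  pk <- peak_table(data.frame(peak_id = letters[1:5], contig = "c",
                              start = seq(1, 401, 100), end = seq(50, 450, 100),
                              fold_enrichment = c(1, 2, 3, 4, 5)))
  tb <- top_bottom(pk, 2)
  expect_identical(tb$top$fold_enrichment, c(5, 4))
  expect_identical(sort(tb$bottom$fold_enrichment), c(1, 2))
  big <- top_bottom(pk, 20)
  expect_length(big$top, 5L)
  expect_length(big$bottom, 5L)
  # deterministic tie-break by (contig, start)
  tie <- peak_table(data.frame(peak_id = c("x", "y"), contig = "c",
                               start = c(200, 100), end = c(250, 150),
                               fold_enrichment = c(2, 2)))
  expect_identical(top_bottom(tie, 1)$top$peak_id, "y")
})

test_that("category membership is nested and consistent", {
  set.seed(31)
  pk <- peak_table(data.frame(peak_id = sprintf("p%02d", 1:50), contig = "c",
                              start = seq(1, by = 500, length.out = 50),
                              end = seq(1, by = 500, length.out = 50) + sample(50:400, 50, TRUE),
                              fold_enrichment = runif(50, 0.5, 5)))
  ctx <- data.frame(peak_id = pk$peak_id,
                    context = sample(c("intergenic", "coding"), 50, TRUE),
                    intergenic_overlap_bp = 0L, window_fully_in_context = FALSE)
  rep <- category_report(pk, ctx, k = 20, fe_threshold = 2)
  all_ids <- rep$members[[1]]
  expect_true(all(rep$members[[2]] %in% all_ids))
  expect_true(all(rep$members[[3]] %in% all_ids))
  expect_length(intersect(rep$members[[3]], rep$members[[4]]), 0L)  # n >= 2k
  expect_identical(rep$n[2], sum(pk$fold_enrichment >= 2))
  expect_equal(rep$percent_intergenic[1],
               100 * mean(ctx$context == "intergenic"))
  # one intergenic + one coding peak -> 50%
  two <- peak_table(data.frame(peak_id = c("a", "b"), contig = "c",
                               start = c(1, 100), end = c(50, 150),
                               fold_enrichment = c(1, 2)))
  ctx2 <- data.frame(peak_id = c("a", "b"), context = c("intergenic", "coding"),
                     intergenic_overlap_bp = 0L, window_fully_in_context = FALSE)
  expect_equal(category_report(two, ctx2)$percent_intergenic[1], 50)
})

test_that("merge_subpeaks merges by gap, letters members, and covers inputs once", {
  pk <- peak_table(data.frame(peak_id = c("p1", "p2", "p3"), contig = "c",
                              start = c(1, 151, 1000), end = c(100, 300, 1100),
                              fold_enrichment = c(1, 3, 2)))
  m <- merge_subpeaks(pk, max_gap_bp = 100)
  expect_length(m$regions, 2L)
  expect_identical(GenomicRanges::start(m$regions), c(1L, 1000L))
  expect_identical(GenomicRanges::end(m$regions), c(300L, 1100L))
  expect_identical(m$regions$max_fold_enrichment, c(3, 2))
  expect_identical(m$members$subpeak_id[1:2], paste0(m$regions$region_id[1], c("a", "b")))
  expect_identical(m$members$subpeak_id[3], m$regions$region_id[2])  # singleton unsuffixed
  # gap wider than max_gap stays split
  pk2 <- peak_table(data.frame(peak_id = c("p1", "p2"), contig = "c",
                               start = c(1, 252), end = c(100, 300),
                               fold_enrichment = 1))
  expect_length(merge_subpeaks(pk2, 100)$regions, 2L)
  # gap exactly max_gap merges
  pk3 <- peak_table(data.frame(peak_id = c("p1", "p2"), contig = "c",
                               start = c(1, 201), end = c(100, 300),
                               fold_enrichment = 1))
  expect_length(merge_subpeaks(pk3, 100)$regions, 1L)
})

test_that("merge_subpeaks agrees with an interval-merge oracle on random tables", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    s <- sort(sample.int(5000, n))
    e <- s + sample(10:200, n, replace = TRUE)
    # avoid overlapping duplicated ids, allow overlaps in spans
    pk <- peak_table(data.frame(peak_id = sprintf("p%02d", 1:n), contig = "c",
                                start = s, end = e, fold_enrichment = runif(n, 1, 5)))
    gap <- sample(c(0, 50, 150), 1)
    m <- merge_subpeaks(pk, gap)
    # oracle: bp mask dilated by gap
    L <- max(e) + gap + 2
    mask <- bp_mask(s, e, L)
    merged <- mask_to_intervals(mask)
    # merge runs separated by <= gap
    if (nrow(merged) > 1) {
      keep <- list(merged[1, ])
      for (i in 2:nrow(merged)) {
        last <- keep[[length(keep)]]
        if (merged[i, "start"] - last["end"] - 1 <= gap) {
          last["end"] <- merged[i, "end"]; keep[[length(keep)]] <- last
        } else keep[[length(keep) + 1]] <- merged[i, ]
      }
      merged <- do.call(rbind, keep)
    }
    expect_identical(as.integer(GenomicRanges::start(m$regions)),
                     as.integer(merged[, "start"]))
    expect_identical(as.integer(GenomicRanges::end(m$regions)),
                     as.integer(merged[, "end"]))
    # every peak appears exactly once; regions non-overlapping
    expect_setequal(m$members$peak_id, pk$peak_id)
    expect_identical(anyDuplicated(m$members$peak_id), 0L)
    if (length(m$regions) > 1) {
      expect_true(all(GenomicRanges::start(m$regions)[-1] >
                      GenomicRanges::end(m$regions)[-length(m$regions)]))
    }
  }
})

test_that("annotate_genes lists overlapping genes in genomic order", {
  g <- make_genome(chr = random_seq(2000))
  genes <- make_genes("chr", c(100, 500, 1200), c(300, 900, 1500),
                      tags = c("gA", "gB", "gC"), genome = g)
  pk <- peak_table(data.frame(peak_id = c("inside", "spanning", "none"),
                              contig = "chr",
                              start = c(150, 250, 1000), end = c(200, 600, 1100),
                              fold_enrichment = 1), g)
  ann <- annotate_genes(pk, genes)
  expect_identical(ann$locus_tag[ann$query_id == "inside"], "gA")
  expect_identical(ann$locus_tag[ann$query_id == "spanning"], c("gA", "gB"))
  expect_false("none" %in% ann$query_id)
})

test_that("annotate_genes matches a per-bp overlap oracle on random cases", {
  set.seed(53)
  for (rep in 1:40) {
    L <- 4000L
    n <- sample(2:15, 1)
    gs <- sort(sample.int(L - 200, n))
    ge <- pmin(L, gs + sample(20:300, n, replace = TRUE))
    tags <- sprintf("g%02d", 1:n)
    g <- make_genome(chr = random_seq(L))
    genes <- make_genes("chr", gs, ge, tags = tags, genome = g)
    ps <- sample.int(L - 400, 5)
    pk <- peak_table(data.frame(peak_id = sprintf("p%d", 1:5), contig = "chr",
                                start = ps, end = ps + sample(50:400, 5, TRUE),
                                fold_enrichment = 1), g)
    ann <- annotate_genes(pk, genes)
    for (i in 1:5) {
      hit <- tags[ge >= GenomicRanges::start(pk)[i] & gs <= GenomicRanges::end(pk)[i]]
      got <- ann$locus_tag[ann$query_id == pk$peak_id[i]]
      expect_identical(got, hit)
    }
  }
})

test_that("width_fe_correlation matches closed forms and flags degeneracy", {
  w <- c(100L, 220L, 340L, 460L, 580L)
  pk <- peak_table(data.frame(peak_id = letters[1:5], contig = "c",
                              start = seq(1, 4001, 1000),
                              end = seq(1, 4001, 1000) + w - 1L,
                              fold_enrichment = 1 + 0.001 * w))
  res <- width_fe_correlation(pk)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 0.001, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-10)
  const <- peak_table(data.frame(peak_id = letters[1:3], contig = "c",
                                 start = c(1, 200, 400), end = c(100, 299, 499),
                                 fold_enrichment = c(1, 2, 3)))
  expect_error(width_fe_correlation(const), "constant")
})

test_that("reproducible_peaks requires overlap in every replicate and averages FE", {
  g <- make_genome(chr = random_seq(3000))
  mk <- function(s, e, fe) peak_table(data.frame(
    peak_id = sprintf("p%d", seq_along(s)), contig = "chr",
    start = s, end = e, fold_enrichment = fe), g)
  r1 <- mk(c(100, 1000, 2000), c(300, 1200, 2200), c(2, 3, 4))
  r2 <- mk(c(150, 2100), c(350, 2300), c(2.5, 5))
  r3 <- mk(c(90, 2050), c(310, 2250), c(1.5, 3))
  rep <- reproducible_peaks(list(r1, r2, r3))
  expect_identical(rep$peak_id, c("p1", "p3"))
  expect_equal(rep$fold_enrichment, c(mean(c(2, 2.5, 1.5)), mean(c(4, 5, 3))))
  expect_identical(rep$replicate_support, c(3L, 3L))
})
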