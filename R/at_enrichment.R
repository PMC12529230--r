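#' Collect summit-window AT fractions per genic context
#'
#' Partitions summit windows by their context call and returns the AT
#' fraction of each window. Windows consisting entirely of N are dropped
#' with a warning.
#'
#' @param windows Summit-window `GRanges` from [summit_window()].
#' @param contexts Context calls from [classify_context()].
#' @param genome A `DNAStringSet`.
#' @return List with numeric vectors `intergenic` and `coding` (named by
#'   `peak_id`), plus `at` -- the full named vector in window order.
#' @export
collect_at <- function(windows, contexts, genome) {
  at <- at_fraction(genome, windows)
  names(at) <- windows$peak_id
  if (anyNA(at)) {
    warning(sum(is.na(at)), " all-N window(s) excluded from AT vectors")
  }
  ctx <- stats::setNames(contexts$context, contexts$peak_id)[windows$peak_id]
  keep <- !is.na(at)
  list(intergenic = at[keep & ctx == "intergenic"],
       coding = at[keep & ctx == "coding"],
       at = at)
}

#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test of two samples, Welch (unequal variances,
#' default) or Student (pooled variance) variant.
#'
#' @param a,b Numeric samples, each with `n >= 2` and positive variance.
#' @param variant `"welch"` or `"student"`.
#' @return List with `t`, `p`, `df`, `variant`.
#' @export
unpaired_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate samples: zero variance in both groups")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), variant = variant)
}

#' Two-sided permutation test for a difference in means
#'
#' Group labels are permuted `n_perm` times; the p-value is
#' `(1 + #\{|diff_perm| >= |diff_obs|\}) / (n_perm + 1)`.
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of permutations, at least 99 (default 999).
#' @param seed Integer seed, recorded in the result.
#' @return List with `p`, `observed_diff`, `n_perm`, `seed`.
#' @export
permutation_test <- function(a, b, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    ix <- sample.int(length(pool), na)
    d <- mean(pool[ix]) - mean(pool[-ix])
    if (abs(d) >= abs(obs) - 1e-15) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (n_perm + 1), observed_diff = obs,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' AT-enrichment report: peak windows versus genomic backgrounds
#'
#' For every fold-enrichment category and each genic context, compares
#' the AT fractions of the category's summit windows with a genomic
#' background of the matching context and runs a two-sided unpaired t
#' test (optionally a permutation test as well). The default background
#' is one AT value per genomic intergenic (or merged coding) interval;
#' `background = "windows"` instead draws `n_background` random
#' window-length segments from the background intervals, equalizing
#' measurement variance.
#'
#' @param report Category report from [category_report()].
#' @param contexts Context calls from [classify_context()].
#' @param window_at Named per-peak window AT vector (from
#'   [collect_at()]`$at`).
#' @param genome A `DNAStringSet`.
#' @param intergenic,coding Background `GRanges` from
#'   [derive_intergenic()].
#' @param variant t-test variant, see [unpaired_t()].
#' @param background `"per-region"` (default) or `"windows"`.
#' @param window_bp Window length for `background = "windows"` (default
#'   60).
#' @param n_background Number of background windows drawn per context
#'   (default 500).
#' @param alpha Significance threshold (default 0.001).
#' @param seed Seed for background window sampling.
#' @param pooled Also emit, per category, comparisons of all its usable
#'   windows (regardless of context call) against each background
#'   (`context` = `"all-vs-intergenic"` / `"all-vs-coding"`); default
#'   `TRUE`.
#' @return Data frame, one row per category x context: sample sizes,
#'   means, `t`, `df`, `p`, `significant`, `method`; rows with fewer than
#'   2 usable windows are marked not computable (`NA` statistics).
#' @export
at_report <- function(report, contexts, window_at, genome, intergenic, coding,
                      variant = c("welch", "student"),
                      background = c("per-region", "windows"),
                      window_bp = 60L, n_background = 500L,
                      alpha = 0.001, seed = 1L, pooled = TRUE) {
  variant <- match.arg(variant)
  background <- match.arg(background)
  bg <- list(
    intergenic = .background_at(genome, intergenic, background, window_bp,
                                n_background, seed),
    coding = .background_at(genome, coding, background, window_bp,
                            n_background, seed + 1L))
  ctx <- stats::setNames(contexts$context, contexts$peak_id)
  method <- paste0(variant, "/", background)
  one_row <- function(category, label, x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    computable <- length(x) >= 2L && length(y) >= 2L &&
      (stats::var(x) > 0 || stats::var(y) > 0)
    if (computable) {
      tt <- unpaired_t(x, y, variant)
      data.frame(category = category, context = label,
                 n_peaks = length(x), n_background = length(y),
                 mean_at_peaks = mean(x), mean_at_background = mean(y),
                 t = tt$t, df = tt$df, p = tt$p,
                 significant = tt$p < alpha, computable = TRUE,
                 method = method, stringsAsFactors = FALSE)
    } else {
      data.frame(category = category, context = label,
                 n_peaks = length(x), n_background = length(y),
                 mean_at_peaks = if (length(x) > 0) mean(x) else NA_real_,
                 mean_at_background = if (length(y) > 0) mean(y) else NA_real_,
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 significant = NA, computable = FALSE,
                 method = method, stringsAsFactors = FALSE)
    }
  }
  rows <- list()
  for (i in seq_len(nrow(report))) {
    ids <- report$members[[i]]
    cat_i <- report$category[i]
    for (context in c("intergenic", "coding")) {
      rows[[length(rows) + 1L]] <-
        one_row(cat_i, context, window_at[ids[ctx[ids] == context]], bg[[context]])
    }
    if (pooled) {
      for (context in c("intergenic", "coding")) {
        rows[[length(rows) + 1L]] <-
          one_row(cat_i, paste0("all-vs-", context), window_at[ids], bg[[context]])
      }
    }
  }
  do.call(rbind, rows)
}

# background AT sample: per interval, or random fixed-length windows
.background_at <- function(genome, gr, background, window_bp, n_background, seed) {
  if (background == "per-region") return(per_region_at(genome, gr))
  gr <- gr[GenomicRanges::width(gr) >= window_bp]
  if (length(gr) == 0L) return(numeric(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  w <- GenomicRanges::width(gr)
  pick <- sample.int(length(gr), n_background, replace = TRUE,
                     prob = w - window_bp + 1)
  off <- floor(stats::runif(n_background) * (w[pick] - window_bp + 1))
  win <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gr)[pick],
    ranges = IRanges::IRanges(GenomicRanges::start(gr)[pick] + as.integer(off),
                              width = window_bp))
  at_fraction(genome, win)
}
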