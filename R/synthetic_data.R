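#' Genome simulation specification
#'
#' Conditions for the synthetic genome: one contig whose coding regions
#' have ~53% AT and whose intergenic regions have ~62% AT, the
#' composition contrast the analyses are designed to detect.
#'
#' @param contig_length_bp Contig length (default 200000).
#' @param n_genes Number of genes (default 150).
#' @param gene_length_bp Two-element range of gene lengths (default
#'   `c(500, 1500)`).
#' @param coding_at Target AT fraction of coding bases (default 0.53).
#' @param intergenic_at Target AT fraction of intergenic bases (default
#'   0.62).
#' @param gap_shape Gamma shape of the random weights distributing
#'   intergenic space over gaps (default 0.3). Small values give a
#'   heavy-tailed gap-size distribution -- many short inter-operon gaps
#'   plus a few kilobase-scale intergenic islands, the landscape on
#'   which kilobase enrichment zones form.
#' @param seed Master seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(contig_length_bp = 200000L, n_genes = 160L,
                        gene_length_bp = c(500L, 1500L),
                        coding_at = 0.53, intergenic_at = 0.62,
                        gap_shape = 0.3, seed = 1L) {
  stopifnot(coding_at > 0, coding_at < 1, intergenic_at > 0, intergenic_at < 1,
            contig_length_bp > 0, n_genes >= 0, gap_shape > 0,
            length(gene_length_bp) == 2L, gene_length_bp[1] <= gene_length_bp[2])
  structure(list(contig_length_bp = as.integer(contig_length_bp),
                 n_genes = as.integer(n_genes),
                 gene_length_bp = as.integer(gene_length_bp),
                 coding_at = coding_at, intergenic_at = intergenic_at,
                 gap_shape = gap_shape,
                 seed = as.integer(seed)), class = "genome_spec")
}

# deterministic master-seed -> child-seed split; adding a stream never
# perturbs earlier streams (child i depends only on master and i)
child_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stream) * 69621) %% 2147483647)
}

# draw n bases with P(A or T) = at; A/T and C/G symmetric
.draw_bases <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

#' Simulate a genome with contrasting coding/intergenic AT composition
#'
#' Places `n_genes` non-overlapping genes with strictly positive
#' intergenic gaps (including both contig ends), then draws every base
#' independently with P(A or T) equal to the AT target of its region
#' class.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (`DNAStringSet`, one contig `"chr"`) and
#'   `genes` (`GRanges` with `locus_tag`, `product`).
#' @export
simulate_genome <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(spec$seed, 1L))
  L <- spec$contig_length_bp
  n <- spec$n_genes
  if (n == 0L) {
    seqchr <- paste(.draw_bases(L, spec$intergenic_at), collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(seqchr, "chr"))
    return(list(genome = genome,
                genes = GenomicRanges::GRanges(seqinfo = genome_seqinfo(genome))))
  }
  glen_range <- seq(spec$gene_length_bp[1], spec$gene_length_bp[2])
  glen <- glen_range[sample.int(length(glen_range), n, replace = TRUE)]
  slack <- L - sum(glen) - (n + 1L)  # one mandatory bp per gap, n+1 gaps
  if (slack < 0L) stop("infeasible packing: genes do not fit with positive gaps")
  # heavy-tailed gap sizes: many short gaps, a few kilobase islands
  wts <- stats::rgamma(n + 1L, shape = spec$gap_shape)
  extra <- if (slack > 0L) as.vector(stats::rmultinom(1, slack, wts + 1e-12)) else
    rep(0L, n + 1L)
  gaps <- 1L + extra
  starts <- cumsum(c(0L, glen)) + cumsum(gaps)
  starts <- starts[seq_len(n)] + 1L
  ends <- starts + glen - 1L
  bases <- character(L)
  inter_mask <- rep(TRUE, L)
  for (i in seq_len(n)) inter_mask[starts[i]:ends[i]] <- FALSE
  bases[!inter_mask] <- .draw_bases(sum(!inter_mask), spec$coding_at)
  bases[inter_mask] <- .draw_bases(sum(inter_mask), spec$intergenic_at)
  genome <- Biostrings::DNAStringSet(stats::setNames(paste(bases, collapse = ""), "chr"))
  genes <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(starts, ends),
    strand = sample(c("+", "-"), n, replace = TRUE),
    locus_tag = sprintf("syn_%04d", seq_len(n)),
    product = "synthetic protein",
    seqinfo = genome_seqinfo(genome))
  list(genome = genome, genes = genes)
}

#' Occupancy simulation specification
#'
#' Parameters of the AT-coupled expected fold-enrichment track: a
#' logistic link from the local AT fraction to enrichment above a unit
#' baseline, bounding enrichment at `baseline + bias_alpha`. Defaults
#' put simulated maxima in the 3-5 fold range over an AT-rich intergenic
#' landscape.
#'
#' @param window_w Moving-average window for local AT, bp (default 200,
#'   the scale of a protected binding patch; this couples occupancy to
#'   the composition of the summit neighbourhood).
#' @param bias_alpha Enrichment amplitude (>= 0, default 4; 0 gives a
#'   flat null track).
#' @param baseline Baseline fold enrichment (default 1).
#' @param at_midpoint Logistic midpoint on the AT scale (default 0.62,
#'   the intergenic AT target, so enrichment discriminates among
#'   intergenic neighbourhoods rather than merely between region
#'   classes).
#' @param at_scale Logistic scale (default 0.02, about one SD of the
#'   windowed AT fraction).
#' @param seed Master seed for downstream sampling.
#' @return An `occupancy_spec` list.
#' @export
occupancy_spec <- function(window_w = 200L, bias_alpha = 4, baseline = 1,
                           at_midpoint = 0.62, at_scale = 0.02, seed = 1L) {
  stopifnot(window_w >= 1L, bias_alpha >= 0, baseline > 0, at_scale > 0)
  structure(list(window_w = as.integer(window_w), bias_alpha = bias_alpha,
                 baseline = baseline, at_midpoint = at_midpoint,
                 at_scale = at_scale, seed = as.integer(seed)),
            class = "occupancy_spec")
}

#' Expected occupancy (fold-enrichment) track
#'
#' Deterministic per-bp expected fold enrichment
#' `E(x) = baseline + alpha * logistic((AT_w(x) - midpoint) / scale)`,
#' where `AT_w` is the centered moving AT fraction over `window_w` bp
#' (edges use the partial window).
#'
#' @param genome A `DNAStringSet` (single contig or first contig used).
#' @param spec An [occupancy_spec()].
#' @param contig Contig name (default first).
#' @return Numeric vector of expected fold enrichment, one value per bp.
#' @export
occupancy_track <- function(genome, spec, contig = names(genome)[1]) {
  seqc <- strsplit(as.character(genome[[contig]]), "")[[1]]
  is_at <- as.numeric(seqc %in% c("A", "T"))
  w <- spec$window_w
  at_w <- data.table::frollmean(is_at, n = w, align = "center", adaptive = FALSE)
  # partial windows at the edges: fall back to cumulative means
  na_ix <- which(is.na(at_w))
  if (length(na_ix) > 0L) {
    L <- length(is_at)
    half <- w %/% 2L
    cs <- c(0, cumsum(is_at))
    lo <- pmax(1L, na_ix - half)
    hi <- pmin(L, na_ix + (w - half - 1L))
    at_w[na_ix] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  spec$baseline + spec$bias_alpha *
    stats::plogis((at_w - spec$at_midpoint) / spec$at_scale)
}

#' Sample replicated Poisson IP and input coverage
#'
#' IP depth at position x is Poisson with mean
#' `depth * E(x) / mean(E)`; input is Poisson with mean `depth`.
#' Replicates are independent, each on its own child seed derived from
#' the master seed so adding a replicate never perturbs earlier ones.
#'
#' @param expected Expected fold-enrichment track from
#'   [occupancy_track()].
#' @param depth Mean per-bp read depth (> 0, default 30).
#' @param n_replicates Number of replicates (default 3).
#' @param seed Master seed.
#' @return List with `ip` and `input`, each a list of integer vectors
#'   (one per replicate), plus `depth`.
#' @export
sample_coverage <- function(expected, depth = 30, n_replicates = 3L, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  mu_ip <- depth * expected / mean(expected)
  ip <- vector("list", n_replicates)
  input <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(child_seed(seed, 100L + r))
    ip[[r]] <- stats::rpois(length(expected), mu_ip)
    set.seed(child_seed(seed, 200L + r))
    input[[r]] <- stats::rpois(length(expected), depth)
  }
  list(ip = ip, input = input, depth = depth)
}

#' Toy peak caller on simulated coverage
#'
#' A deliberately simple run-based segmenter for simulated tracks (real
#' peak calling is out of scope): replicate-averaged IP and input are
#' smoothed with a centered moving average, the per-bp fold enrichment
#' `FE = (IP + 1) / (input + 1)` (normalized by the depth ratio) is
#' thresholded, runs closer than `merge_gap_bp` are merged, and runs
#' shorter than `min_width_bp` are dropped. The summit is the leftmost
#' argmax of FE inside the peak; the peak fold enrichment is the mean FE
#' over the peak.
#'
#' @param coverage Output of [sample_coverage()].
#' @param genome A `DNAStringSet` (for bounds/seqinfo).
#' @param smoothing_bp Moving-average window (default 200).
#' @param fe_cutoff Fold-enrichment threshold (default 1.5).
#' @param min_width_bp Minimum peak width (default 200).
#' @param merge_gap_bp Maximum sub-threshold gap to bridge (default 100).
#' @param contig Contig name (default first).
#' @return A peak `GRanges` as from [peak_table()].
#' @export
call_toy_peaks <- function(coverage, genome, smoothing_bp = 200L,
                           fe_cutoff = 1.5, min_width_bp = 200L,
                           merge_gap_bp = 100L, contig = names(genome)[1]) {
  ip <- Reduce(`+`, coverage$ip) / length(coverage$ip)
  input <- Reduce(`+`, coverage$input) / length(coverage$input)
  sm <- function(x) {
    y <- data.table::frollmean(x, n = smoothing_bp, align = "center")
    y[is.na(y)] <- x[is.na(y)]
    y
  }
  fe <- (sm(ip) + 1) / (sm(input) + 1)
  fe <- fe / (mean(ip + 1) / mean(input + 1))  # depth-ratio normalization
  above <- fe >= fe_cutoff
  if (!any(above)) return(peak_table(data.frame(), genome))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by <= merge_gap_bp
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= merge_gap_bp) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_width_bp, , drop = FALSE]
  if (nrow(merged) == 0L) return(peak_table(data.frame(), genome))
  summit <- integer(nrow(merged))
  pfe <- numeric(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    seg <- fe[merged$start[i]:merged$end[i]]
    summit[i] <- merged$start[i] + which.max(seg) - 1L
    pfe[i] <- mean(seg)
  }
  peak_table(data.frame(peak_id = sprintf("peak_%03d", seq_len(nrow(merged))),
                        contig = contig, start = merged$start, end = merged$end,
                        summit = summit, fold_enrichment = pfe),
             genome)
}

#' Uniformly placed null peaks
#'
#' Peaks with summits drawn uniformly over a contig and small
#' fluctuation-scale fold enrichments; the null model for context and
#' AT-calibration checks (a zero-amplitude occupancy track yields no
#' called peaks at all).
#'
#' @param genome A `DNAStringSet`.
#' @param n Number of peaks.
#' @param width_bp Peak width range (default `c(300, 1200)`).
#' @param seed Seed.
#' @param contig Contig name (default first).
#' @return A peak `GRanges`.
#' @export
random_peaks <- function(genome, n, width_bp = c(300L, 1200L), seed = 1L,
                         contig = names(genome)[1]) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 7L))
  L <- Biostrings::width(genome)[match(contig, names(genome))]
  w_range <- seq(width_bp[1], width_bp[2])
  w <- w_range[sample.int(length(w_range), n, replace = TRUE)]
  start <- vapply(w, function(wi) sample.int(L - wi + 1L, 1L), integer(1))
  end <- start + w - 1L
  summit <- start + vapply(w, function(wi) sample.int(wi, 1L), integer(1)) - 1L
  fe <- 1 + abs(stats::rnorm(n, 0, 0.15))
  peak_table(data.frame(peak_id = sprintf("null_%03d", seq_len(n)),
                        contig = contig, start = start, end = end,
                        summit = summit, fold_enrichment = fe),
             genome)
}

#' Simulate an EMSA saturation titration
#'
#' Fraction bound follows the single-site isotherm
#' `theta = c / (kd + c)` with additive Gaussian noise, clipped to
#' `[0, 1]`.
#'
#' @param kd_nM True dissociation constant, nM (> 0).
#' @param concentrations Protein concentrations, nM, ascending.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed Seed.
#' @param probe_id Probe label.
#' @return An `emsa_titration`.
#' @export
simulate_emsa <- function(kd_nM, concentrations, noise_sd = 0, seed = 1L,
                          probe_id = "sim") {
  if (kd_nM <= 0) stop("kd_nM must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 3L))
  theta <- concentrations / (kd_nM + concentrations)
  if (noise_sd > 0) theta <- theta + stats::rnorm(length(theta), 0, noise_sd)
  structure(list(probe_id = probe_id,
                 concentration_nM = as.numeric(concentrations),
                 fraction_bound = pmin(1, pmax(0, theta))),
            class = "emsa_titration")
}

#' Simulate an AFM topograph with ground truth
#'
#' Each complex is a cluster of Gaussian bumps (one per focus) placed on
#' a flat background; complexes are spaced so that they segment into
#' separate components. The realized per-complex maximum height and the
#' placed foci count are returned as ground truth.
#'
#' @param n_complexes Number of complexes.
#' @param heights_nm Per-complex peak amplitude(s), recycled.
#' @param foci Per-complex foci count(s), recycled.
#' @param map_size Map edge length in pixels (default 256).
#' @param sigma_px Gaussian bump SD in pixels (default 3).
#' @param foci_spacing_px Distance between focus centers within a
#'   complex (default `3 * sigma_px`: resolvable as separate maxima yet
#'   still connected above typical segmentation thresholds, as foci of
#'   one DNA-protein complex are).
#' @param noise_sd_nm Background Gaussian roughness SD (default 0.05).
#' @param seed Seed.
#' @return List with `map` (a `height_map`) and `truth` (data frame
#'   `complex_id`, `max_height_nm`, `foci_count`, `center_row`,
#'   `center_col`).
#' @export
simulate_afm <- function(n_complexes, heights_nm, foci = 1L, map_size = 256L,
                         sigma_px = 3, foci_spacing_px = 3 * sigma_px,
                         noise_sd_nm = 0.05, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 5L))
  z <- matrix(0, map_size, map_size)
  if (noise_sd_nm > 0) {
    z <- z + matrix(stats::rnorm(map_size^2, 0, noise_sd_nm), map_size, map_size)
  }
  if (n_complexes == 0L) {
    return(list(map = height_map(z),
                truth = data.frame(complex_id = integer(),
                                   max_height_nm = numeric(),
                                   foci_count = integer(),
                                   center_row = numeric(), center_col = numeric())))
  }
  heights_nm <- rep_len(heights_nm, n_complexes)
  foci <- rep_len(as.integer(foci), n_complexes)
  max_foci <- max(foci)
  complex_radius <- foci_spacing_px * (max_foci - 1) / 2 + 4 * sigma_px
  min_dist <- 2 * complex_radius + 4 * sigma_px
  margin <- ceiling(complex_radius) + 1
  if (2 * margin >= map_size) stop("map too small for the requested complexes")
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < n_complexes) {
    cand <- stats::runif(2, margin, map_size - margin)
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2))) >= min_dist) {
      centers <- rbind(centers, cand)
    }
    tries <- tries + 1L
    if (tries > 2000L * n_complexes) {
      stop("packing failure: cannot place ", n_complexes,
           " complexes without overlap")
    }
  }
  rows <- matrix(rep(seq_len(map_size), map_size), map_size, map_size)
  cols <- t(rows)
  truth <- data.frame(complex_id = seq_len(n_complexes),
                      max_height_nm = NA_real_, foci_count = foci,
                      center_row = centers[, 1], center_col = centers[, 2])
  for (i in seq_len(n_complexes)) {
    # foci laid out on a line through the complex center, random orientation
    ang <- stats::runif(1, 0, pi)
    offs <- (seq_len(foci[i]) - (foci[i] + 1) / 2) * foci_spacing_px
    fr <- centers[i, 1] + offs * cos(ang)
    fc <- centers[i, 2] + offs * sin(ang)
    for (k in seq_len(foci[i])) {
      z <- z + heights_nm[i] *
        exp(-((rows - fr[k])^2 + (cols - fc[k])^2) / (2 * sigma_px^2))
    }
    near <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= complex_radius^2
    truth$max_height_nm[i] <- max(z[near])
  }
  list(map = height_map(z), truth = truth)
}
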