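#' Fraction bound from EMSA lane intensities
#'
#' Converts per-lane free-probe and total signal into the bound fraction
#' `1 - free/total`, clipped to `[0, 1]`.
#'
#' @param concentrations Protein monomer concentrations (nM), strictly
#'   increasing, `>= 0`.
#' @param free_signal,total_signal Per-lane intensities; `total_signal`
#'   must be positive.
#' @param probe_id Optional probe label.
#' @return An `emsa_titration` list: `probe_id`, `concentration_nM`,
#'   `fraction_bound`.
#' @export
fraction_bound <- function(concentrations, free_signal, total_signal,
                           probe_id = "probe") {
  if (length(concentrations) != length(free_signal) ||
      length(free_signal) != length(total_signal)) {
    stop("concentrations, free_signal and total_signal must have equal length")
  }
  if (any(total_signal <= 0)) stop("zero or negative total signal in lane(s) ",
                                   paste(which(total_signal <= 0), collapse = ", "))
  if (any(diff(concentrations) <= 0)) stop("concentrations must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  theta <- pmin(1, pmax(0, 1 - free_signal / total_signal))
  structure(list(probe_id = probe_id,
                 concentration_nM = as.numeric(concentrations),
                 fraction_bound = theta),
            class = "emsa_titration")
}

#' Read EMSA lane-intensity tables
#'
#' TSV with columns `probe_id`, `concentration_nM`, `free_signal`,
#' `total_signal`; one titration per probe.
#'
#' @param path Input TSV path.
#' @return Named list of `emsa_titration` objects, one per probe.
#' @export
read_emsa <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("probe_id", "concentration_nM", "free_signal", "total_signal")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("EMSA TSV lacks column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$probe_id), function(d) {
    d <- d[order(d$concentration_nM), ]
    fraction_bound(d$concentration_nM, d$free_signal, d$total_signal,
                   probe_id = d$probe_id[1])
  })
  out[unique(df$probe_id)]
}

#' Fit an apparent dissociation constant to a saturation titration
#'
#' Least-squares fit of the single-site isotherm
#' `theta = [P] / (KD + [P])` (or the Hill variant
#' `theta = [P]^h / (KD^h + [P]^h)`) to a fraction-bound titration, with
#' a multistart over log-spaced KD initial values. The estimate is
#' "apparent": no mechanistic single-site claim is made for ladder-type
#' binding.
#'
#' @param titration An `emsa_titration` (see [fraction_bound()]).
#' @param model `"hyperbolic"` (default) or `"hill"`.
#' @param n_starts Number of log-spaced KD starting values spanning the
#'   concentration range (default 8).
#' @return List with `kd_apparent` (nM), `hill_coefficient` (`NA` for the
#'   hyperbolic model), `residual_sse`, `converged`, `model`, `n_points`.
#'   Non-convergence sets `converged = FALSE` rather than raising.
#' @export
fit_kd <- function(titration, model = c("hyperbolic", "hill"), n_starts = 8L) {
  model <- match.arg(model)
  conc <- titration$concentration_nM
  theta <- titration$fraction_bound
  if (length(conc) < 4L) stop("need at least 4 titration points")
  if (all(conc <= 0)) stop("titration needs positive concentrations")
  d <- data.frame(P = conc, y = theta)
  lo <- max(min(conc[conc > 0]), 1e-3)
  hi <- max(conc) * 10
  starts <- exp(seq(log(lo), log(hi), length.out = n_starts))
  best <- NULL
  for (kd0 in starts) {
    fit <- tryCatch({
      if (model == "hyperbolic") {
        minpack.lm::nlsLM(y ~ P / (kd + P), data = d,
                          start = list(kd = kd0),
                          lower = c(kd = 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ P^h / (kd^h + P^h), data = d,
                          start = list(kd = kd0, h = 1),
                          lower = c(kd = 1e-9, h = 0.1),
                          upper = c(kd = Inf, h = 10),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(list(kd_apparent = NA_real_, hill_coefficient = NA_real_,
                residual_sse = NA_real_, converged = FALSE,
                model = model, n_points = length(conc)))
  }
  cf <- stats::coef(best$fit)
  list(kd_apparent = unname(cf["kd"]),
       hill_coefficient = if (model == "hill") unname(cf["h"]) else NA_real_,
       residual_sse = best$sse,
       converged = TRUE,
       model = model, n_points = length(conc))
}

#' Read a height map from a plain-text matrix
#'
#' Whitespace-separated numeric matrix of heights in nm, one image row
#' per line.
#'
#' @param path Input path.
#' @param pixel_size_nm Physical pixel size in nm (default 1).
#' @return A `height_map` list: `z` (matrix, nm), `pixel_size_nm`.
#' @export
read_height_map <- function(path, pixel_size_nm = 1) {
  z <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(z) <- NULL
  height_map(z, pixel_size_nm)
}

#' Construct a height map
#' @param z Numeric matrix of heights (nm), all finite.
#' @param pixel_size_nm Pixel size in nm, positive.
#' @return A `height_map` list.
#' @export
height_map <- function(z, pixel_size_nm = 1) {
  if (!is.matrix(z) || !is.numeric(z)) stop("z must be a numeric matrix")
  if (any(!is.finite(z))) stop("height map contains non-finite values")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  structure(list(z = z, pixel_size_nm = pixel_size_nm), class = "height_map")
}

# least-squares plane fit z ~ row + col; returns the levelled matrix
.level_plane <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  fit <- stats::lm.fit(cbind(1, rows, cols), as.vector(z))
  matrix(fit$residuals, nr, nc)
}

# 8-connected component labeling of a logical mask (two-pass union-find)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  next_label <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      neigh <- integer(0)
      if (i > 1L && mask[i - 1L, j]) neigh <- c(neigh, labels[i - 1L, j])
      if (j > 1L) {
        if (mask[i, j - 1L]) neigh <- c(neigh, labels[i, j - 1L])
        if (i > 1L && mask[i - 1L, j - 1L]) neigh <- c(neigh, labels[i - 1L, j - 1L])
        if (i < nr && mask[i + 1L, j - 1L]) neigh <- c(neigh, labels[i + 1L, j - 1L])
      }
      if (length(neigh) == 0L) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        labels[i, j] <- next_label
      } else {
        roots <- vapply(neigh, find, integer(1))
        r <- min(roots)
        labels[i, j] <- r
        for (x in roots) parent[x] <- r
      }
    }
  }
  if (next_label == 0L) return(labels)
  roots <- vapply(seq_len(next_label), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  nz <- labels > 0L
  labels[nz] <- relabel[labels[nz]]
  labels
}

#' Segment DNA(-protein) complexes in an AFM height map
#'
#' The map is levelled by subtracting a least-squares background plane,
#' then thresholded at `height_threshold_nm` above the background; the
#' 8-connected components with at least `min_area_px` pixels are the
#' complexes.
#'
#' @param map A `height_map`.
#' @param height_threshold_nm Threshold above the fitted background
#'   plane, nm (default 1).
#' @param min_area_px Minimum component area in pixels (default 4).
#' @param level Subtract the background plane first (default `TRUE`).
#' @return List with `complexes` (data frame: `complex_id`,
#'   `max_height_nm`, `area_px`), `labels` (integer matrix, 0 =
#'   background) and `z` (the levelled matrix).
#' @export
segment_complexes <- function(map, height_threshold_nm = 1, min_area_px = 4L,
                              level = TRUE) {
  z <- if (level) .level_plane(map$z) else map$z
  labels <- .label_components(z > height_threshold_nm)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (length(ids) == 0L) {
    return(list(complexes = data.frame(complex_id = integer(),
                                       max_height_nm = numeric(),
                                       area_px = integer()),
                labels = labels, z = z))
  }
  area <- tabulate(labels[labels > 0L], nbins = max(ids))
  keep <- which(area >= min_area_px)
  stats_df <- data.frame(
    complex_id = seq_along(keep),
    max_height_nm = vapply(keep, function(k) max(z[labels == k]), numeric(1)),
    area_px = area[keep])
  relabel <- integer(max(ids))
  relabel[keep] <- seq_along(keep)
  nz <- labels > 0L
  labels[nz] <- relabel[labels[nz]]
  list(complexes = stats_df, labels = labels, z = z)
}

# flood fill on `ok` starting from (i0, j0); returns TRUE if any visited
# pixel satisfies `target`
.reaches_taller <- function(ok, target, i0, j0) {
  nr <- nrow(ok); nc <- ncol(ok)
  visited <- matrix(FALSE, nr, nc)
  stack <- list(c(i0, j0))
  visited[i0, j0] <- TRUE
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (di in -1:1) for (dj in -1:1) {
      i <- p[1] + di; j <- p[2] + dj
      if (i < 1L || i > nr || j < 1L || j > nc) next
      if (visited[i, j] || !ok[i, j]) next
      if (target[i, j]) return(TRUE)
      visited[i, j] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, j)
    }
  }
  FALSE
}

#' Count foci within one segmented complex
#'
#' Foci are regional maxima of the levelled height inside the complex
#' mask with topographic prominence of at least `prominence_nm` (a
#' maximum is discarded when it connects to a strictly taller pixel
#' without descending more than `prominence_nm`) and pairwise separation
#' of at least `min_separation_px` (greedy suppression from the tallest
#' down). Every non-empty complex has at least one focus.
#'
#' @param z Levelled height matrix (from [segment_complexes()]).
#' @param labels Label matrix from [segment_complexes()].
#' @param complex_id Which complex to analyze.
#' @param prominence_nm Minimum prominence in nm (default 0.5).
#' @param min_separation_px Minimum center-to-center distance in pixels
#'   (default 3).
#' @return Integer foci count (>= 1).
#' @export
count_foci <- function(z, labels, complex_id, prominence_nm = 0.5,
                       min_separation_px = 3) {
  mask <- labels == complex_id
  if (!any(mask)) stop("complex ", complex_id, " is empty")
  nr <- nrow(z); nc <- ncol(z)
  idx <- which(mask, arr.ind = TRUE)
  # regional maxima: >= all 8 neighbours (outside-mask neighbours count via z)
  is_max <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    v <- z[i, j]
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
      if (z[ii, jj] > v) ok <- FALSE
    }
    is_max[k] <- ok
  }
  cand <- idx[is_max, , drop = FALSE]
  h <- z[cand]
  # deduplicate plateau maxima: same height within separation collapse later
  o <- order(-h)
  cand <- cand[o, , drop = FALSE]
  h <- h[o]
  # prominence: drop candidates that reach a strictly taller pixel while
  # staying above (candidate height - prominence), within the mask
  keep_prom <- logical(length(h))
  for (k in seq_along(h)) {
    if (k == 1L) { keep_prom[1] <- TRUE; next }  # global max always prominent
    ok <- mask & (z >= h[k] - prominence_nm)
    taller <- mask & (z > h[k])
    keep_prom[k] <- !.reaches_taller(ok, taller, cand[k, 1], cand[k, 2])
  }
  cand <- cand[keep_prom, , drop = FALSE]
  h <- h[keep_prom]
  # greedy non-maximum suppression by distance
  kept <- integer(0)
  for (k in seq_along(h)) {
    if (length(kept) == 0L) { kept <- k; next }
    dmin <- min(sqrt((cand[kept, 1] - cand[k, 1])^2 +
                     (cand[kept, 2] - cand[k, 2])^2))
    if (dmin >= min_separation_px) kept <- c(kept, k)
  }
  max(1L, length(kept))
}

#' Aggregate AFM complex statistics
#'
#' Bins per-complex maximum heights into the standard 0-2 / 2-4 / 4-6 /
#' >6 nm classes, reports the percentage per bin, the percentage of
#' complexes taller than `tall_cutoff_nm`, and (when foci counts are
#' given) the foci-count distribution.
#'
#' @param complexes Data frame from [segment_complexes()] (column
#'   `max_height_nm`), optionally with a `foci_count` column.
#' @param breaks Bin edges in nm (default `c(0, 2, 4, 6, Inf)`;
#'   right-open bins).
#' @param tall_cutoff_nm Tall-complex cutoff, nm (default 12).
#' @return List with `n_complexes`, `height_bins` (data frame `bin`,
#'   `n`, `percent`), `percent_above_cutoff`, `tall_cutoff_nm`,
#'   `foci_table` (or `NULL`), `mean_foci`. An empty population returns
#'   an empty report (no division by zero).
#' @export
afm_report <- function(complexes, breaks = c(0, 2, 4, 6, Inf),
                       tall_cutoff_nm = 12) {
  n <- nrow(complexes)
  labs <- paste0("[", breaks[-length(breaks)], ",",
                 ifelse(is.finite(breaks[-1]), breaks[-1], "Inf"), ")")
  if (n == 0L) {
    return(list(n_complexes = 0L,
                height_bins = data.frame(bin = labs, n = 0L, percent = NA_real_),
                percent_above_cutoff = NA_real_,
                tall_cutoff_nm = tall_cutoff_nm,
                foci_table = NULL, mean_foci = NA_real_))
  }
  h <- complexes$max_height_nm
  cut_ix <- findInterval(h, breaks, left.open = FALSE, rightmost.closed = FALSE)
  cut_ix[cut_ix < 1L] <- 1L
  cut_ix[cut_ix >= length(breaks)] <- length(breaks) - 1L
  counts <- tabulate(cut_ix, nbins = length(breaks) - 1L)
  foci_table <- NULL
  mean_foci <- NA_real_
  if ("foci_count" %in% names(complexes)) {
    foci_table <- as.data.frame(table(foci_count = complexes$foci_count),
                                stringsAsFactors = FALSE)
    names(foci_table)[2] <- "n"
    foci_table$percent <- 100 * foci_table$n / n
    mean_foci <- mean(complexes$foci_count)
  }
  list(n_complexes = n,
       height_bins = data.frame(bin = labs, n = counts,
                                percent = 100 * counts / n),
       percent_above_cutoff = 100 * mean(h > tall_cutoff_nm),
       tall_cutoff_nm = tall_cutoff_nm,
       foci_table = foci_table, mean_foci = mean_foci)
}

#' Full AFM quantification of a height map
#'
#' Convenience wrapper: segments complexes, counts foci per complex and
#' aggregates the report.
#'
#' @inheritParams segment_complexes
#' @inheritParams count_foci
#' @inheritParams afm_report
#' @return List with `complexes` (including `foci_count`) and `report`.
#' @export
quantify_afm <- function(map, height_threshold_nm = 1, min_area_px = 4L,
                         prominence_nm = 0.5, min_separation_px = 3,
                         breaks = c(0, 2, 4, 6, Inf), tall_cutoff_nm = 12,
                         level = TRUE) {
  seg <- segment_complexes(map, height_threshold_nm, min_area_px, level = level)
  cx <- seg$complexes
  if (nrow(cx) > 0L) {
    cx$foci_count <- vapply(cx$complex_id, function(id) {
      count_foci(seg$z, seg$labels, id, prominence_nm, min_separation_px)
    }, integer(1))
  } else {
    cx$foci_count <- integer(0)
  }
  list(complexes = cx, report = afm_report(cx, breaks, tall_cutoff_nm))
}
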