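#' Band-limited Patterson function by FFT
#'
#' Inverse Fourier synthesis of the intensities in a resolution band,
#' expanded to the full reciprocal sphere under Friedel and Laue symmetry.
#' F(000) is omitted, so the map has zero mean and the origin peak height
#' equals the sum of the band intensities.  Only Patterson-usable
#' coefficients are included: for mean-intensity data these are the
#' net-positive reflections.
#'
#' @param rs a [reflection_set()] with intensities (run
#'   [recover_intensities()] first for non-intensity provenances).
#' @param dmin,dmax resolution band in Angstrom (defaults 5 and 10).
#' @param grid_spacing target grid spacing in Angstrom; default `dmin / 4`,
#'   fine enough to localize peaks well inside the origin-exclusion radius.
#' @return An object of class `patterson_map`: 3-D array `values` (indexed
#'   from the cell origin), `cell`, `sg`, `band`, grid dimensions `dims`,
#'   and `origin_height`.
#' @export
compute_patterson <- function(rs, dmin = 5, dmax = 10, grid_spacing = NULL) {
  stopifnot(inherits(rs, "reflection_set"))
  if (is.null(rs$I)) stop("reflection set has no intensities; run recover_intensities()")
  if (is.null(grid_spacing)) grid_spacing <- dmin / 4
  use <- rs$d >= dmin & rs$d <= dmax & is.finite(rs$I)
  pos <- if (!is.null(rs$pos)) rs$pos else rs$I > 0
  use <- use & pos
  if (sum(use) < 30)
    stop(sprintf("only %d usable reflections in the %.1f-%.1f A band (need >= 30)",
                 sum(use), dmin, dmax))
  hkl <- rs$hkl[use, , drop = FALSE]
  I <- rs$I[use]

  dims <- vapply(c(rs$cell$a, rs$cell$b, rs$cell$c),
                 function(L) fft_friendly(ceiling(L / grid_spacing)), 0L)
  hmax <- apply(abs(hkl), 2, max)
  if (any(dims < 2 * hmax + 2)) dims <- pmax(dims, 2L * hmax + 2L)

  ex <- expand_hkl_laue(rs$sg, hkl)
  coef <- I[ex$parent]
  arr <- array(0 + 0i, dim = dims)
  idx <- sweep(ex$hkl, 2, dims, "%%") + 1
  arr[cbind(idx[, 1], idx[, 2], idx[, 3])] <- coef
  map <- Re(stats::fft(arr, inverse = TRUE)) / rs$cell$volume

  structure(list(values = map, cell = rs$cell, sg = rs$sg,
                 band = c(dmin = dmin, dmax = dmax), dims = dims,
                 origin_height = map[1, 1, 1]),
            class = "patterson_map")
}

#' @export
print.patterson_map <- function(x, ...) {
  cat(sprintf("Patterson map: %dx%dx%d grid, band %.1f-%.1f A, origin height %.4g\n",
              x$dims[1], x$dims[2], x$dims[3], x$band[1], x$band[2], x$origin_height))
  invisible(x)
}

## smallest 2,3,5-smooth integer >= n (fast FFT sizes)
fft_friendly <- function(n) {
  m <- as.integer(n)
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

## mean and sd of map values outside the origin-exclusion sphere
map_stats <- function(map, exclude_radius = 15) {
  g <- grid_frac(map$dims)
  d <- min_image_dist(map$cell, g)
  v <- as.numeric(map$values)[d >= exclude_radius]
  if (!length(v)) v <- as.numeric(map$values)
  c(mean = mean(v), sd = stats::sd(v))
}

## fractional coordinates of every grid point (array order)
grid_frac <- function(dims) {
  cbind(rep((seq_len(dims[1]) - 1) / dims[1], times = dims[2] * dims[3]),
        rep(rep((seq_len(dims[2]) - 1) / dims[2], each = dims[1]), times = dims[3]),
        rep((seq_len(dims[3]) - 1) / dims[3], each = dims[1] * dims[2]))
}

#' Pick symmetry-unique off-origin Patterson peaks
#'
#' Finds local maxima of the Patterson map (26-neighbour rule, periodic),
#' refines positions by quadratic interpolation, filters by minimum
#' origin distance (minimum-image) and minimum height as a percentage of
#' the origin peak, merges peaks closer than two grid points, and reduces
#' the survivors to symmetry-unique representatives under the Patterson
#' (Laue) symmetry.  Cells with any edge shorter than `min_dist` are
#' flagged pathological (most likely peptides) and yield no peaks.
#'
#' @param map a [compute_patterson()] result.
#' @param min_dist minimum distance from the origin in Angstrom (default 15).
#' @param min_height_pct minimum peak height as percent of the origin peak
#'   (default 16.8).
#' @param zscore_exclude radius (Angstrom) of the origin sphere excluded
#'   from the map statistics used for Z-scores; defaults to `min_dist`.
#' @return A data frame of class `patterson_peaks` with columns `u`, `v`,
#'   `w` (fractional coordinates), `orth_dist` (Angstrom), `height_pct`
#'   and `zscore`, sorted by descending height (ties broken
#'   lexicographically on the coordinates).  The attribute `status` is
#'   `"ok"` or `"pathological"`.
#' @export
pick_peaks <- function(map, min_dist = 15, min_height_pct = 16.8,
                       zscore_exclude = NULL) {
  stopifnot(inherits(map, "patterson_map"))
  if (is.null(zscore_exclude)) zscore_exclude <- min_dist
  empty <- data.frame(u = numeric(0), v = numeric(0), w = numeric(0),
                      orth_dist = numeric(0), height_pct = numeric(0),
                      zscore = numeric(0))
  class(empty) <- c("patterson_peaks", "data.frame")
  if (min(map$cell$a, map$cell$b, map$cell$c) < min_dist) {
    attr(empty, "status") <- "pathological"
    return(empty)
  }
  st <- map_stats(map, zscore_exclude)
  pk <- local_maxima(map$values)
  if (nrow(pk) == 0) { attr(empty, "status") <- "ok"; return(empty) }

  frac <- refine_quadratic(map$values, pk, map$dims)
  height <- pk[, 4]
  height_pct <- 100 * height / map$origin_height
  keep <- height_pct >= min_height_pct
  frac <- frac[keep, , drop = FALSE]; height <- height[keep]
  height_pct <- height_pct[keep]
  if (!nrow(frac)) { attr(empty, "status") <- "ok"; return(empty) }

  dist <- min_image_dist(map$cell, frac)
  keep <- dist >= min_dist
  frac <- frac[keep, , drop = FALSE]; height <- height[keep]
  height_pct <- height_pct[keep]; dist <- dist[keep]
  if (!nrow(frac)) { attr(empty, "status") <- "ok"; return(empty) }

  # symmetry-unique under the Laue (Patterson) group, then merge near-dups
  canon <- canonical_frac(map$sg, frac)
  tol <- 2 / min(map$dims)
  key <- apply(round(canon / tol), 1, paste, collapse = ",")
  ord <- order(-height, canon[, 1], canon[, 2], canon[, 3])
  first <- ord[!duplicated(key[ord])]

  out <- data.frame(u = canon[first, 1], v = canon[first, 2], w = canon[first, 3],
                    orth_dist = dist[first],
                    height_pct = height_pct[first],
                    zscore = if (st["sd"] > 0) (height[first] - st["mean"]) / st["sd"]
                             else rep(NA_real_, length(first)))
  out <- out[order(-out$height_pct, out$u, out$v, out$w), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("patterson_peaks", "data.frame")
  attr(out, "status") <- "ok"
  out
}

## periodic 26-neighbour local maxima; returns cbind(i, j, k, value)
local_maxima <- function(a) {
  d <- dim(a)
  sh <- function(x, s) {
    # cyclic shift of a 3-D array by s
    i1 <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
    i2 <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
    i3 <- ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1
    x[i1, i2, i3, drop = FALSE]
  }
  ismax <- array(TRUE, d)
  for (du in -1:1) for (dv in -1:1) for (dw in -1:1) {
    if (du == 0 && dv == 0 && dw == 0) next
    ismax <- ismax & (a > sh(a, c(du, dv, dw)))
  }
  idx <- which(ismax, arr.ind = TRUE)
  cbind(idx, a[idx])
}

## sub-grid peak positions: separable quadratic fit over +/-1 grid points
refine_quadratic <- function(a, pk, dims) {
  n <- nrow(pk)
  frac <- matrix(0, n, 3)
  for (r in seq_len(n)) {
    ijk <- pk[r, 1:3]
    off <- numeric(3)
    for (axis in 1:3) {
      m <- ijk; p <- ijk
      m[axis] <- ((ijk[axis] - 2) %% dims[axis]) + 1
      p[axis] <- (ijk[axis] %% dims[axis]) + 1
      fm <- a[m[1], m[2], m[3]]; f0 <- a[ijk[1], ijk[2], ijk[3]]
      fp <- a[p[1], p[2], p[3]]
      den <- fm - 2 * f0 + fp
      off[axis] <- if (den < 0) max(-0.5, min(0.5, 0.5 * (fm - fp) / den)) else 0
    }
    frac[r, ] <- (ijk - 1 + off) / dims
  }
  frac - floor(frac)
}

## canonical representative of fractional positions under Laue rotations:
## lexicographic minimum over images (mod 1, rounded for comparison)
canonical_frac <- function(sg, frac) {
  best <- frac - floor(frac)
  for (R in sg$laue) {
    cand <- t(R %*% t(frac))
    cand <- cand - floor(cand)
    cr <- round(cand, 6); br <- round(best, 6)
    swap <- (cr[, 1] < br[, 1]) |
      (cr[, 1] == br[, 1] & cr[, 2] < br[, 2]) |
      (cr[, 1] == br[, 1] & cr[, 2] == br[, 2] & cr[, 3] < br[, 3])
    best[swap, ] <- cand[swap, , drop = FALSE]
  }
  best
}

#' Z-score test for a Patterson peak
#'
#' TRUE when the peak's Z-score (standard deviations above the map mean,
#' with the origin sphere excluded from the statistics) reaches the
#' threshold.  The default threshold 11.36 is the calibrated value for a
#' 5-15 Angstrom Patterson band.
#'
#' @param map a [compute_patterson()] result (used to detect degenerate,
#'   constant maps).
#' @param peak one row of a [pick_peaks()] data frame.
#' @param t Z-score threshold.
#' @return logical; FALSE (with a warning) when the map variance is zero.
#' @export
zscore_threshold <- function(map, peak, t = 11.36) {
  if (stats::sd(as.numeric(map$values)) == 0 || is.na(peak$zscore)) {
    warning("constant Patterson map: Z-score undefined")
    return(FALSE)
  }
  peak$zscore >= t
}

#' Filter coiled-coil-like peak ladders
#'
#' Removes runs of three or more peaks whose origin distances increase by
#' a near-constant short spacing in the helical-repeat window, the
#' Patterson signature of coiled coils and amyloid repeats.
#'
#' @param peaks a [pick_peaks()] data frame.
#' @param spacing_window allowed successive-spacing range in Angstrom
#'   (default 4.5 to 6.0).
#' @param spread_tol maximum spread of the spacings within one run
#'   (Angstrom) for it to count as a common spacing.
#' @return The filtered peak data frame (attributes preserved).
#' @export
coiled_coil_filter <- function(peaks, spacing_window = c(4.5, 6.0),
                               spread_tol = 0.8) {
  if (nrow(peaks) < 3) return(peaks)
  ord <- order(peaks$orth_dist)
  d <- peaks$orth_dist[ord]
  gaps <- diff(d)
  inwin <- gaps >= spacing_window[1] & gaps <= spacing_window[2]
  drop <- logical(length(d))
  i <- 1
  while (i <= length(gaps)) {
    if (!inwin[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= length(gaps) && inwin[j + 1] &&
           diff(range(gaps[i:(j + 1)])) <= spread_tol) j <- j + 1
    if (j > i || (j == i && FALSE)) {
      # run of >= 2 qualifying gaps -> >= 3 peaks
      drop[i:(j + 1)] <- TRUE
    }
    i <- j + 1
  }
  keep_idx <- ord[!drop]
  out <- peaks[sort(keep_idx), , drop = FALSE]
  out <- out[order(-out$height_pct, out$u, out$v, out$w), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(peaks)
  attr(out, "status") <- attr(peaks, "status")
  out
}
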