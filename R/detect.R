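#' Detection configuration
#'
#' All thresholds of the TNCS detection pipeline with their calibrated
#' defaults: Patterson band 5-10 Angstrom, 15 Angstrom origin-distance
#' threshold, 16.8 percent peak threshold, 8 percent noise floor for the
#' commensurate analysis, 3 Angstrom resolution truncation, 80 percent
#' completeness warning level and 10 degree coordinate-analysis tolerance.
#'
#' @param pmin,pmax Patterson resolution band (Angstrom).
#' @param origin_dist minimum peak distance from the origin (Angstrom).
#' @param peak_frac minimum peak height, percent of the origin peak.
#' @param zscore_t Z-score threshold option (calibrated for a 5-15
#'   Angstrom band).
#' @param noise_floor commensurate-analysis noise floor, percent of the
#'   origin peak.
#' @param dmin_truncate high-resolution truncation (Angstrom).
#' @param completeness_warn completeness fraction below which a warning is
#'   issued.
#' @param r_deg angular tolerance for the coordinate classifier (degrees).
#' @param max_order maximum commensurate order considered.
#' @param fourier_cut strong-term cut, multiples of the median absolute
#'   low-order Fourier magnitude.
#' @param match_tol predicted-peak matching tolerance (fractional).
#' @param coiled_coil_window helical-repeat spacing window (Angstrom).
#' @param seed integer seed recorded in reports.
#' @return Object of class `tncs_config`.
#' @export
tncs_config <- function(pmin = 5, pmax = 10, origin_dist = 15,
                        peak_frac = 16.8, zscore_t = 11.36, noise_floor = 8,
                        dmin_truncate = 3, completeness_warn = 0.8,
                        r_deg = 10, max_order = 8, fourier_cut = 3,
                        match_tol = 0.02, coiled_coil_window = c(4.5, 6.0),
                        seed = 1) {
  stopifnot(pmax > pmin, pmin > 0, origin_dist > 0,
            peak_frac > 0, peak_frac <= 100,
            noise_floor > 0, noise_floor <= 100, max_order >= 2)
  structure(as.list(environment()), class = "tncs_config")
}

## smallest min-image difference between a fractional vector and any Laue
## image of another; returns max-axis deviation
frac_mismatch <- function(sg, a, b) {
  best <- Inf
  for (R in sg$laue) {
    d <- a - as.numeric(R %*% b)
    best <- min(best, max(abs(d - round(d))))
  }
  best
}

#' Commensurate-order analysis of the noise-reduced Patterson
#'
#' Zeroes all map values below the noise floor (a percentage of the origin
#' peak), transforms the noise-reduced map to reciprocal space, and reads
#' commensurate modulation off the strong low-order Fourier terms.  Peak
#' positions of the floored map that snap to fractions m/n of the cell
#' (within tolerance) generate pseudo-cell hypotheses of order n with
#' predicted peaks at every multiple of the basic vector; a hypothesis is
#' kept when a strong Fourier term is consistent with the basic vector and
#' at least half of the predicted peaks (rounded up) are present above
#' the noise floor.
#'
#' @param map a [compute_patterson()] result.
#' @param noise_floor_pct noise floor, percent of the origin height.
#' @param max_order maximum order considered.
#' @param fourier_cut strong-term threshold, multiples of the median
#'   absolute Fourier magnitude over indices with max |index| <= 8.
#' @param match_tol fractional tolerance for snapping and peak matching.
#' @return List of candidates, each a list with `n`, `t` (basic fractional
#'   vector), `predicted` (matrix of predicted peak positions, one per
#'   multiple) and `coverage` (fraction of predicted peaks observed above
#'   the noise floor).  Ordered by decreasing order, then coverage.
#' @export
commensurate_orders <- function(map, noise_floor_pct = 8, max_order = 8,
                                fourier_cut = 3, match_tol = 0.02) {
  stopifnot(inherits(map, "patterson_map"))
  nf <- noise_floor_pct / 100 * map$origin_height
  fl <- map$values
  fl[fl < nf] <- 0

  # strong low-order Fourier terms of the noise-reduced map
  Tc <- stats::fft(fl)
  dims <- map$dims
  lo <- 8
  idx <- as.matrix(expand.grid(u = -lo:lo, v = -lo:lo, w = -lo:lo))
  idx <- idx[rowSums(abs(idx)) > 0, , drop = FALSE]
  ii <- sweep(idx, 2, dims, "%%") + 1
  mag <- Mod(Tc[cbind(ii[, 1], ii[, 2], ii[, 3])])
  cut <- fourier_cut * stats::median(mag)
  strong <- idx[mag >= cut, , drop = FALSE]
  if (!nrow(strong)) return(list())

  # off-origin maxima of the floored map (candidate modulation peaks)
  pk <- local_maxima(fl)
  if (nrow(pk) == 0) return(list())
  frac <- sweep(pk[, 1:3, drop = FALSE] - 1, 2, dims, "/")
  dist <- min_image_dist(map$cell, frac)
  gmin <- 2 * max(1 / dims[1], 1 / dims[2], 1 / dims[3])
  off <- dist > gmin * min(map$cell$a, map$cell$b, map$cell$c)
  frac <- frac[off, , drop = FALSE]
  if (!nrow(frac)) return(list())

  cands <- list()
  seen <- character(0)
  for (qi in seq_len(nrow(frac))) {
    q <- frac[qi, ]
    for (n in seq(max_order, 2)) {
      p <- round(n * q)
      if (max(abs(n * q - p)) > match_tol * n) next
      g <- Reduce(gcd2, c(abs(p), n))
      neff <- n %/% g
      if (neff < 2) next
      # cyclic group generated by the snapped peak
      members <- outer(seq_len(neff - 1), (p %/% g) / neff)
      members <- members - floor(members)
      # basic vector: member closest to the origin, ties lexicographic
      ml <- min_image_dist(map$cell, members)
      ord <- order(ml, members[, 1], members[, 2], members[, 3])
      tb <- members[ord[1], ]
      key <- paste(neff, paste(sprintf("%.4f", sort(ml)), collapse = ","),
                   paste(sprintf("%.4f", canonical_frac(map$sg, matrix(tb, 1))), collapse = ","))
      if (key %in% seen) next
      # Fourier consistency: some strong term must index the pseudo-cell
      ht <- strong %*% tb
      if (!any(abs(ht - round(ht)) < 0.1 & rowSums(abs(strong)) > 0)) next
      # predicted-peak support above the noise floor
      found <- vapply(seq_len(nrow(members)), function(k) {
        any(apply(frac, 1, function(f) frac_mismatch(map$sg, f, members[k, ]) <= match_tol))
      }, TRUE)
      if (sum(found) < ceiling((neff - 1) / 2)) next
      seen <- c(seen, key)
      cands <- c(cands, list(list(n = neff, t = tb, predicted = members,
                                  coverage = mean(found))))
    }
  }
  ord <- order(-vapply(cands, `[[`, 0, "n"), -vapply(cands, `[[`, 0, "coverage"))
  cands[ord]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Rank TNCS hypotheses from peaks and commensurate candidates
#'
#' Builds the ranked hypothesis list: commensurate hypotheses that predict
#' the top-ranked Patterson peak first, remaining commensurate hypotheses
#' next, then an independent order-2 hypothesis per surviving peak ordered
#' by peak height, and always terminated by the no-TNCS (n = 1)
#' hypothesis.  Ties are broken by predicted-peak coverage.  With no
#' surviving peaks the status is "tncs-not-indicated".
#'
#' @param peaks a [pick_peaks()] data frame (after any coiled-coil
#'   filtering).
#' @param cands [commensurate_orders()] output.
#' @param sg the [space_group()] (for symmetry-aware peak matching).
#' @param config a [tncs_config()].
#' @return Object of class `tncs_report`: `status`, `hypotheses` (list of
#'   entries with `hyp`, `evidence`), `peaks`.
#' @export
rank_hypotheses <- function(peaks, cands, sg, config = tncs_config()) {
  status <- attr(peaks, "status")
  if (identical(status, "pathological"))
    return(structure(list(status = "pathological", hypotheses = list(),
                          peaks = peaks, config = config), class = "tncs_report"))
  if (nrow(peaks) == 0)
    return(structure(list(status = "tncs-not-indicated", hypotheses = list(),
                          peaks = peaks, config = config), class = "tncs_report"))
  top <- as.numeric(peaks[1, c("u", "v", "w")])
  entries <- list()
  seen <- character(0)
  keyof <- function(n, t) paste(n, paste(sprintf("%.3f", canonical_frac(sg, matrix(t, 1))), collapse = ","))

  if (length(cands)) {
    predicts_top <- vapply(cands, function(cc)
      any(apply(cc$predicted, 1, function(m) frac_mismatch(sg, top, m) <= config$match_tol)),
      TRUE)
    cov <- vapply(cands, `[[`, 0, "coverage")
    nn <- vapply(cands, `[[`, 0, "n")
    ord <- order(-predicts_top, -nn, -cov)
    for (k in ord) {
      cc <- cands[[k]]
      key <- keyof(cc$n, cc$t)
      if (key %in% seen) next
      seen <- c(seen, key)
      entries <- c(entries, list(list(
        hyp = tncs_hypothesis(cc$n, cc$t),
        evidence = list(kind = "commensurate", coverage = cc$coverage,
                        predicts_top = predicts_top[k],
                        top_height_pct = peaks$height_pct[1]))))
    }
  }
  for (r in seq_len(nrow(peaks))) {
    t2 <- as.numeric(peaks[r, c("u", "v", "w")])
    key <- keyof(2L, t2)
    if (key %in% seen) next
    seen <- c(seen, key)
    entries <- c(entries, list(list(
      hyp = tncs_hypothesis(2L, t2),
      evidence = list(kind = "independent-pair",
                      height_pct = peaks$height_pct[r],
                      zscore = peaks$zscore[r]))))
  }
  entries <- c(entries, list(list(hyp = tncs_hypothesis(1L),
                                  evidence = list(kind = "no-tncs"))))
  structure(list(status = "hypotheses", hypotheses = entries, peaks = peaks,
                 config = config), class = "tncs_report")
}

#' @export
print.tncs_report <- function(x, ...) {
  cat("TNCS detection report - status:", x$status, "\n")
  if (x$status == "hypotheses") {
    for (k in seq_along(x$hypotheses)) {
      h <- x$hypotheses[[k]]$hyp
      ev <- x$hypotheses[[k]]$evidence
      if (h$n == 1) cat(sprintf("%2d. no TNCS\n", k))
      else cat(sprintf("%2d. TNCS_%d t=(%.3f,%.3f,%.3f) [%s]\n",
                       k, h$n, h$t[1], h$t[2], h$t[3], ev$kind))
    }
  }
  invisible(x)
}

#' End-to-end TNCS detection
#'
#' The full detection pipeline: intensity recovery, band-limited Patterson
#' synthesis, peak picking with distance and height thresholds plus the
#' coiled-coil cluster filter, commensurate-order analysis of the
#' noise-reduced map, and hypothesis ranking.  A completeness check warns
#' (but does not fail) below the configured fraction.
#'
#' @param rs a [reflection_set()].
#' @param config a [tncs_config()].
#' @return A `tncs_report` (see [rank_hypotheses()]); pathological cells
#'   are reported as status `"pathological"`.
#' @export
detect_tncs <- function(rs, config = tncs_config()) {
  stopifnot(inherits(rs, "reflection_set"))
  if (is.null(rs$I) || is.null(rs$pos)) rs <- recover_intensities(rs)
  comp <- completeness(rs, config$pmin, config$pmax)
  if (!is.na(comp) && comp < config$completeness_warn)
    warning(sprintf("data only %.1f%% complete in the %g-%g A band; detection is less reliable",
                    100 * comp, config$pmin, config$pmax))
  if (min(rs$cell$a, rs$cell$b, rs$cell$c) < config$origin_dist) {
    empty <- data.frame(u = numeric(0), v = numeric(0), w = numeric(0),
                        orth_dist = numeric(0), height_pct = numeric(0),
                        zscore = numeric(0))
    attr(empty, "status") <- "pathological"
    return(structure(list(status = "pathological", hypotheses = list(),
                          peaks = empty, config = config,
                          completeness = comp), class = "tncs_report"))
  }
  map <- compute_patterson(rs, config$pmin, config$pmax)
  peaks <- pick_peaks(map, min_dist = config$origin_dist,
                      min_height_pct = config$peak_frac)
  peaks <- coiled_coil_filter(peaks, spacing_window = config$coiled_coil_window)
  cands <- if (nrow(peaks) > 0)
    commensurate_orders(map, config$noise_floor, config$max_order,
                        config$fourier_cut, config$match_tol)
  else list()
  rep <- rank_hypotheses(peaks, cands, rs$sg, config)
  rep$completeness <- comp
  rep
}

#' Serialize a detection report to JSON
#'
#' Machine-readable report embedding the resolved configuration and the
#' package version.
#'
#' @param report a `tncs_report`.
#' @param path optional output file; when NULL the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  obj <- list(
    schema = "tncs-report/1",
    package_version = as.character(utils::packageVersion("tncscout")),
    status = report$status,
    completeness = report$completeness,
    config = unclass(report$config),
    peaks = report$peaks,
    hypotheses = lapply(report$hypotheses, function(e) list(
      n = e$hyp$n, t = e$hyp$t, rot_deg = e$hyp$rot_deg,
      rmsd = e$hyp$rmsd, evidence = e$evidence)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
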