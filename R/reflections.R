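#' Reflection set
#'
#' Container for merged reflection data: unit cell, space group, Miller
#' indices reduced to a canonical reciprocal-space asymmetric unit, and
#' intensity data with provenance.
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param I mean intensities (any scale), or NULL when amplitudes or
#'   anomalous intensities are supplied instead.
#' @param sigI intensity uncertainties (>= 0), or NULL.
#' @param Iplus,sigIplus,Iminus,sigIminus anomalous (Friedel-separated)
#'   intensities; NA marks an absent mate.
#' @param F,sigF structure-factor amplitudes.
#' @param provenance one of `"mean-intensity"`, `"anomalous-intensity"`,
#'   `"amplitude-french-wilson"`, `"amplitude-raw"`.  Inferred from the
#'   supplied columns when missing: mean I, then anomalous I, then F
#'   (amplitudes default to `"amplitude-french-wilson"`).
#' @return An object of class `reflection_set` with fields `cell`, `sg`,
#'   `hkl`, `I`, `sigI`, `d` (resolution per reflection, Angstrom),
#'   `provenance`, and any anomalous/amplitude columns given.  The logical
#'   field `pos` (set by [recover_intensities()]) marks reflections usable
#'   as Patterson coefficients.
#' @export
reflection_set <- function(cell, sg, hkl, I = NULL, sigI = NULL,
                           Iplus = NULL, sigIplus = NULL,
                           Iminus = NULL, sigIminus = NULL,
                           F = NULL, sigF = NULL, provenance = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "integer"
  red <- reduce_hkl(sg, hkl)
  key <- paste(red[, 1], red[, 2], red[, 3])
  if (anyDuplicated(key))
    stop("hkl not unique after reduction to the asymmetric unit")
  if (is.null(provenance)) {
    provenance <- if (!is.null(I)) "mean-intensity"
    else if (!is.null(Iplus) || !is.null(Iminus)) "anomalous-intensity"
    else if (!is.null(F)) "amplitude-french-wilson"
    else stop("no intensity or amplitude data supplied")
  }
  provenance <- match.arg(provenance, c("mean-intensity", "anomalous-intensity",
                                        "amplitude-french-wilson", "amplitude-raw"))
  if (!is.null(sigI) && any(sigI < 0, na.rm = TRUE))
    stop("sigI must be non-negative")
  rs <- structure(list(
    cell = cell, sg = sg, hkl = red,
    I = I, sigI = sigI,
    Iplus = Iplus, sigIplus = sigIplus, Iminus = Iminus, sigIminus = sigIminus,
    F = F, sigF = sigF,
    d = d_spacing(cell, red),
    provenance = provenance,
    pos = NULL), class = "reflection_set")
  rs
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("Reflection set: %d unique reflections, %.2f-%.2f A, %s, provenance %s\n",
              nrow(x$hkl), max(x$d), min(x$d), x$sg$symbol, x$provenance))
  invisible(x)
}

#' Generate the complete unique reflection list for a resolution shell
#'
#' Enumerates all Miller indices with `dmin <= d <= dmax`, reduced to the
#' canonical asymmetric unit of reciprocal space under the Laue group.
#' (0,0,0) is excluded.
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @param dmin high-resolution limit (Angstrom).
#' @param dmax low-resolution limit (Angstrom), default infinite.
#' @return m x 3 integer matrix of unique Miller indices.
#' @export
generate_hkl <- function(cell, sg, dmin, dmax = Inf) {
  stopifnot(dmin > 0)
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / dmin) + 1L
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                             k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  d <- d_spacing(cell, g)
  g <- g[d >= dmin & d <= dmax, , drop = FALSE]
  red <- reduce_hkl(sg, g)
  red <- red[!duplicated(paste(red[, 1], red[, 2], red[, 3])), , drop = FALSE]
  storage.mode(red) <- "integer"
  red
}

#' Truncate a reflection set at a high-resolution limit
#'
#' @param rs a [reflection_set()].
#' @param dmin high-resolution cutoff in Angstrom (default 3.0); reflections
#'   with `d < dmin` are removed.
#' @return The truncated reflection set, with attributes `n_before` and
#'   `n_after` recording the reflection counts.
#' @export
truncate_resolution <- function(rs, dmin = 3.0) {
  stopifnot(inherits(rs, "reflection_set"), dmin > 0)
  keep <- rs$d >= dmin
  if (!any(keep))
    stop(sprintf("no reflections at or below %.2f A resolution", dmin))
  out <- subset_reflections(rs, keep)
  attr(out, "n_before") <- length(keep)
  attr(out, "n_after") <- sum(keep)
  out
}

## subset every per-reflection column
subset_reflections <- function(rs, keep) {
  per <- c("I", "sigI", "Iplus", "sigIplus", "Iminus", "sigIminus",
           "F", "sigF", "d", "pos")
  rs$hkl <- rs$hkl[keep, , drop = FALSE]
  for (f in per) if (!is.null(rs[[f]])) rs[[f]] <- rs[[f]][keep]
  rs
}

#' Completeness of a reflection set in a resolution shell
#'
#' Fraction of theoretically measurable unique reflections in
#' `[dmin, dmax]` that are present in the set.
#'
#' @param rs a [reflection_set()].
#' @param dmin,dmax resolution shell limits in Angstrom, `dmax > dmin`.
#' @return Fraction in \[0, 1\].
#' @export
completeness <- function(rs, dmin, dmax) {
  stopifnot(dmax > dmin, dmin > 0)
  full <- generate_hkl(rs$cell, rs$sg, dmin, dmax)
  if (nrow(full) == 0) return(NA_real_)
  obs <- rs$hkl[rs$d >= dmin & rs$d <= dmax, , drop = FALSE]
  have <- paste(obs[, 1], obs[, 2], obs[, 3])
  want <- paste(full[, 1], full[, 2], full[, 3])
  mean(want %in% have)
}

#' Recover working intensities according to data provenance
#'
#' Applies the provenance-specific rules for obtaining intensities used in
#' Patterson and likelihood calculations:
#' \describe{
#'   \item{mean-intensity}{all reflections retained; only net-positive
#'     intensities are flagged for Patterson use.}
#'   \item{anomalous-intensity}{the mean intensity is the unweighted average
#'     of the Friedel mates, or the singleton when only one is present.}
#'   \item{amplitude-french-wilson}{the French-Wilson transformation is
#'     reversed by numerical inversion of the posterior-mean amplitude
#'     mapping (bisection per reflection).}
#'   \item{amplitude-raw}{intensity is the squared amplitude; amplitudes
#'     stored as zero (negative experimental intensities) give I = 0.}
#' }
#'
#' @param rs a [reflection_set()].
#' @return The reflection set with `I` filled in, `pos` flagging
#'   Patterson-usable reflections, and provenance preserved.
#' @export
recover_intensities <- function(rs) {
  stopifnot(inherits(rs, "reflection_set"))
  switch(rs$provenance,
    "mean-intensity" = {
      if (is.null(rs$I)) stop("provenance mean-intensity but no I column")
      rs$pos <- rs$I > 0
    },
    "anomalous-intensity" = {
      ip <- rs$Iplus; im <- rs$Iminus
      if (is.null(ip) && is.null(im)) stop("no anomalous intensity columns")
      if (is.null(ip)) ip <- rep(NA_real_, nrow(rs$hkl))
      if (is.null(im)) im <- rep(NA_real_, nrow(rs$hkl))
      rs$I <- ifelse(is.na(ip), im, ifelse(is.na(im), ip, (ip + im) / 2))
      sp <- if (is.null(rs$sigIplus)) rep(NA_real_, nrow(rs$hkl)) else rs$sigIplus
      sm <- if (is.null(rs$sigIminus)) rep(NA_real_, nrow(rs$hkl)) else rs$sigIminus
      rs$sigI <- ifelse(is.na(sp), sm,
                        ifelse(is.na(sm), sp, sqrt(sp^2 + sm^2) / 2))
      rs$pos <- rs$I > 0
    },
    "amplitude-french-wilson" = {
      if (is.null(rs$F)) stop("provenance amplitude-french-wilson but no F column")
      sigI <- rs$sigI
      if (is.null(sigI)) {
        # error propagation sig(I) ~ 2 F sig(F); floor keeps inversion stable
        sF <- if (is.null(rs$sigF)) 0.1 * rs$F else rs$sigF
        sigI <- pmax(2 * rs$F * sF, 1e-6 * mean(rs$F^2))
      }
      S <- wilson_mean_by_bin(rs$d, rs$F^2)
      rs$I <- french_wilson_reverse(rs$F, sigI, S)
      rs$sigI <- sigI
      rs$pos <- rs$I > 0
    },
    "amplitude-raw" = {
      if (is.null(rs$F)) stop("provenance amplitude-raw but no F column")
      rs$I <- rs$F^2
      if (!is.null(rs$sigF)) rs$sigI <- 2 * rs$F * rs$sigF
      rs$pos <- rs$I > 0
    },
    stop("provenance missing"))
  rs
}

## per-reflection Wilson mean intensity from binned averages (20 bins in
## 1/d^3, equal-volume)
wilson_mean_by_bin <- function(d, I, nbins = 20) {
  s3 <- 1 / d^3
  br <- stats::quantile(s3, probs = seq(0, 1, length.out = nbins + 1))
  br[1] <- br[1] - 1e-9; br[nbins + 1] <- br[nbins + 1] + 1e-9
  bin <- cut(s3, breaks = unique(br), include.lowest = TRUE)
  mu <- tapply(I, bin, mean)
  pmax(as.numeric(mu[bin]), 1e-12 * mean(I))
}

#' Forward French-Wilson posterior-mean amplitude (acentric)
#'
#' Given a measured intensity with Gaussian error and a Wilson (exponential)
#' prior of mean `S`, the posterior of the true intensity J is a normal
#' truncated at zero with location `I - sig^2/S` and scale `sig`; the
#' French-Wilson amplitude is the posterior mean of sqrt(J), evaluated here
#' by fixed-grid quadrature.
#'
#' @param I measured intensities (may be negative).
#' @param sig intensity standard deviations (> 0).
#' @param S Wilson prior mean intensity, scalar or per reflection.
#' @param ngrid number of quadrature nodes.
#' @return Posterior-mean amplitudes, same length as `I`.
#' @export
french_wilson_forward <- function(I, sig, S, ngrid = 801) {
  n <- max(length(I), length(sig), length(S))
  I <- rep_len(I, n); sig <- rep_len(sig, n); S <- rep_len(S, n)
  mu <- I - sig^2 / S               # truncated-normal location
  hi <- pmax(mu, 0) + 10 * sig
  u <- seq(0, 1, length.out = ngrid)
  J <- outer(hi, u)                  # n x ngrid grid on [0, hi]
  w <- exp(-(J - mu)^2 / (2 * sig^2))
  # trapezoid weights on a uniform grid
  tw <- rep(1, ngrid); tw[c(1, ngrid)] <- 0.5
  num <- (sqrt(J) * w) %*% tw
  den <- w %*% tw
  as.numeric(num / den)
}

#' Reverse the French-Wilson transformation
#'
#' Numerically inverts [french_wilson_forward()] per reflection: finds the
#' measured intensity whose posterior-mean amplitude equals the stored
#' amplitude, by vectorized bisection (relative tolerance 1e-8).  The
#' mapping is strictly increasing in I, so the root is unique.
#'
#' @param F stored French-Wilson amplitudes (>= 0).
#' @param sig intensity standard deviations used in the forward transform.
#' @param S Wilson prior mean intensity, scalar or per reflection.
#' @return Recovered measured intensities.
#' @export
french_wilson_reverse <- function(F, sig, S) {
  n <- max(length(F), length(sig), length(S))
  F <- rep_len(F, n); sig <- rep_len(sig, n); S <- rep_len(S, n)
  lo <- F^2 - 12 * sig
  hi <- F^2 + 12 * sig
  # expand bounds where needed
  for (i in 1:8) {
    flo <- french_wilson_forward(lo, sig, S)
    bad <- flo > F
    if (!any(bad)) break
    lo[bad] <- lo[bad] - 10 * sig[bad]
  }
  for (i in 1:8) {
    fhi <- french_wilson_forward(hi, sig, S)
    bad <- fhi < F
    if (!any(bad)) break
    hi[bad] <- hi[bad] + 10 * sig[bad]
  }
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    fm <- french_wilson_forward(mid, sig, S)
    up <- fm < F
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < 1e-8 * max(1, max(abs(hi)))) break
  }
  (lo + hi) / 2
}
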