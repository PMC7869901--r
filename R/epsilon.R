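#' TNCS hypothesis
#'
#' Parameters of a translational-noncrystallographic-symmetry model: the
#' order n (n = 1 is the no-TNCS hypothesis), the basic fractional
#' translation, a small rotational perturbation between copies, the TNCS
#' r.m.s.d. (random coordinate differences between copies, Angstrom) and
#' the molecular radius governing the rotational interference falloff.
#'
#' @param n integer TNCS order >= 1.
#' @param t basic fractional translation (length 3); ignored for n = 1.
#' @param rot_deg rotational perturbation angle in degrees.
#' @param rot_axis rotation axis (orthogonal frame).
#' @param rmsd TNCS r.m.s.d. sigma-Delta in Angstrom (>= 0).
#' @param r_mol molecular radius in Angstrom (> 0).
#' @return Object of class `tncs_hypothesis`.
#' @export
tncs_hypothesis <- function(n, t = c(0, 0, 0), rot_deg = 0,
                            rot_axis = c(0, 0, 1), rmsd = 0, r_mol = 12) {
  if (n < 1) stop("TNCS order n must be >= 1")
  if (rmsd < 0) stop("rmsd must be >= 0")
  if (r_mol <= 0) stop("r_mol must be > 0")
  structure(list(n = as.integer(n), t = as.numeric(t), rot_deg = rot_deg,
                 rot_axis = rot_axis, rmsd = rmsd, r_mol = r_mol),
            class = "tncs_hypothesis")
}

#' @export
print.tncs_hypothesis <- function(x, ...) {
  if (x$n == 1) cat("TNCS hypothesis: no TNCS (n = 1)\n")
  else cat(sprintf("TNCS hypothesis: order %d, t=(%.3f,%.3f,%.3f), rot %.2f deg, rmsd %.2f A\n",
                   x$n, x$t[1], x$t[2], x$t[3], x$rot_deg, x$rmsd))
  invisible(x)
}

#' TNCS expected-intensity (epsilon) factors
#'
#' Per-reflection expected-intensity factors for a TNCS hypothesis of
#' order n with basic translation t:
#' `g(h) = n + 2 * sum_m (n - m) * rho(h)^m * cos(2 pi m h.t_s)`,
#' averaged over the distinct symmetry images t_s of t under the
#' rotational parts of the space group (modulations from very different
#' symmetry images tend to cancel).  The damping `rho(h)` in \[0, 1\]
#' combines a coordinate-difference falloff
#' `exp(-(2 pi^2 / 3) * rmsd^2 / d^2)` and the spherical-interference
#' (G-function) falloff for the rotational perturbation,
#' `G(2 pi R_mol |q|)` with `G(x) = 3 (sin x - x cos x) / x^3` and q the
#' reciprocal-space offset produced by the rotation.  Factors are
#' normalized to unit mean over the reflection set.
#'
#' @param rs a [reflection_set()] (supplies hkl, cell, space group).
#' @param hyp a [tncs_hypothesis()].
#' @param dmin,dmax optional resolution band; default uses every
#'   reflection in the set.
#' @param rho optional fixed damping value overriding the model (used in
#'   closed-form checks).
#' @return Object of class `epsilon_factors`: `eps` (normalized factors),
#'   `hkl`, `d`, `band` and the hypothesis.
#' @export
epsilon_factors <- function(rs, hyp, dmin = NULL, dmax = NULL, rho = NULL) {
  stopifnot(inherits(rs, "reflection_set"), inherits(hyp, "tncs_hypothesis"))
  keep <- rep(TRUE, nrow(rs$hkl))
  if (!is.null(dmin)) keep <- keep & rs$d >= dmin
  if (!is.null(dmax)) keep <- keep & rs$d <= dmax
  hkl <- rs$hkl[keep, , drop = FALSE]
  d <- rs$d[keep]
  if (!nrow(hkl)) stop("no reflections in the requested band")
  g <- epsilon_raw(hkl, d, rs$cell, rs$sg, hyp, rho)
  structure(list(eps = g / mean(g), hkl = hkl, d = d,
                 band = c(dmin = if (is.null(dmin)) min(d) else dmin,
                          dmax = if (is.null(dmax)) max(d) else dmax),
                 hyp = hyp),
            class = "epsilon_factors")
}

## unnormalized expected-intensity factors
epsilon_raw <- function(hkl, d, cell, sg, hyp, rho = NULL) {
  n <- hyp$n
  if (n == 1) return(rep(1, nrow(hkl)))
  R_rot <- rotation_matrix(hyp$rot_axis, hyp$rot_deg)
  # distinct symmetry images of t under the rotational parts
  timgs <- unique(t(vapply(sg$ops, function(op) round(op$R %*% hyp$t, 9), numeric(3))))
  g <- numeric(nrow(hkl))
  for (si in seq_len(nrow(timgs))) {
    ts <- timgs[si, ]
    if (is.null(rho)) {
      s <- hkl %*% cell$frac                      # scattering vectors, A^-1
      q <- s %*% (diag(3) - R_rot)                # reciprocal offset from rotation
      x <- 2 * pi * hyp$r_mol * sqrt(rowSums(q^2))
      Grot <- ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
      Grot <- pmin(pmax(Grot, 0), 1)
      rho_h <- Grot * exp(-(2 * pi^2 / 3) * hyp$rmsd^2 / d^2)
    } else rho_h <- rep(rho, nrow(hkl))
    gs <- rep(as.numeric(n), nrow(hkl))
    ht <- drop(hkl %*% ts)
    for (m in seq_len(n - 1))
      gs <- gs + 2 * (n - m) * rho_h^m * cos(2 * pi * m * ht)
    g <- g + gs
  }
  pmax(g / nrow(timgs), 0)
}

#' @export
print.epsilon_factors <- function(x, ...) {
  cat(sprintf("Epsilon factors: %d reflections, band %.1f-%.1f A, sigma1^2 = %.4f\n",
              length(x$eps), x$band[1], x$band[2], eps_tncs(x)))
  invisible(x)
}

#' eps-TNCS modulation statistic
#'
#' The variance of the normalized epsilon factors about 1,
#' `sigma_1^2 = mean((eps - 1)^2)`: zero for unmodulated data, n - 1 for
#' ideal commensurate TNCS of order n with balanced reflection classes,
#' and bounded by `(n/2)^2 + (n/2 - 1)^2`.
#'
#' @param eps an [epsilon_factors()] object or a numeric vector of
#'   normalized epsilon factors.
#' @return sigma_1^2 >= 0.
#' @export
eps_tncs <- function(eps) {
  v <- if (inherits(eps, "epsilon_factors")) eps$eps else as.numeric(eps)
  if (!length(v)) stop("empty epsilon-factor set")
  mean((v - 1)^2)
}

#' Refine TNCS rotation and r.m.s.d. by Wilson likelihood
#'
#' Maximizes the acentric Wilson (exponential) log-likelihood of the
#' observed intensities, `sum_h log p(I_h; eps_h * Sigma_bin)`, over the
#' rotational perturbation (axis-angle, 3 parameters) and the TNCS
#' r.m.s.d.  `Sigma_bin` is the maximum-likelihood mean intensity per
#' resolution bin (20 equal-population bins in 1/d^3) given the current
#' epsilon factors.  Multiple starts over a fixed perturbation grid
#' (0, 2, 5 and 10 degrees about each axis) guard against local optima.
#'
#' @param rs a [reflection_set()] with recovered intensities.
#' @param hyp0 starting [tncs_hypothesis()] (order and translation are
#'   held fixed; rotation and rmsd are refined).
#' @param dmin,dmax refinement band in Angstrom (defaults 5 and 10).
#' @param nbins number of resolution bins for Sigma.
#' @return A list with `hyp` (refined hypothesis), `eps`
#'   ([epsilon_factors()] at the optimum), `sigma1sq`, `logL`, `logL0`
#'   (log-likelihood at `hyp0`) and `converged`.
#' @export
refine_tncs <- function(rs, hyp0, dmin = 5, dmax = 10, nbins = 20) {
  stopifnot(inherits(rs, "reflection_set"), inherits(hyp0, "tncs_hypothesis"))
  if (is.null(rs$I)) stop("reflection set has no intensities; run recover_intensities()")
  keep <- rs$d >= dmin & rs$d <= dmax & is.finite(rs$I) & rs$I >= 0
  if (sum(keep) < 200)
    stop(sprintf("only %d reflections in the %.1f-%.1f A refinement band (need >= 200)",
                 sum(keep), dmin, dmax))
  hkl <- rs$hkl[keep, , drop = FALSE]
  d <- rs$d[keep]
  I <- rs$I[keep]
  s3 <- 1 / d^3
  br <- unique(stats::quantile(s3, probs = seq(0, 1, length.out = nbins + 1)))
  br[1] <- br[1] - 1e-9; br[length(br)] <- br[length(br)] + 1e-9
  bin <- as.integer(cut(s3, breaks = br, include.lowest = TRUE))

  negll <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    hyp <- tncs_hypothesis(hyp0$n, hyp0$t, rot_deg = ang,
                           rot_axis = if (ang > 1e-9) par[1:3] else c(0, 0, 1),
                           rmsd = par[4], r_mol = hyp0$r_mol)
    g <- epsilon_raw(hkl, d, rs$cell, rs$sg, hyp)
    eps <- pmax(g / mean(g), 1e-4)
    # ML Sigma per bin given eps, then Wilson log-likelihood
    Ie <- I / eps
    Sig <- tapply(Ie, bin, mean)
    Sig <- pmax(as.numeric(Sig[bin]), 1e-12 * mean(I))
    -sum(-log(eps * Sig) - I / (eps * Sig))
  }

  starts <- list(c(hyp0$rot_axis / sqrt(sum(hyp0$rot_axis^2)) * hyp0$rot_deg,
                   max(hyp0$rmsd, 0.01)))
  for (ang in c(2, 5, 10)) for (ax in 1:3) {
    v <- numeric(3); v[ax] <- ang
    starts <- c(starts, list(c(v, 0.5)))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- try(stats::optim(p0, negll, method = "L-BFGS-B",
                            lower = c(-25, -25, -25, 0),
                            upper = c(25, 25, 25, 5),
                            control = list(maxit = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  logL0 <- -negll(starts[[1]])
  if (is.null(best)) {
    warning("TNCS refinement failed to converge from every start; returning hyp0")
    eps0 <- epsilon_factors(rs, hyp0, dmin, dmax)
    return(list(hyp = hyp0, eps = eps0, sigma1sq = eps_tncs(eps0),
                logL = logL0, logL0 = logL0, converged = FALSE))
  }
  par <- best$par
  ang <- sqrt(sum(par[1:3]^2))
  hyp <- tncs_hypothesis(hyp0$n, hyp0$t, rot_deg = ang,
                         rot_axis = if (ang > 1e-9) par[1:3] else c(0, 0, 1),
                         rmsd = par[4], r_mol = hyp0$r_mol)
  eps <- epsilon_factors(rs, hyp, dmin, dmax)
  list(hyp = hyp, eps = eps, sigma1sq = eps_tncs(eps),
       logL = -best$value, logL0 = logL0, converged = TRUE)
}
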