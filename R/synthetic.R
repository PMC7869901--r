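#' Rotation matrix from axis and angle
#'
#' Rodrigues rotation about a (not necessarily unit) axis.
#'
#' @param axis numeric length-3 axis vector.
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, deg) {
  th <- deg * pi / 180
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -n[3], n[2], n[3], 0, -n[1], -n[2], n[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Angle of a rotation matrix
#'
#' Rotation angle in degrees recovered from the matrix trace,
#' `acos((trace - 1)/2)`.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

## sub-seed a named RNG stream from a user seed (stays below 2^31)
stream_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + match(stream, c("coords", "jitter", "noise", "split")) * 7919L) %% 2000000011L
}

#' Generate a synthetic point-atom crystal with planted TNCS
#'
#' Builds a point-scatterer "molecule" (atoms uniform in a sphere of radius
#' `r_mol`, unit scattering weights) and places `n` copies related by
#' multiples of a basic fractional translation `t`, with an optional
#' rotational perturbation applied about each copy centroid (copy m is
#' rotated by `m * rot_deg`) and independent Gaussian coordinate jitter per
#' copy per atom.  Deterministic for a fixed seed.
#'
#' With a per-atom 3D r.m.s. jitter of `jitter` Angstrom per copy, the
#' r.m.s. coordinate difference between two copies is `sqrt(2) * jitter`,
#' which is the TNCS r.m.s.d. the intensity model sees.
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()]; P1 and P21 supported.
#' @param n_atoms atoms per copy (10 to 500).
#' @param n TNCS order; 1 means a single copy.
#' @param t basic fractional translation (length 3); required non-zero when
#'   `n >= 2`.
#' @param rot_deg rotational perturbation per copy (degrees).
#' @param rot_axis rotation axis (orthogonal frame).
#' @param jitter per-atom, per-copy 3D r.m.s. coordinate displacement
#'   (Angstrom).
#' @param r_mol molecular radius (Angstrom).
#' @param centre fractional position of the first copy centroid.
#' @param shape `"sphere"` draws atoms uniformly in a sphere of radius
#'   `r_mol` (a compact molecule, matching the spherical-interference
#'   rotation model); `"cell"` draws them uniformly over the whole unit
#'   cell, for which cross terms between different atoms vanish exactly in
#'   expectation and the epsilon-factor algebra is exact.
#' @param seed integer seed.
#' @return Object of class `synthetic_crystal`: `cell`, `sg`, `xyz_frac`
#'   (fractional coordinates, all copies), `weights`, `copy` (copy index per
#'   atom), ideal copy centroids `centroids`, and the generating parameters.
#' @export
generate_crystal <- function(cell, sg, n_atoms = 40, n = 1, t = c(0, 0, 0),
                             rot_deg = 0, rot_axis = c(0, 0, 1), jitter = 0,
                             r_mol = 12, centre = c(0.23, 0.31, 0.27),
                             shape = c("sphere", "cell"), seed = 1) {
  shape <- match.arg(shape)
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  if (n < 1) stop("TNCS order n must be >= 1")
  if (n_atoms < 10 || n_atoms > 500) stop("n_atoms must be in [10, 500]")
  if (n >= 2 && all(t == 0)) stop("TNCS of order >= 2 requires a non-zero translation")

  set.seed(stream_seed(seed, "coords"))
  if (shape == "sphere") {
    # uniform in a sphere of radius r_mol (orthogonal frame, centred)
    u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * r_mol * stats::runif(n_atoms)^(1 / 3)
  } else {
    uf <- matrix(stats::runif(3 * n_atoms), ncol = 3)
    u <- frac_to_orth(cell, sweep(uf, 2, centre, "-"))
  }

  set.seed(stream_seed(seed, "jitter"))
  xyz <- vector("list", n)
  centroids <- matrix(0, n, 3)
  for (m in seq_len(n) - 1) {
    R <- rotation_matrix(rot_axis, m * rot_deg)
    x <- t(R %*% t(u))                                    # rotate about centroid
    if (jitter > 0)
      x <- x + matrix(stats::rnorm(3 * n_atoms, sd = jitter / sqrt(3)), ncol = 3)
    cen_frac <- centre + m * t
    cen_frac <- cen_frac - floor(cen_frac)                # keep copies in cell
    centroids[m + 1, ] <- cen_frac
    xyz[[m + 1]] <- orth_to_frac(cell, sweep(x, 2, frac_to_orth(cell, cen_frac), "+"))
  }
  structure(list(
    cell = cell, sg = sg,
    xyz_frac = do.call(rbind, xyz),
    weights = rep(1, n * n_atoms),
    copy = rep(seq_len(n), each = n_atoms),
    centroids = centroids,
    n = n, t = t, rot_deg = rot_deg, rot_axis = rot_axis,
    jitter = jitter, r_mol = r_mol, n_atoms = n_atoms, shape = shape,
    seed = seed),
    class = "synthetic_crystal")
}

#' @export
print.synthetic_crystal <- function(x, ...) {
  cat(sprintf("Synthetic crystal: %d x %d atoms, TNCS order %d, t=(%.3f,%.3f,%.3f), rot %.1f deg, jitter %.2f A\n",
              x$n, x$n_atoms, x$n, x$t[1], x$t[2], x$t[3], x$rot_deg, x$jitter))
  invisible(x)
}

#' Structure factors by direct summation
#'
#' Computes F(h) = sum over symmetry operations and atoms of
#' w * exp(2 pi i h . (R x + t)) for every unique reflection in the
#' resolution shell, with intensities I = |F|^2.  No FFT is involved; this
#' is the independent oracle for the Fourier-based modules.
#'
#' @param cry a [generate_crystal()] result.
#' @param dmin,dmax resolution shell (Angstrom).
#' @return A [reflection_set()] with provenance `"mean-intensity"` and
#'   `sigI = 0`.
#' @export
direct_sf <- function(cry, dmin, dmax = Inf) {
  hkl <- generate_hkl(cry$cell, cry$sg, dmin, dmax)
  X <- t(cry$xyz_frac)            # 3 x natoms
  Fc <- complex(real = numeric(nrow(hkl)), imaginary = numeric(nrow(hkl)))
  for (op in cry$sg$ops) {
    ph <- (hkl %*% op$R %*% X) + drop(hkl %*% op$t)   # nrefl x natoms
    Fc <- Fc + (exp(2i * pi * ph) %*% cry$weights)[, 1]
  }
  reflection_set(cry$cell, cry$sg, hkl, I = Mod(Fc)^2,
                 sigI = rep(0, nrow(hkl)), provenance = "mean-intensity")
}

#' Degrade a reflection set: missing wedge and multiplicative noise
#'
#' Removes a contiguous reciprocal-space wedge about a random direction
#' (the fraction of solid angle removed equals `wedge_fraction`) and adds
#' multiplicative Gaussian noise to the intensities.
#'
#' @param rs a [reflection_set()].
#' @param wedge_fraction fraction of reciprocal space to remove, in \[0, 1).
#' @param noise_level relative standard deviation of the multiplicative
#'   intensity noise (e.g. 0.1 for 10 percent).
#' @param seed integer seed.
#' @return The degraded reflection set.
#' @export
degrade <- function(rs, wedge_fraction = 0, noise_level = 0, seed = 1) {
  stopifnot(wedge_fraction >= 0, wedge_fraction < 1)
  out <- rs
  if (wedge_fraction > 0) {
    set.seed(stream_seed(seed, "coords"))
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    s <- rs$hkl %*% rs$cell$frac
    cosang <- abs((s %*% ax) / sqrt(rowSums(s^2)))
    keep <- as.numeric(cosang) <= (1 - wedge_fraction)
    out <- subset_reflections(out, keep)
  }
  if (noise_level > 0) {
    set.seed(stream_seed(seed, "noise"))
    out$I <- out$I * (1 + stats::rnorm(length(out$I), sd = noise_level))
    if (!is.null(out$sigI)) out$sigI <- pmax(out$sigI, noise_level * abs(out$I))
  }
  out
}

#' Write a synthetic crystal as a PDB file
#'
#' Minimal PDB with a CRYST1 record and one chain per TNCS copy, so the
#' coordinate-based analysis can be exercised on files.  Atoms are written
#' as carbon CA pseudo-atoms.
#'
#' @param cry a [generate_crystal()] result.
#' @param path output file path.
#' @export
write_crystal_pdb <- function(cry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d\n",
              cry$cell$a, cry$cell$b, cry$cell$c,
              cry$cell$alpha, cry$cell$beta, cry$cell$gamma,
              cry$sg$symbol, 1), file = con)
  xyz <- frac_to_orth(cry$cell, cry$xyz_frac)
  chains <- LETTERS[cry$copy]
  serial <- 0L
  for (i in seq_len(nrow(xyz))) {
    serial <- serial + 1L
    res_i <- ((i - 1L) %% cry$n_atoms) + 1L
    cat(sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C\n",
                serial, chains[i], res_i,
                xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 20.0), file = con)
  }
  cat("END\n", file = con)
  invisible(path)
}
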