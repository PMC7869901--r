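# Shared fixtures: everything is generated in code at test time.

uc_std <- unit_cell(60, 70, 50)
sg_p1 <- space_group("P1")
sg_p21 <- space_group("P21")

# smallest min-image mismatch between two fractional vectors under Laue symmetry
frac_mm <- function(sg, a, b) {
  best <- Inf
  for (R in sg$laue) {
    d <- a - as.numeric(R %*% b)
    best <- min(best, max(abs(d - round(d))))
  }
  best
}

# intensities of a planted-TNCS crystal, ready for Patterson work
tncs_reflections <- function(n = 2, t = c(0, 0.5, 0), jitter = 0, rot_deg = 0,
                             seed = 1, n_atoms = 40, cell = uc_std, sg = sg_p1,
                             dmin = 5, dmax = 10, ...) {
  cry <- generate_crystal(cell, sg, n_atoms = n_atoms, n = n, t = t,
                          jitter = jitter, rot_deg = rot_deg, seed = seed, ...)
  recover_intensities(direct_sf(cry, dmin, dmax))
}

# chain translated (fractionally) and rotated about its centroid
shifted_chain <- function(base_xyz, cell, rot = 0, axis = c(0, 0, 1),
                          shift_frac = c(0, 0, 0), id = "A") {
  cen <- colMeans(base_xyz)
  R <- rotation_matrix(axis, rot)
  x <- t(R %*% t(sweep(base_xyz, 2, cen))) +
    matrix(cen + frac_to_orth(cell, shift_frac), nrow(base_xyz), 3, byrow = TRUE)
  chain_model(id, rep("A", nrow(x)), x)
}

random_chain_xyz <- function(n = 30, seed = 4, cell = uc_std) {
  cry <- generate_crystal(cell, sg_p1, n_atoms = n, n = 1, seed = seed)
  frac_to_orth(cell, cry$xyz_frac)
}
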