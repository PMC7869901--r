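test_that("chain matching respects the sequence-identity threshold", {
  xyz <- random_chain_xyz(60)
  seqA <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, replace = TRUE)
  seqB <- seqA
  seqB[1:2] <- ifelse(seqB[1:2] == "A", "G", "A")   # ~96.7% identity
  seqC <- rev(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, replace = TRUE))
  mdl <- coord_model(uc_std, sg_p1, list(
    chain_model("A", seqA, xyz), chain_model("B", seqB, xyz + 5),
    chain_model("C", seqC, xyz + 10)))
  m <- match_chains(mdl, identity_threshold = 0.95)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$i, m$j), c(1L, 2L))
  # identical chains always match; unrelated never do
  mdl2 <- coord_model(uc_std, sg_p1, list(
    chain_model("A", seqA, xyz), chain_model("B", seqA, xyz + 5)))
  expect_equal(nrow(match_chains(mdl2)), 1L)
  mdl3 <- coord_model(uc_std, sg_p1, list(
    chain_model("A", seqA, xyz), chain_model("C", seqC, xyz + 5)))
  expect_equal(nrow(match_chains(mdl3)), 0L)
})

test_that("superposition recovers planted rotations and translations", {
  xyz <- random_chain_xyz(40)
  A <- chain_model("A", rep("A", 40), xyz)
  # pure translation: identity op, zero angle, translation t
  B <- shifted_chain(xyz, uc_std, rot = 0, shift_frac = c(0.1, 0.25, 0), id = "B")
  sp <- superpose_pair(A, B, sg_p1, uc_std)
  expect_equal(sp$angle_deg[1], 0, tolerance = 1e-6)
  expect_equal(as.numeric(sp[1, c("t1", "t2", "t3")]), c(0.1, 0.25, 0),
               tolerance = 1e-6)
  # planted 2-degree rotation
  B2 <- shifted_chain(xyz, uc_std, rot = 2, axis = c(1, 1, 0),
                      shift_frac = c(0, 0.5, 0), id = "B")
  sp2 <- superpose_pair(A, B2, sg_p1, uc_std)
  expect_equal(sp2$angle_deg[1], 2, tolerance = 0.05)
  # collinear atoms are flagged as degenerate
  lin <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose_pair(chain_model("L", rep("A", 10), lin),
                              chain_model("M", rep("A", 10), lin + 1),
                              sg_p1, uc_std), "degenerate")
})

test_that("superposition agrees with an independent all-atom fit", {
  xyz <- random_chain_xyz(40)
  B <- shifted_chain(xyz, uc_std, rot = 7, axis = c(0, 1, 1),
                     shift_frac = c(0.3, 0, 0), id = "B")
  sp <- superpose_pair(chain_model("A", rep("A", 40), xyz), B, sg_p1, uc_std)
  # oracle: bio3d rot.lsq on the same coordinate sets
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(B$xyz)),
                                            mobile = as.numeric(t(xyz))))
  rmsd_oracle <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - B$xyz)^2)))
  expect_equal(sp$rmsd_fit[1], rmsd_oracle, tolerance = 1e-6)
  expect_equal(sp$angle_deg[1], 7, tolerance = 0.05)
})

test_that("chains related only through a symmetry operation superpose under it", {
  xyz <- random_chain_xyz(30)
  A <- chain_model("A", rep("A", 30), xyz)
  # build B as the P21 screw image of A, then displace by a fractional shift
  op <- sg_p21$ops[[2]]
  Bf <- t(op$R %*% t(orth_to_frac(uc_std, xyz))) +
    matrix(op$t + c(0.25, 0, 0), 30, 3, byrow = TRUE)
  B <- chain_model("B", rep("A", 30), frac_to_orth(uc_std, Bf))
  sp <- superpose_pair(A, B, sg_p21, uc_std)
  expect_gt(sp$angle_deg[sp$op == 1], 170)   # identity op: ~180 degrees
  expect_equal(sp$angle_deg[sp$op == 2], 0, tolerance = 1e-6)
})

test_that("the closed-group rule groups 2/2/4-degree chains at 3-degree tolerance", {
  xyz <- random_chain_xyz(30)
  mdl <- coord_model(uc_std, sg_p1, list(
    shifted_chain(xyz, uc_std, rot = 0, shift_frac = c(0, 0, 0), id = "A"),
    shifted_chain(xyz, uc_std, rot = 2, shift_frac = c(0, 0, 0.25), id = "B"),
    shifted_chain(xyz, uc_std, rot = 4, shift_frac = c(0, 0, 0.5), id = "C")))
  res <- pdb_tncs(mdl, r_deg = 3)
  expect_true(res$has_tncs)
  expect_equal(length(res$groups), 1L)
  expect_equal(res$groups[[1]]$order, 3L)
  expect_setequal(res$groups[[1]]$members, c("A", "B", "C"))
  expect_equal(res$groups[[1]]$max_rotation_deg, 4, tolerance = 0.05)
  expect_equal(res$groups[[1]]$scattering_fraction, 1)
  # at 1-degree tolerance no edge qualifies
  expect_false(pdb_tncs(mdl, r_deg = 1)$has_tncs)
})

test_that("an order-4 ladder is recovered with its basic vector", {
  cry <- generate_crystal(uc_std, sg_p1, n_atoms = 30, n = 4,
                          t = c(0, 0, 0.25), seed = 9)
  res <- pdb_tncs(crystal_to_model(cry), r_deg = 3)
  expect_equal(res$groups[[1]]$order, 4L)
  expect_equal(abs(res$groups[[1]]$t_frac), c(0, 0, 0.25), tolerance = 1e-6)
  # oracle: exhaustive pairing - all 6 pairs superpose with ~0 rotation and
  # translations that are multiples of (0,0,0.25)
  mdl <- crystal_to_model(cry)
  for (i in 1:3) for (j in (i + 1):4) {
    sp <- superpose_pair(mdl$chains[[i]], mdl$chains[[j]], sg_p1, uc_std)
    expect_lt(sp$angle_deg[1], 0.01)
    tv <- as.numeric(sp[1, c("t1", "t2", "t3")]) * 4
    expect_equal(tv - round(tv), c(0, 0, 0), tolerance = 1e-4)
  }
})

test_that("the classifier is monotone in the angular tolerance", {
  xyz <- random_chain_xyz(30)
  mdl <- coord_model(uc_std, sg_p1, list(
    shifted_chain(xyz, uc_std, rot = 0, shift_frac = c(0, 0, 0), id = "A"),
    shifted_chain(xyz, uc_std, rot = 12, shift_frac = c(0, 0.5, 0), id = "B")))
  expect_false(pdb_tncs(mdl, r_deg = 10)$has_tncs)
  expect_true(pdb_tncs(mdl, r_deg = 15)$has_tncs)
  got <- vapply(c(2, 5, 10, 13, 16, 20),
                function(r) pdb_tncs(mdl, r_deg = r)$has_tncs, TRUE)
  expect_true(all(diff(as.integer(got)) >= 0))
  # single chain: never TNCS
  one <- coord_model(uc_std, sg_p1, list(chain_model("A", rep("A", 30), xyz)))
  expect_false(pdb_tncs(one)$has_tncs)
})

test_that("reported order never decreases as the tolerance grows", {
  xyz <- random_chain_xyz(30)
  # A-B and B-C close, A-C far: order 2 at small r, order 3 once closure kicks in
  mdl <- coord_model(uc_std, sg_p1, list(
    shifted_chain(xyz, uc_std, rot = 0, shift_frac = c(0, 0, 0), id = "A"),
    shifted_chain(xyz, uc_std, rot = 4, shift_frac = c(0, 0, 0.25), id = "B"),
    shifted_chain(xyz, uc_std, rot = 8, shift_frac = c(0, 0, 0.5), id = "C")))
  ords <- vapply(c(2, 5, 10, 20), function(r) {
    g <- pdb_tncs(mdl, r_deg = r)$groups
    if (length(g)) max(vapply(g, `[[`, 0L, "order")) else 0L
  }, 0L)
  expect_true(all(diff(ords) >= 0))
  expect_equal(ords[length(ords)], 3L)
})

test_that("PDB round trip preserves the coordinate analysis", {
  cry <- generate_crystal(uc_std, sg_p21, n_atoms = 30, n = 2,
                          t = c(0.5, 0, 0), seed = 10)
  f <- tempfile(fileext = ".pdb")
  write_crystal_pdb(cry, f)
  mdl <- read_coords_pdb(f)
  unlink(f)
  expect_equal(length(mdl$chains), 2L)
  expect_equal(mdl$sg$symbol, "P 1 21 1")
  res <- pdb_tncs(mdl, r_deg = 3)
  expect_true(res$has_tncs)
  expect_equal(abs(res$groups[[1]]$t_frac), c(0.5, 0, 0), tolerance = 1e-3)
})

test_that("MTRIX records that are not applied generate the extra copies", {
  cry <- generate_crystal(uc_std, sg_p1, n_atoms = 30, n = 1, seed = 12)
  f <- tempfile(fileext = ".pdb")
  write_crystal_pdb(cry, f)
  lines <- readLines(f)
  tv <- frac_to_orth(uc_std, c(0, 0.5, 0))
  mtrix <- c(sprintf("MTRIX1   1%10.6f%10.6f%10.6f     %10.5f", 1, 0, 0, tv[1]),
             sprintf("MTRIX2   1%10.6f%10.6f%10.6f     %10.5f", 0, 1, 0, tv[2]),
             sprintf("MTRIX3   1%10.6f%10.6f%10.6f     %10.5f", 0, 0, 1, tv[3]))
  writeLines(c(lines[1], mtrix, lines[-1]), f)
  mdl <- read_coords_pdb(f)
  unlink(f)
  expect_equal(length(mdl$chains), 2L)
  res <- pdb_tncs(mdl, r_deg = 3)
  expect_true(res$has_tncs)
  expect_equal(abs(res$groups[[1]]$t_frac), c(0, 0.5, 0), tolerance = 1e-3)
})
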