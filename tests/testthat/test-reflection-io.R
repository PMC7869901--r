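test_that("sf-mmCIF and CSV writers round-trip hkl, intensities and cell", {
  rs <- tncs_reflections(seed = 3)
  for (ext in c(".cif", ".csv")) {
    f <- tempfile(fileext = ext)
    if (ext == ".cif") write_sf_cif(rs, f) else write_refl_csv(rs, f)
    rs2 <- load_reflections(f)
    expect_equal(rs2$cell$a, rs$cell$a, tolerance = 1e-4)
    expect_equal(rs2$sg$symbol, rs$sg$symbol)
    k1 <- paste(rs$hkl[, 1], rs$hkl[, 2], rs$hkl[, 3])
    k2 <- paste(rs2$hkl[, 1], rs2$hkl[, 2], rs2$hkl[, 3])
    expect_setequal(k2, k1)
    expect_equal(rs2$I[match(k1, k2)], rs$I, tolerance = 1e-7)
    expect_equal(rs2$provenance, "mean-intensity")
    unlink(f)
  }
})

test_that("provenance is inferred from available columns", {
  base <- tncs_reflections(seed = 3)
  n <- nrow(base$hkl)
  # only Friedel-separated intensities -> anomalous provenance
  anom <- reflection_set(base$cell, base$sg, base$hkl,
                         Iplus = base$I * 1.1, sigIplus = rep(1, n),
                         Iminus = base$I * 0.9, sigIminus = rep(1, n))
  expect_equal(anom$provenance, "anomalous-intensity")
  f <- tempfile(fileext = ".cif")
  write_sf_cif(anom, f)
  expect_equal(load_reflections(f)$provenance, "anomalous-intensity")
  unlink(f)
  # only amplitudes -> French-Wilson by default, raw on request
  amp <- reflection_set(base$cell, base$sg, base$hkl, F = sqrt(pmax(base$I, 0)))
  expect_equal(amp$provenance, "amplitude-french-wilson")
  f <- tempfile(fileext = ".cif")
  write_sf_cif(amp, f)
  expect_equal(load_reflections(f)$provenance, "amplitude-french-wilson")
  expect_equal(load_reflections(f, amplitude_raw = TRUE)$provenance, "amplitude-raw")
  unlink(f)
  expect_error(reflection_set(base$cell, base$sg, base$hkl), "no intensity")
})

test_that("intensity recovery follows the provenance rules", {
  cell <- unit_cell(30, 30, 30)
  sg <- space_group("P1")
  hkl <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  # anomalous: unweighted Friedel average, singleton used alone
  rs <- reflection_set(cell, sg, hkl,
                       Iplus = c(4, 10, NA), Iminus = c(2, NA, 6),
                       provenance = "anomalous-intensity")
  out <- recover_intensities(rs)
  expect_equal(out$I, c(3, 10, 6))
  # raw amplitudes: I = F^2, F = 0 (negative experimental I) -> I = 0
  rsF <- reflection_set(cell, sg, hkl, F = c(0, 2, 3), provenance = "amplitude-raw")
  expect_equal(recover_intensities(rsF)$I, c(0, 4, 9))
  # mean-intensity: idempotent, net-positive flagged for Patterson use
  rsI <- reflection_set(cell, sg, hkl, I = c(-1, 5, 2))
  r1 <- recover_intensities(rsI)
  expect_equal(r1$pos, c(FALSE, TRUE, TRUE))
  expect_identical(recover_intensities(r1)$I, r1$I)
  expect_equal(length(r1$I), 3L)   # all retained for likelihood work
})

test_that("French-Wilson reversal inverts the forward posterior-mean map", {
  set.seed(42)
  n <- 1000
  S <- 100
  I_true <- rexp(n, rate = 1 / S)              # Wilson acentric intensities
  sig <- runif(n, 5, 15)
  I_obs <- I_true + rnorm(n, sd = sig)         # measurement error
  Fa <- french_wilson_forward(I_obs, sig, S)
  expect_true(all(Fa >= 0))
  I_back <- french_wilson_reverse(Fa, sig, S)
  expect_lt(max(abs(I_back - I_obs)) / stats::sd(I_obs), 1e-6)
  # round trip on the amplitude side to the stated tolerance
  Fa2 <- french_wilson_forward(I_back, sig, S)
  expect_lt(max(abs(Fa2 - Fa) / Fa), 1e-4)
  # forward map is monotone in I (inversion well-posed)
  g <- french_wilson_forward(seq(-50, 300, by = 10), 10, S)
  expect_true(all(diff(g) > 0))
})

test_that("full-pipeline recovery from French-Wilson amplitudes preserves the Patterson", {
  rs <- tncs_reflections(seed = 8)
  S <- mean(rs$I)
  sig <- pmax(0.05 * rs$I, 1)
  Fa <- french_wilson_forward(rs$I, sig, S)
  rsF <- reflection_set(rs$cell, rs$sg, rs$hkl, F = Fa, sigI = sig,
                        provenance = "amplitude-french-wilson")
  out <- recover_intensities(rsF)
  # recovered intensities correlate tightly with the originals
  expect_gt(cor(out$I, rs$I), 0.999)
  pk <- pick_peaks(compute_patterson(out))
  expect_equal(as.numeric(pk[1, c("u", "v", "w")]), c(0, 0.5, 0), tolerance = 0.02)
})

test_that("resolution truncation matches a brute-force shell count", {
  cry <- generate_crystal(uc_std, sg_p1, n_atoms = 20, n = 1, seed = 2)
  rs <- direct_sf(cry, 2.8, 20)
  tr <- truncate_resolution(rs, 3.0)
  expect_true(all(tr$d >= 3.0))
  # oracle: direct enumeration over the hkl sphere
  expect_equal(nrow(tr$hkl), nrow(generate_hkl(uc_std, sg_p1, 3.0, 20)))
  expect_equal(attr(tr, "n_before"), nrow(rs$hkl))
  expect_error(truncate_resolution(rs, 100), "no reflections")
})

test_that("completeness counts observed against theoretical unique reflections", {
  rs <- tncs_reflections(seed = 3)
  expect_equal(completeness(rs, 5, 10), 1.0)
  # every second reflection removed -> one half
  half <- tncscout:::subset_reflections(rs, seq_len(nrow(rs$hkl)) %% 2 == 0)
  expect_equal(completeness(half, 5, 10), 0.5, tolerance = 2 / nrow(rs$hkl))
  # monotone non-increasing under deletion
  vals <- vapply(c(1, 0.8, 0.5, 0.2), function(f) {
    keep <- seq_len(nrow(rs$hkl)) <= f * nrow(rs$hkl)
    completeness(tncscout:::subset_reflections(rs, keep), 5, 10)
  }, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("wedge removal reduces completeness by the wedge solid-angle fraction", {
  rs <- tncs_reflections(seed = 3, n = 1, n_atoms = 20)
  for (wf in c(0.2, 0.3, 0.5)) {
    dg <- degrade(rs, wedge_fraction = wf, seed = 7)
    expect_equal(completeness(dg, 5, 10), 1 - wf, tolerance = 0.06)
  }
  # identity when nothing is degraded
  dg0 <- degrade(rs, 0, 0, seed = 7)
  expect_identical(dg0$I, rs$I)
})
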