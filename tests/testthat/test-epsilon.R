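test_that("epsilon factors reproduce the closed forms for simple hypotheses", {
  rs <- tncs_reflections(n = 2, t = c(0, 0.5, 0), seed = 2)
  # no TNCS: epsilon identically one
  e1 <- epsilon_factors(rs, tncs_hypothesis(1))
  expect_true(all(e1$eps == 1))
  expect_equal(eps_tncs(e1), 0)
  # exact order 2, no damping: 2 for even k, 0 for odd k
  e2 <- epsilon_factors(rs, tncs_hypothesis(2, c(0, 0.5, 0)))
  odd <- e2$hkl[, 2] %% 2 == 1
  expect_equal(unname(e2$eps[odd]), rep(0, sum(odd)), tolerance = 1e-9)
  expect_equal(mean(e2$eps), 1, tolerance = 1e-12)
  expect_true(all(abs(e2$eps[!odd] - max(e2$eps)) < 1e-6))
  # fixed damping 0.5: classes at 0.5 and 1.5 (up to class balance)
  eh <- epsilon_factors(rs, tncs_hypothesis(2, c(0, 0.5, 0)), rho = 0.5)
  expect_equal(sort(unique(round(eh$eps, 2))), c(0.5, 1.51), tolerance = 0.02)
  expect_error(tncs_hypothesis(0), "order")
})

test_that("epsilon factors stay mean-normalized for arbitrary hypotheses", {
  rs <- tncs_reflections(n = 1, n_atoms = 20, seed = 3, sg = sg_p21)
  set.seed(1)
  for (k in 1:10) {
    hyp <- tncs_hypothesis(sample(1:6, 1), runif(3), rot_deg = runif(1, 0, 10),
                           rot_axis = rnorm(3), rmsd = runif(1, 0, 2),
                           r_mol = runif(1, 5, 25))
    e <- epsilon_factors(rs, hyp)
    expect_equal(mean(e$eps), 1, tolerance = 1e-6)
    expect_true(all(e$eps >= 0))
  }
})

test_that("eps-TNCS equals the variance about one and its ideal values", {
  expect_equal(eps_tncs(rep(1, 100)), 0)
  expect_equal(eps_tncs(c(rep(0, 50), rep(2, 50))), 1)
  # ideal order n with balanced classes: sigma_1^2 = n - 1
  for (n in 2:6) {
    # one class in n at eps = n, the rest extinct: mean is exactly 1
    eps <- c(rep(n, 100), rep(0, 100 * (n - 1)))
    expect_equal(mean(eps), 1)
    expect_equal(eps_tncs(eps), (1 / n) * (n - 1)^2 + ((n - 1) / n), tolerance = 1e-12)
    expect_equal(eps_tncs(eps), n - 1)
  }
  expect_error(eps_tncs(numeric(0)), "empty")
})

test_that("sigma_1^2 respects the printed range bound for orders up to 8", {
  rs <- tncs_reflections(n = 1, n_atoms = 20, seed = 3)
  set.seed(2)
  for (n in 2:8) {
    for (k in 1:3) {
      hyp <- tncs_hypothesis(n, round(runif(3), 2),
                             rmsd = runif(1, 0, 1.5), rot_deg = runif(1, 0, 8))
      s2 <- eps_tncs(epsilon_factors(rs, hyp))
      expect_gte(s2, 0)
      expect_lte(s2, (n / 2)^2 + (n / 2 - 1)^2 + 1e-9)
    }
  }
})

test_that("sigma_1^2 decreases strictly with growing TNCS r.m.s.d.", {
  rs <- tncs_reflections(n = 2, t = c(0, 0.5, 0), seed = 2)
  s2 <- vapply(seq(0, 2, by = 0.25), function(sd)
    eps_tncs(epsilon_factors(rs, tncs_hypothesis(2, c(0, 0.5, 0), rmsd = sd))), 0)
  expect_true(all(diff(s2) < 0))
})

test_that("epsilon model matches direct-summation class means under jitter", {
  # Monte-Carlo cross-module oracle at small n: 40 random structures
  nrep <- 40
  jit <- 0.5
  cw <- cs <- tot <- numeric(nrep)
  rs0 <- NULL
  for (r in seq_len(nrep)) {
    cry <- generate_crystal(uc_std, sg_p1, n_atoms = 25, n = 2, t = c(0, 0.5, 0),
                            jitter = jit, shape = "cell", seed = 40000 + r)
    rs <- direct_sf(cry, 5, 10)
    if (is.null(rs0)) { rs0 <- rs; odd <- rs$hkl[, 2] %% 2 == 1 }
    cw[r] <- mean(rs$I[odd]); cs[r] <- mean(rs$I[!odd]); tot[r] <- mean(rs$I)
  }
  e <- epsilon_factors(rs0, tncs_hypothesis(2, c(0, 0.5, 0), rmsd = sqrt(2) * jit))
  predw <- mean(e$eps[odd]) * mean(tot)
  preds <- mean(e$eps[!odd]) * mean(tot)
  expect_lt(abs(mean(cw) - predw) / (sd(cw) / sqrt(nrep)), 3.5)
  expect_lt(abs(mean(cs) - preds) / (sd(cs) / sqrt(nrep)), 3.5)
})

test_that("likelihood refinement recovers planted parameters and never worsens", {
  rs <- tncs_reflections(n = 2, t = c(0, 0.5, 0), jitter = 0.6 / sqrt(2),
                         rot_deg = 2, rot_axis = c(1, 0, 0), n_atoms = 60,
                         seed = 11)
  fit <- refine_tncs(rs, tncs_hypothesis(2, c(0, 0.5, 0), r_mol = 12))
  expect_true(fit$converged)
  expect_gte(fit$logL, fit$logL0)
  expect_equal(fit$hyp$rmsd, 0.6, tolerance = 0.2)
  expect_equal(fit$hyp$rot_deg, 2, tolerance = 1)
  expect_gt(fit$sigma1sq, 0.3)
  # forcing TNCS on unmodulated data drives the modulation statistic to ~0
  rs0 <- tncs_reflections(n = 1, n_atoms = 80, seed = 12)
  fit0 <- refine_tncs(rs0, tncs_hypothesis(2, c(0, 0.5, 0), r_mol = 12))
  expect_lt(fit0$sigma1sq, 0.05)
  expect_gte(fit0$logL, fit0$logL0)
  # too-small band errors
  expect_error(refine_tncs(rs, tncs_hypothesis(2, c(0, 0.5, 0)), 20, 25),
               "refinement band")
})

test_that("modulation statistic correlates with the top Patterson peak height", {
  # cohort with varying TNCS r.m.s.d.: sigma_1^2 tracks peak height
  rmsds <- c(0.1, 0.5, 0.9, 1.3, 1.7, 2.1)
  h <- s2 <- numeric(length(rmsds))
  for (k in seq_along(rmsds)) {
    rs <- tncs_reflections(n = 2, t = c(0, 0.5, 0), jitter = rmsds[k] / sqrt(2),
                           n_atoms = 40, seed = 600 + k)
    pk <- pick_peaks(compute_patterson(rs), min_height_pct = 1)
    h[k] <- pk$height_pct[1]
    fit <- refine_tncs(rs, tncs_hypothesis(2, c(0, 0.5, 0), r_mol = 12))
    s2[k] <- fit$sigma1sq
  }
  expect_gt(cor(h, s2), 0.9)
})
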