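test_that("generated gradient schemes match the requested acquisition", {
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 7)
  expect_length(sch$bvals, 28L)
  expect_equal(sum(sch$bvals == 0), 1L)
  expect_true(all(sch$bvals %in% c(0, 1200)))
  dw <- sch$bvecs[sch$bvals > 0, ]
  expect_equal(unname(sqrt(rowSums(dw^2))), rep(1, 27), tolerance = 1e-12)

  sch6 <- make_gradient_scheme(6, 1000, include_b0 = FALSE, seed = 0)
  expect_length(sch6$bvals, 6L)
  expect_gt(min_pairwise_angle(sch6$bvecs), 0)
  expect_error(make_gradient_scheme(5, 1000), ">= 6")
})

test_that("repulsion schemes are better separated than random ones", {
  sch <- make_gradient_scheme(64, 1200, include_b0 = FALSE, seed = 1)
  ours <- min_pairwise_angle(sch$bvecs)
  rand <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(64 * 3), ncol = 3)
    min_pairwise_angle(x / sqrt(rowSums(x^2)))
  }, numeric(1))
  expect_gte(ours, mean(rand))
})

test_that("schemes are deterministic in the seed", {
  expect_identical(make_gradient_scheme(27, 1200, seed = 5),
                   make_gradient_scheme(27, 1200, seed = 5))
})

test_that("tensor signal follows the monoexponential model", {
  d_iso <- 1e-3 * diag(3)
  g <- c(0, 0, 1)
  expect_equal(tensor_signal(0, g, d_iso, 100), 100)
  expect_equal(tensor_signal(1200, g, d_iso, 100),
               100 * exp(-1200 * 1e-3))
  # prolate tensor, gradient parallel to the axis
  d_pro <- 0.3e-3 * diag(3) + (1.7e-3 - 0.3e-3) * outer(c(1, 0, 0),
                                                        c(1, 0, 0))
  expect_equal(tensor_signal(1200, c(1, 0, 0), d_pro, 1),
               exp(-1200 * 1.7e-3))
  d_bad <- diag(c(1e-3, 1e-3, -1e-4))
  expect_error(tensor_signal(1000, g, d_bad, 1), "negative eigenvalue")
})

test_that("tensor eigenvalues reproduce the requested FA and MD", {
  for (fa in c(0.15, 0.5, 0.85)) {
    ev <- tensor_eigenvalues(fa, 0.8e-3)
    md <- (ev["axial"] + 2 * ev["radial"]) / 3
    fa_back <- (ev["axial"] - ev["radial"]) /
      sqrt(ev["axial"]^2 + 2 * ev["radial"]^2)
    expect_equal(unname(md), 0.8e-3, tolerance = 1e-10)
    expect_equal(unname(fa_back), fa, tolerance = 1e-8)
  }
})

test_that("phantom construction is a pure function of its spec", {
  spec <- phantom_spec(grid_shape = c(12L, 12L, 12L), core_radius = 2,
                       shell_outer_radius = 4.5,
                       capsule_thickness_mm = 1, seed = 9)
  a <- build_core_shell_phantom(spec)
  b <- build_core_shell_phantom(spec)
  expect_identical(a$dwi$data, b$dwi$data)
  expect_identical(a$labels, b$labels)
})

test_that("phantom labels partition the tumor sphere", {
  ph <- build_core_shell_phantom(phantom_spec(
    grid_shape = c(20L, 20L, 20L), core_radius = 3,
    shell_outer_radius = 7, capsule_thickness_mm = 1, snr = NULL,
    seed = 0))
  expect_false(any(ph$core$mask & ph$shell$mask))
  expect_identical(ph$core$mask | ph$shell$mask, ph$tumor$mask)
  expect_error(build_core_shell_phantom(phantom_spec(
    core_radius = 5, shell_outer_radius = 5.5)), "one voxel")
})

test_that("core voxels vary less across directions than shell voxels at equal MD", {
  # equal mean diffusivity isolates the anisotropy contrast
  ph <- build_core_shell_phantom(phantom_spec(
    grid_shape = c(20L, 20L, 20L), core_radius = 3,
    shell_outer_radius = 7, capsule_thickness_mm = 1,
    core_md = 0.8e-3, shell_md = 0.8e-3, snr = NULL, seed = 1))
  dw <- ph$dwi$data[, , , ph$dwi$scheme$bvals > 0]
  nvol <- dim(dw)[4]
  flat <- matrix(dw, ncol = nvol)
  vvar <- apply(flat, 1, stats::var)
  expect_lt(max(vvar[ph$core$mask]), min(vvar[ph$shell$mask]))
})

test_that("equal-FA, equal-orientation core and shell are indistinguishable", {
  ph <- build_core_shell_phantom(phantom_spec(
    grid_shape = c(18L, 18L, 18L), core_radius = 3,
    shell_outer_radius = 7, capsule_thickness_mm = 1,
    core_md = 0.8e-3, shell_md = 0.8e-3,
    core_fa = 0.7, shell_fa = 0.7, core_coherence = 1,
    shell_jitter_max = 0, shell_jitter_min = 0, snr = NULL, seed = 2))
  dw <- ph$dwi$data[, , , ph$dwi$scheme$bvals > 0]
  flat <- matrix(dw, ncol = dim(dw)[4])
  vvar <- apply(flat, 1, stats::var)
  # same tensor field model on both sides of the core boundary
  expect_equal(mean(vvar[ph$core$mask]), mean(vvar[ph$shell$mask]),
               tolerance = 0.15)
})

test_that("Rician noise has the expected zero-signal (Rayleigh) limit", {
  sch <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  dims <- c(48L, 48L, 48L)
  data <- array(0, c(dims, 2L))
  data[, , , 1] <- 100          # b0 defines the noise scale
  dwi <- dwi_volume(data, c(1, 1, 1), sch)
  snr <- 10
  noisy <- add_rician_noise(dwi, snr, seed = 4)
  sdn <- 100 / snr
  zero_vals <- noisy$data[, , , 2]         # >= 1e5 Rayleigh draws
  expect_equal(mean(zero_vals), sdn * sqrt(pi / 2), tolerance = 0.01)
  # determinism and the infinite-SNR identity
  noisy2 <- add_rician_noise(dwi, snr, seed = 4)
  expect_identical(noisy$data, noisy2$data)
  clean <- add_rician_noise(dwi, Inf, seed = 4)
  expect_identical(clean$data, dwi$data)
})

test_that("cohort simulation honours its spec", {
  co <- simulate_cohort(cohort_spec(n_subjects = 200,
                                    censoring_fraction = 0, seed = 1))
  expect_true(all(co$event == 1L))
  expect_true(all(co$time_months > 0))
  expect_identical(co, simulate_cohort(cohort_spec(n_subjects = 200,
                                                   censoring_fraction = 0,
                                                   seed = 1)))
  # necrosis anti-correlates with the c/s ratio
  expect_lt(cor(co$cs_ratio, co$necrosis), -0.9)
})

test_that("a protective c/s effect lengthens survival of the high group", {
  co <- simulate_cohort(cohort_spec(n_subjects = 3000,
                                    log_hazard_slope = -1.5,
                                    censoring_fraction = 0.15,
                                    seed = 2))
  sp <- median_split(co$cs_ratio)
  km_lo <- km_estimate(co[sp$low, ])
  km_hi <- km_estimate(co[sp$high, ])
  expect_gt(km_hi$median, km_lo$median)
})
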