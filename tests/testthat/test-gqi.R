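test_that("icosphere tessellations have the expected structure", {
  expect_equal(nrow(tessellate_sphere(0)$vertices), 12L)
  expect_equal(nrow(tessellate_sphere(1)$vertices), 42L)
  expect_equal(nrow(tessellate_sphere(2)$vertices), 162L)
  t3 <- tessellate_sphere(3)
  expect_equal(nrow(t3$vertices), 642L)
  expect_equal(unname(sqrt(rowSums(t3$vertices^2))),
               rep(1, 642), tolerance = 1e-9)
  # exact antipodal pairing
  expect_identical(t3$vertices[t3$antipode, ], -t3$vertices)
  # symmetric neighbour relation
  for (v in seq_len(42)) {
    t1 <- tessellate_sphere(1)
    for (w in t1$neighbors[[v]]) expect_true(v %in% t1$neighbors[[w]])
  }
  # nearest-neighbour angle shrinks with refinement
  edges <- vapply(0:3, function(l) tessellate_sphere(l)$max_edge_deg,
                  numeric(1))
  expect_true(all(diff(edges) < 0))
})

test_that("vectorized reconstruction matches the per-voxel double-loop oracle", {
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 11)
  spec <- phantom_spec(grid_shape = c(5L, 5L, 5L), center = c(2, 2, 2),
                       core_radius = 1.2, shell_outer_radius = 2.4,
                       capsule_thickness_mm = 0, snr = 15,
                       n_directions = 27, seed = 11)
  ph <- build_core_shell_phantom(spec)
  mask <- full_mask(ph$dwi)
  cfg <- recon_config(subdivision_level = 2)
  odf <- reconstruct_odf(ph$dwi, mask, cfg)
  tess <- tessellate_sphere(2)
  for (k in sample(nrow(odf$voxels), 25)) {
    v <- odf$voxels[k, ]
    ref <- naive_odf(ph$dwi$data[v[1], v[2], v[3], ], ph$dwi$scheme,
                     tess$vertices, cfg$l_delta, cfg$d0)
    expect_lt(max(abs(odf$values[k, ] - ref)) / max(abs(ref)), 1e-10)
  }
})

test_that("isotropic signal gives a nearly uniform ODF", {
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 2)
  dwi <- tensor_dwi(sch, 1e-3 * diag(3), dims = c(3L, 3L, 3L))
  odf <- reconstruct_odf(dwi, full_mask(dwi))
  cv <- apply(odf$values, 1, function(v) stats::sd(v) / mean(v))
  expect_true(all(cv < 0.02))
})

test_that("the top ODF peak recovers a prolate tensor's axis", {
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 2)
  tess <- tessellate_sphere(3)
  axis <- c(2, 1, 0.5); axis <- axis / sqrt(sum(axis^2))
  dwi <- tensor_dwi(sch, prolate_tensor(axis), dims = c(3L, 3L, 3L))
  odf <- reconstruct_odf(dwi, full_mask(dwi))
  expect_true(all(odf$n_peaks >= 1))
  for (k in seq_len(nrow(odf$voxels)))
    expect_angle_le(odf$peak_dirs[k, 1, ], axis, tess$max_edge_deg)
  # antipodal symmetry is exact
  expect_identical(odf$values, odf$values[, tess$antipode])
})

test_that("a b0-only scheme yields a constant ODF proportional to total signal", {
  sch <- gradient_scheme(c(0, 0, 0),
                         matrix(0, 3, 3))
  data <- array(rep(c(10, 20, 30), each = 8), c(2, 2, 2, 3))
  dwi <- dwi_volume(data, c(1, 1, 1), sch)
  odf <- reconstruct_odf(dwi, full_mask(dwi))
  expect_equal(unname(odf$values[1, ]),
               rep(60, ncol(odf$values)))
  expect_equal(odf$n_peaks, rep(0L, 8))   # constant => no strict maxima
})

test_that("peak extraction finds strict local maxima only", {
  tess <- tessellate_sphere(2)
  const <- rep(1, nrow(tess$vertices))
  expect_length(extract_peaks(const, tess)$qa, 0L)
  spiked <- const
  v <- 10
  spiked[v] <- 2
  spiked[tess$antipode[v]] <- 2
  pk <- extract_peaks(spiked, tess)
  expect_equal(nrow(pk$directions), 1L)
  expect_angle_le(pk$directions[1, ], tess$vertices[v, ], 1e-6)
})

test_that("a 90-degree two-tensor crossing yields two peaks on the axes", {
  sch <- make_gradient_scheme(64, 1200, include_b0 = TRUE, seed = 3)
  tess <- tessellate_sphere(3)
  d1 <- prolate_tensor(c(1, 0, 0), fa = 0.85)
  d2 <- prolate_tensor(c(0, 1, 0), fa = 0.85)
  sig <- vapply(seq_along(sch$bvals), function(i)
    0.5 * tensor_signal(sch$bvals[i], sch$bvecs[i, ], d1, 100) +
      0.5 * tensor_signal(sch$bvals[i], sch$bvecs[i, ], d2, 100),
    numeric(1))
  dwi <- dwi_volume(array(rep(sig, each = 1), c(1, 1, 1, length(sig))),
                    c(1, 1, 1), sch)
  odf <- reconstruct_odf(dwi, full_mask(dwi))
  expect_gte(odf$n_peaks[1], 2L)
  p1 <- odf$peak_dirs[1, 1, ]; p2 <- odf$peak_dirs[1, 2, ]
  axes <- rbind(c(1, 0, 0), c(0, 1, 0))
  err <- function(p) min(apply(axes, 1, function(a)
    acos(min(abs(sum(p * a)), 1)) * 180 / pi))
  expect_lt(err(p1), tess$max_edge_deg)
  expect_lt(err(p2), tess$max_edge_deg)
  # the two peaks point at different axes
  expect_gt(acos(min(abs(sum(p1 * p2)), 1)) * 180 / pi, 45)
})

test_that("reconstruction is equivariant under joint rotation", {
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 5)
  sch_rot <- gradient_scheme(sch$bvals, sch$bvecs %*% t(rot))
  axis <- c(1, 0, 0)
  tess <- tessellate_sphere(3)
  odf_of <- function(scheme, ax) {
    dwi <- tensor_dwi(scheme, prolate_tensor(ax), dims = c(1L, 1L, 1L))
    reconstruct_odf(dwi, full_mask(dwi))
  }
  o1 <- odf_of(sch, axis)
  o2 <- odf_of(sch_rot, as.numeric(rot %*% axis))
  expect_angle_le(o2$peak_dirs[1, 1, ],
                  as.numeric(rot %*% o1$peak_dirs[1, 1, ]),
                  2 * tess$max_edge_deg)
})

test_that("signal scaling scales the ODF but not peaks or normalized QA", {
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 6)
  dwi1 <- tensor_dwi(sch, prolate_tensor(c(0, 1, 1)), dims = c(2L, 2L, 2L))
  dwi2 <- dwi1
  dwi2$data <- dwi1$data * 3.7
  o1 <- reconstruct_odf(dwi1, full_mask(dwi1))
  o2 <- reconstruct_odf(dwi2, full_mask(dwi2))
  expect_equal(o2$values, 3.7 * o1$values, tolerance = 1e-12)
  expect_equal(o2$peak_dirs, o1$peak_dirs)
  expect_equal(o2$qa, o1$qa, tolerance = 1e-12)
})

test_that("all-zero voxels are flagged degenerate and carry no peaks", {
  sch <- make_gradient_scheme(27, 1200, include_b0 = TRUE, seed = 8)
  dwi <- tensor_dwi(sch, prolate_tensor(c(1, 0, 0)), dims = c(2L, 2L, 2L))
  dwi$data[1, 1, 1, ] <- 0
  odf <- reconstruct_odf(dwi, full_mask(dwi))
  k <- which(odf$voxels[, 1] == 1 & odf$voxels[, 2] == 1 &
               odf$voxels[, 3] == 1)
  expect_true(odf$degenerate[k])
  expect_equal(odf$n_peaks[k], 0L)
  expect_true(all(odf$values[k, ] == 0))
})
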