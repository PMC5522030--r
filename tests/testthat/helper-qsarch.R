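# Shared fixtures, all generated in code.

# prolate tensor with principal axis v
prolate_tensor <- function(v, fa = 0.7, md = 0.8e-3) {
  v <- v / sqrt(sum(v^2))
  ev <- tensor_eigenvalues(fa, md)
  unname(ev["radial"] * diag(3) +
           (ev["axial"] - ev["radial"]) * outer(v, v))
}

# constant-tensor DWI volume over a small grid
tensor_dwi <- function(scheme, d_tensor, dims = c(5L, 5L, 5L), s0 = 100,
                       voxel_size = c(1, 1, 1)) {
  n <- length(scheme$bvals)
  sig <- vapply(seq_len(n), function(i)
    tensor_signal(scheme$bvals[i], scheme$bvecs[i, ], d_tensor, s0),
    numeric(1L))
  data <- array(rep(sig, each = prod(dims)), c(dims, n))
  dwi_volume(data, voxel_size, scheme)
}

full_mask <- function(dwi) {
  voxel_mask(array(TRUE, dim(dwi$data)[1:3]), dwi$voxel_size, dwi$affine)
}

# reference ODF implementation: per-voxel, per-vertex double loop over
# the sinc-kernel summation, independent of the vectorized path
naive_odf <- function(signal, scheme, vertices, l_delta = 1.25,
                      d0 = 2.5e-3) {
  nv <- nrow(vertices)
  out <- numeric(nv)
  for (v in seq_len(nv)) {
    acc <- 0
    for (i in seq_along(scheme$bvals)) {
      x <- l_delta * sqrt(6 * d0 * scheme$bvals[i]) *
        sum(scheme$bvecs[i, ] * vertices[v, ])
      acc <- acc + signal[i] * (if (abs(x) < 1e-12) 1 else sin(x) / x)
    }
    out[v] <- acc
  }
  out
}

# small core-shell phantom run (build + reconstruct + track), sized for
# unit tests rather than the full-scale recovery study
small_phantom_run <- function(seed = 0L, core_coherence = 0, snr = 20) {
  spec <- phantom_spec(grid_shape = c(22L, 22L, 22L),
                       core_radius = 3, shell_outer_radius = 7,
                       capsule_thickness_mm = 2,
                       core_coherence = core_coherence,
                       snr = snr, seed = seed)
  ph <- build_core_shell_phantom(spec)
  odf <- reconstruct_odf(ph$dwi, ph$tracking)
  cfg <- tracking_config(max_length_mm = 30)
  seeds <- generate_seeds(ph$tumor, 2L, seed = seed + 100L)
  list(phantom = ph, odf = odf, seeds = seeds,
       tractogram = track(odf, seeds, cfg), cfg = cfg)
}

# fabricate a minimal odf_field with prescribed per-voxel peak
# directions on a grid (QA 1 for every listed peak)
fake_peak_field <- function(dirs_array, dims, voxel_size = c(1, 1, 1)) {
  vox <- as.matrix(expand.grid(seq_len(dims[1L]), seq_len(dims[2L]),
                               seq_len(dims[3L])))
  n <- nrow(vox)
  pk <- array(0, c(n, 3L, 3L))
  qa <- matrix(0, n, 3L)
  npk <- integer(n)
  for (k in seq_len(n)) {
    d <- dirs_array[[k]]
    if (is.null(d)) next
    d <- matrix(d, ncol = 3L)
    npk[k] <- nrow(d)
    pk[k, seq_len(nrow(d)), ] <- d
    qa[k, seq_len(nrow(d))] <- 1
  }
  structure(list(voxels = vox, values = NULL, peak_dirs = pk, qa = qa,
                 n_peaks = npk, degenerate = rep(FALSE, n),
                 tessellation = NULL, grid_dim = dims,
                 voxel_size = voxel_size,
                 affine = qsarch:::grid_affine(voxel_size)),
            class = "odf_field")
}

expect_angle_le <- function(u, v, max_deg) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  expect_lte(acos(min(cosang, 1)) * 180 / pi, max_deg)
}
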