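#' Core-shell diffusion phantom specification
#'
#' Describes a spherical tumor phantom with a disorganized,
#' higher-diffusivity core surrounded by a coherently oriented,
#' anisotropic shell — the architecture the tract-length analysis is
#' designed to detect. Defaults emulate a human-scale acquisition:
#' 1 mm isotropic voxels, b = 1200 s/mm^2, 27 directions plus one b0,
#' SNR 20 Rician noise.
#'
#' Diffusivities are not tied to any reported tumor values (none are
#' available); the defaults are generic DWI-literature magnitudes: an
#' elevated, nearly isotropic core (necrosis-like free diffusion) and a
#' lower-diffusivity, strongly anisotropic shell (packed aligned cells).
#'
#' @param grid_shape 3 integers, image grid.
#' @param voxel_size voxel dimensions (mm).
#' @param center tumor centre in 0-based voxel coordinates; defaults to
#'   the grid centre.
#' @param core_radius,shell_outer_radius core and tumor radii (mm);
#'   `0 < core_radius < shell_outer_radius`.
#' @param core_md,shell_md,background_md mean diffusivities (mm^2/s).
#' @param core_fa,shell_fa fractional anisotropy targets in [0, 1) with
#'   `core_fa < shell_fa`.
#' @param core_coherence in `[0, 1]`: 0 gives i.i.d. random per-voxel core
#'   orientations (fully disorganized); 1 aligns the core with the same
#'   circumferential field as the shell.
#' @param shell_jitter_max,shell_jitter_min in `[0, 1]`: amplitude of
#'   random orientation jitter mixed into the circumferential field at
#'   the inner shell boundary (`max`) decaying linearly with radius to
#'   `min` at the outer capsule edge. The resulting radial coherence
#'   gradient (cellular alignment greatest at the tumor periphery) makes
#'   mean tract length increase from the core outward, the radial
#'   architecture the ring profile is designed to detect.
#' @param shell_orientation `"circumferential"` (tangential directions
#'   around the tumor centre, continuous across voxels so long tracts can
#'   form) or `"uniform-axis"` (constant +x axis).
#' @param capsule_thickness_mm thickness of the peritumoral rim of
#'   tangentially displaced fibers surrounding the tumor (mm; 0 disables
#'   it). Expanding masses displace surrounding parenchyma into a
#'   coherent capsule, and tumor-seeded streamlines may continue into
#'   it, so rim tracts are not artificially cut at the tumor boundary.
#' @param capsule_fa fractional anisotropy of the capsule rim.
#' @param background_mode `"isotropic"` or `"fiber-bundle"` (+x prolate).
#' @param s0 non-diffusion-weighted signal level (arbitrary units).
#' @param snr Rician signal-to-noise ratio relative to the mean b0
#'   signal, or `NULL` for a noise-free phantom.
#' @param b_value,n_directions acquisition parameters (one b0 volume is
#'   always included).
#' @param seed RNG seed controlling directions, core orientations and
#'   noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size = c(1, 1, 1),
                         center = NULL,
                         core_radius = 5, shell_outer_radius = 12,
                         core_md = 1.5e-3, shell_md = 0.8e-3,
                         background_md = 0.8e-3,
                         core_fa = 0.15, shell_fa = 0.7,
                         core_coherence = 0,
                         shell_jitter_max = 0.5, shell_jitter_min = 0.15,
                         shell_orientation = c("circumferential",
                                               "uniform-axis"),
                         capsule_thickness_mm = 3, capsule_fa = 0.55,
                         background_mode = c("isotropic", "fiber-bundle"),
                         s0 = 100, snr = 20,
                         b_value = 1200, n_directions = 27L,
                         seed = 0L) {
  shell_orientation <- match.arg(shell_orientation)
  background_mode <- match.arg(background_mode)
  if (is.null(center)) center <- (as.numeric(grid_shape) - 1) / 2
  if (!(core_radius > 0 && core_radius < shell_outer_radius))
    stop("need 0 < core_radius < shell_outer_radius")
  # equality permitted so degenerate no-contrast controls can be built
  if (!(core_fa >= 0 && core_fa <= shell_fa && shell_fa < 1))
    stop("need 0 <= core_fa <= shell_fa < 1")
  if (!is.null(snr) && snr <= 0) stop("snr must be positive (or NULL)")
  if (core_coherence < 0 || core_coherence > 1)
    stop("core_coherence must lie in [0, 1]")
  if (shell_jitter_max < 0 || shell_jitter_max > 1 ||
      shell_jitter_min < 0 || shell_jitter_min > shell_jitter_max)
    stop("need 0 <= shell_jitter_min <= shell_jitter_max <= 1")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 center = as.numeric(center),
                 core_radius = core_radius,
                 shell_outer_radius = shell_outer_radius,
                 core_md = core_md, shell_md = shell_md,
                 background_md = background_md,
                 core_fa = core_fa, shell_fa = shell_fa,
                 core_coherence = core_coherence,
                 shell_jitter_max = shell_jitter_max,
                 shell_jitter_min = shell_jitter_min,
                 shell_orientation = shell_orientation,
                 capsule_thickness_mm = capsule_thickness_mm,
                 capsule_fa = capsule_fa,
                 background_mode = background_mode,
                 s0 = s0, snr = snr, b_value = b_value,
                 n_directions = as.integer(n_directions),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Axially symmetric diffusion tensor eigenvalues from FA and MD
#'
#' Solves for the axial and radial eigenvalues of a prolate tensor with
#' the requested fractional anisotropy and mean diffusivity, using
#' `FA = (l_ax - l_rad) / sqrt(l_ax^2 + 2 l_rad^2)` and
#' `MD = (l_ax + 2 l_rad) / 3`.
#'
#' @param fa fractional anisotropy in [0, 1).
#' @param md mean diffusivity (mm^2/s).
#' @return c(axial, radial) eigenvalues (mm^2/s).
#' @export
tensor_eigenvalues <- function(fa, md) {
  stopifnot(fa >= 0, fa < 1, md > 0)
  if (fa == 0) return(c(axial = md, radial = md))
  f <- function(la) {
    lr <- (3 * md - la) / 2
    (la - lr) - fa * sqrt(la^2 + 2 * lr^2)
  }
  la <- stats::uniroot(f, c(md, 3 * md - 1e-12), tol = 1e-14)$root
  c(axial = la, radial = (3 * md - la) / 2)
}

#' Single-tensor diffusion signal
#'
#' The monoexponential tensor model `S = S0 * exp(-b * g' D g)` used to
#' synthesize phantom signals.
#'
#' @param b b-value (s/mm^2).
#' @param g unit gradient direction (length 3).
#' @param d_tensor symmetric positive semi-definite 3 x 3 tensor
#'   (mm^2/s).
#' @param s0 signal at b = 0.
#' @return scalar signal in (0, s0].
#' @export
tensor_signal <- function(b, g, d_tensor, s0 = 1) {
  d_tensor <- as.matrix(d_tensor)
  if (any(abs(d_tensor - t(d_tensor)) > 1e-12))
    stop("diffusion tensor must be symmetric")
  ev <- eigen(d_tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-15))
    stop("diffusion tensor has a negative eigenvalue: ", min(ev))
  s0 * exp(-b * drop(t(g) %*% d_tensor %*% g))
}

# Continuous circumferential orientation field: the tangent to the
# horizontal circle around the vertical axis through the tumour centre.
# Near the axis (where the tangent is undefined) falls back to +x.
.circumferential <- function(rel) {
  t_ <- cbind(-rel[, 2L], rel[, 1L], 0)
  nrm <- sqrt(rowSums(t_^2))
  bad <- nrm < 1e-9
  t_[bad, ] <- matrix(rep(c(1, 0, 0), each = sum(bad)), ncol = 3L)
  nrm[bad] <- 1
  t_ / nrm
}

#' Build a core-shell diffusion phantom
#'
#' Synthesizes the 4D signal of a spherical tumor with a coherently
#' oriented anisotropic shell (prolate tensors tangent to circles around
#' the tumour centre, continuous across voxels) and a disorganized core
#' (per-voxel random orientations, low FA, elevated diffusivity), plus a
#' uniform background. All randomness (gradient directions, core
#' orientations, Rician noise) derives from `spec$seed`, so the phantom
#' is a pure function of its spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `dwi` (a [dwi_volume()]), `labels` (integer array,
#'   0 = background, 1 = core, 2 = shell), and [voxel_mask()]s `core`,
#'   `shell`, `tumor`, `background`.
#' @export
build_core_shell_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$shell_outer_radius - spec$core_radius < max(spec$voxel_size))
    stop("shell must be at least one voxel thick")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  scheme <- make_gradient_scheme(spec$n_directions, spec$b_value,
                                 include_b0 = TRUE,
                                 seed = spec$seed)
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  # voxel-centre world coordinates relative to the tumour centre
  ctr_world <- (spec$center + 0.5) * vs
  gx <- (seq_len(dims[1L]) - 0.5) * vs[1L] - ctr_world[1L]
  gy <- (seq_len(dims[2L]) - 0.5) * vs[2L] - ctr_world[2L]
  gz <- (seq_len(dims[3L]) - 0.5) * vs[3L] - ctr_world[3L]
  rel <- cbind(rep(gx, times = dims[2L] * dims[3L]),
               rep(rep(gy, each = dims[1L]), times = dims[3L]),
               rep(gz, each = dims[1L] * dims[2L]))
  r <- sqrt(rowSums(rel^2))
  labels <- integer(length(r))
  labels[r <= spec$shell_outer_radius] <- 2L
  labels[r <= spec$core_radius] <- 1L
  # peritumoral capsule: displaced-fiber rim outside the tumor proper
  region <- labels
  region[labels == 0L &
           r <= spec$shell_outer_radius + spec$capsule_thickness_mm] <- 3L

  # per-voxel principal orientation
  orient <- .circumferential(rel)
  bg_bundle <- spec$background_mode == "fiber-bundle"
  if (spec$shell_orientation == "uniform-axis") {
    orient[labels == 2L, ] <- matrix(rep(c(1, 0, 0),
                                         each = sum(labels == 2L)),
                                     ncol = 3L)
  } else if (spec$shell_jitter_max > 0) {
    # radial coherence gradient across shell + capsule: alignment
    # improves toward the periphery
    sh <- which(region >= 2L)
    r_edge <- spec$shell_outer_radius + spec$capsule_thickness_mm
    frac <- (r[sh] - spec$core_radius) / (r_edge - spec$core_radius)
    w <- spec$shell_jitter_max +
      (spec$shell_jitter_min - spec$shell_jitter_max) * frac
    w <- pmin(pmax(w, 0), 1)
    rnd <- matrix(stats::rnorm(3L * length(sh)), ncol = 3L)
    rnd <- rnd / sqrt(rowSums(rnd^2))
    mix <- (1 - w) * orient[sh, , drop = FALSE] + w * rnd
    nrm <- sqrt(rowSums(mix^2))
    deg <- nrm < 1e-9
    mix[deg, ] <- rnd[deg, , drop = FALSE]
    nrm[deg] <- 1
    orient[sh, ] <- mix / nrm
  }
  core_idx <- which(labels == 1L)
  if (length(core_idx)) {
    rnd <- matrix(stats::rnorm(3L * length(core_idx)), ncol = 3L)
    rnd <- rnd / sqrt(rowSums(rnd^2))
    mix <- spec$core_coherence * orient[core_idx, , drop = FALSE] +
      (1 - spec$core_coherence) * rnd
    nrm <- sqrt(rowSums(mix^2))
    deg <- nrm < 1e-9
    mix[deg, ] <- rnd[deg, , drop = FALSE]
    nrm[deg] <- 1
    orient[core_idx, ] <- mix / nrm
  }
  if (bg_bundle) {
    orient[region == 0L, ] <- matrix(rep(c(1, 0, 0),
                                         each = sum(region == 0L)),
                                     ncol = 3L)
  }

  ev_core <- tensor_eigenvalues(spec$core_fa, spec$core_md)
  ev_shell <- tensor_eigenvalues(spec$shell_fa, spec$shell_md)
  ev_caps <- tensor_eigenvalues(spec$capsule_fa, spec$shell_md)
  ev_bg <- if (bg_bundle) tensor_eigenvalues(0.6, spec$background_md)
           else tensor_eigenvalues(0, spec$background_md)
  lam_r <- c(ev_bg["radial"], ev_core["radial"], ev_shell["radial"],
             ev_caps["radial"])[region + 1L]
  lam_d <- c(ev_bg["axial"] - ev_bg["radial"],
             ev_core["axial"] - ev_core["radial"],
             ev_shell["axial"] - ev_shell["radial"],
             ev_caps["axial"] - ev_caps["radial"])[region + 1L]

  # S(v, i) = s0 * exp(-b_i * (lam_r + dlam * (g_i . o_v)^2))
  dots <- orient %*% t(scheme$bvecs)                 # nvox x N
  expo <- -(outer(lam_r, scheme$bvals) + dots^2 * outer(lam_d,
                                                        scheme$bvals))
  sig <- spec$s0 * exp(expo)
  data <- array(sig, c(dims, length(scheme$bvals)))
  dwi <- dwi_volume(data, vs, scheme)
  if (!is.null(spec$snr))
    dwi <- add_rician_noise(dwi, spec$snr, seed = spec$seed + 1L)

  lab_arr <- array(labels, dims)
  reg_arr <- array(region, dims)
  mk <- function(which) voxel_mask(lab_arr == which, vs, dwi$affine)
  list(dwi = dwi, labels = lab_arr,
       core = mk(1L), shell = mk(2L),
       tumor = voxel_mask(lab_arr > 0L, vs, dwi$affine),
       tracking = voxel_mask(reg_arr > 0L, vs, dwi$affine),
       background = voxel_mask(lab_arr == 0L, vs, dwi$affine),
       spec = spec)
}

#' Add Rician noise to a DWI volume
#'
#' Replaces every sample S by `sqrt((S + n1)^2 + n2^2)` with n1, n2
#' i.i.d. zero-mean Gaussians of standard deviation
#' `mean b0 signal / snr` — the magnitude-MR noise model. Zero-signal
#' voxels therefore acquire Rayleigh-distributed values with mean
#' `sd * sqrt(pi / 2)`. Deterministic for a fixed seed.
#'
#' @param volume a [dwi_volume()].
#' @param snr signal-to-noise ratio (> 0) relative to the mean b0 signal.
#' @param seed RNG seed.
#' @return a noisy [dwi_volume()].
#' @export
add_rician_noise <- function(volume, snr, seed = 0L) {
  stopifnot(inherits(volume, "dwi_volume"))
  if (snr <= 0) stop("snr must be positive")
  b0 <- which(is_b0(volume$scheme))
  if (!length(b0)) stop("scheme has no b0 volume to define the SNR")
  sd <- mean(volume$data[, , , b0]) / snr
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- length(volume$data)
  n1 <- stats::rnorm(n, sd = sd)
  n2 <- stats::rnorm(n, sd = sd)
  out <- volume
  out$data <- array(sqrt((volume$data + n1)^2 + n2^2), dim(volume$data))
  out
}
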