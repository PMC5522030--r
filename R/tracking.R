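#' Streamline tractograms
#'
#' A tractogram is an ordered set of streamlines, each an n x 3 matrix of
#' world-mm points, together with per-streamline lengths and provenance.
#'
#' @param streamlines list of numeric matrices (>= 2 rows, 3 columns each;
#'   an empty list is a valid empty tractogram).
#' @param voxel_size,grid_dim,affine geometry of the source volume,
#'   carried into TRK headers.
#' @param provenance free-form list (config hash, source id).
#' @param validate_spacing check consecutive-point spacing against
#'   `max_spacing` when not NULL.
#' @param max_spacing upper bound on consecutive-point spacing (mm).
#' @return object of class `tractogram` with elements `streamlines`,
#'   `lengths`, and geometry fields.
#' @export
tractogram <- function(streamlines, voxel_size = NULL, grid_dim = NULL,
                       affine = NULL, provenance = list(),
                       validate_spacing = FALSE, max_spacing = NULL) {
  stopifnot(is.list(streamlines))
  for (pts in streamlines) {
    if (!is.matrix(pts) || ncol(pts) != 3L || nrow(pts) < 2L)
      stop("each streamline must be an n x 3 matrix with n >= 2")
  }
  lengths <- vapply(streamlines, streamline_length, numeric(1L))
  if (validate_spacing && !is.null(max_spacing)) {
    for (pts in streamlines) {
      sp <- sqrt(rowSums(diff(pts)^2))
      if (any(sp > max_spacing + 1e-6))
        stop("streamline point spacing exceeds step size")
    }
  }
  structure(list(streamlines = streamlines, lengths = lengths,
                 voxel_size = voxel_size, grid_dim = grid_dim,
                 affine = affine, provenance = provenance),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("Tractogram: ", length(x$streamlines), " streamlines",
      if (length(x$lengths))
        sprintf(", length %.1f-%.1f mm (mean %.2f)",
                min(x$lengths), max(x$lengths), mean(x$lengths)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Arc length of a streamline
#'
#' @param points n x 3 matrix of ordered world-mm points, n >= 2.
#' @return sum of consecutive Euclidean distances (mm).
#' @export
streamline_length <- function(points) {
  if (!is.matrix(points) || nrow(points) < 2L)
    stop("a streamline needs at least 2 points")
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Keep streamlines within a length band
#'
#' Bounds are inclusive, matching the tract-length filters used to define
#' core (short) and shell (long) tumor tract populations.
#'
#' @param tractogram a [tractogram()].
#' @param lo_mm,hi_mm band edges (mm), `lo_mm <= hi_mm`.
#' @return filtered [tractogram()].
#' @export
filter_by_length <- function(tractogram, lo_mm, hi_mm) {
  stopifnot(inherits(tractogram, "tractogram"), lo_mm <= hi_mm)
  keep <- tractogram$lengths >= lo_mm & tractogram$lengths <= hi_mm
  out <- tractogram
  out$streamlines <- tractogram$streamlines[keep]
  out$lengths <- tractogram$lengths[keep]
  out
}

#' Tracking configuration
#'
#' Defaults follow the human-scale analysis: a 35 degree angular threshold,
#' 1 mm steps and a 1-55 mm analyzed length domain. The rat-scale
#' equivalents are 0.1 mm steps with a 25 mm cap.
#'
#' @param angle_threshold_deg maximum angle between consecutive steps
#'   (degrees, in (0, 90)).
#' @param step_size_mm advance per step (mm).
#' @param min_length_mm,max_length_mm retained length band (mm).
#' @param seeds_per_voxel jittered seed points per masked voxel.
#' @param qa_termination_threshold stop when the followed peak's QA falls
#'   below this value.
#' @param seed RNG seed for sub-voxel seed jitter.
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(angle_threshold_deg = 35, step_size_mm = 1.0,
                            min_length_mm = 1, max_length_mm = 55,
                            seeds_per_voxel = 4L,
                            qa_termination_threshold = 0.05, seed = 0L) {
  if (angle_threshold_deg <= 0 || angle_threshold_deg >= 90)
    stop("angle_threshold_deg must lie in (0, 90)")
  if (step_size_mm <= 0) stop("step_size_mm must be positive")
  if (min_length_mm >= max_length_mm)
    stop("min_length_mm must be smaller than max_length_mm")
  structure(list(angle_threshold_deg = angle_threshold_deg,
                 step_size_mm = step_size_mm,
                 min_length_mm = min_length_mm,
                 max_length_mm = max_length_mm,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 qa_termination_threshold = qa_termination_threshold,
                 seed = as.integer(seed)),
            class = "tracking_config")
}

#' Generate jittered seed points inside a mask
#'
#' Places `seeds_per_voxel` uniformly jittered sub-voxel positions in every
#' masked voxel; deterministic for a fixed seed.
#'
#' @param mask a [voxel_mask()].
#' @param seeds_per_voxel seeds per masked voxel.
#' @param seed RNG seed.
#' @return m x 3 matrix of world-mm seed points.
#' @export
generate_seeds <- function(mask, seeds_per_voxel = 4L, seed = 0L) {
  stopifnot(inherits(mask, "voxel_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)     # 1-based voxel indices
  if (nrow(idx) == 0L) stop("mask is empty")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- nrow(idx) * seeds_per_voxel
  rep_idx <- idx[rep(seq_len(nrow(idx)), each = seeds_per_voxel), ,
                 drop = FALSE]
  jitter <- matrix(stats::runif(3L * n, -0.5, 0.5), ncol = 3L)
  vs <- mask$voxel_size
  centres <- sweep(rep_idx - 0.5, 2L, vs, `*`)  # centre of 1-based voxel i
  centres + sweep(jitter, 2L, vs, `*`)
}

#' Deterministic streamline tractography over an ODF peak field
#'
#' From every seed, tracks bidirectionally through the per-voxel peak
#' field: at each step the peak of the current voxel (nearest-voxel
#' lookup) that minimizes the angle to the incoming direction is followed,
#' with its sign resolved towards the direction of travel. A half-track
#' terminates when that angle exceeds `angle_threshold_deg`, the followed
#' peak's quantitative anisotropy falls below the termination threshold,
#' the point leaves the peak field (mask or grid), or the total length
#' budget is spent (the forward half runs first; the backward half may
#' only use the remainder, so the concatenated streamline never exceeds
#' `max_length_mm`). The two half-tracks are concatenated at the seed and
#' streamlines shorter than `min_length_mm` are discarded.
#' Ties between equally angled peaks resolve to the highest-QA peak, so
#' the procedure is fully deterministic.
#'
#' @param odf_field an ODF field from [reconstruct_odf()] with extracted peaks.
#' @param seeds m x 3 matrix of world-mm seed points (see
#'   [generate_seeds()]).
#' @param cfg a [tracking_config()].
#' @return a [tractogram()]; streamline lengths all lie within the
#'   configured band, and `$seed_index` maps each retained streamline to
#'   its seed row.
#' @export
track <- function(odf_field, seeds, cfg = tracking_config()) {
  stopifnot(inherits(odf_field, "odf_field"))
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L)
    return(tractogram(list(), voxel_size = odf_field$voxel_size,
                      grid_dim = odf_field$grid_dim,
                      affine = odf_field$affine))
  dims <- odf_field$grid_dim
  vs <- odf_field$voxel_size
  nvox_grid <- prod(dims)
  # dense per-grid-voxel lookup tables (zero outside the mask)
  npk <- integer(nvox_grid)
  max_pk <- ncol(odf_field$qa)
  pdir <- array(0, c(nvox_grid, max_pk, 3L))
  pqa <- matrix(0, nvox_grid, max_pk)
  lin <- as.integer((odf_field$voxels[, 3L] - 1L) * dims[1L] * dims[2L] +
                    (odf_field$voxels[, 2L] - 1L) * dims[1L] +
                    odf_field$voxels[, 1L])
  npk[lin] <- odf_field$n_peaks
  for (j in seq_len(max_pk)) {
    pdir[lin, j, ] <- odf_field$peak_dirs[, j, ]
    pqa[lin, j] <- odf_field$qa[, j]
  }
  cos_thr <- cos(cfg$angle_threshold_deg * pi / 180)
  max_steps <- floor(cfg$max_length_mm / cfg$step_size_mm)

  vox_lin <- function(p) {
    ix <- floor(p[, 1L] / vs[1L]); iy <- floor(p[, 2L] / vs[2L])
    iz <- floor(p[, 3L] / vs[3L])
    inside <- ix >= 0 & ix < dims[1L] & iy >= 0 & iy < dims[2L] &
      iz >= 0 & iz < dims[3L]
    out <- rep(NA_integer_, nrow(p))
    out[inside] <- as.integer(iz[inside] * dims[1L] * dims[2L] +
                              iy[inside] * dims[1L] + ix[inside] + 1L)
    out
  }

  n <- nrow(seeds)
  v0 <- vox_lin(seeds)
  ok0 <- !is.na(v0) & npk[pmax(v0, 1L)] > 0L & !is.na(npk[pmax(v0, 1L)])
  ok0[is.na(ok0)] <- FALSE
  init_dir <- matrix(0, n, 3L)
  init_dir[ok0, ] <- pdir[v0[ok0], 1L, ]

  run_half <- function(sign_dir, budget) {
    pos <- seeds
    dir <- sign_dir * init_dir
    active <- ok0 & budget > 0L
    hist <- array(NA_real_, c(max_steps, n, 3L))
    nsteps <- integer(n)
    for (s in seq_len(max_steps)) {
      if (!any(active)) break
      ia <- which(active)
      p <- pos[ia, , drop = FALSE]
      d <- dir[ia, , drop = FALSE]
      v <- vox_lin(p)
      alive <- !is.na(v)
      vv <- v[alive]
      if (length(vv)) alive[alive] <- npk[vv] > 0L
      # choose, per streamline, the candidate peak with the largest
      # |cos(angle to incoming direction)|; ties -> lowest peak index
      best_cos <- rep(-Inf, length(ia))
      best_j <- integer(length(ia))
      for (j in seq_len(max_pk)) {
        u <- matrix(0, length(ia), 3L)
        has <- alive & npk[pmax(v, 1L)] >= j
        if (!any(has)) next
        u[has, ] <- pdir[v[has], j, ]
        cj <- abs(rowSums(u * d))
        better <- has & cj > best_cos + 1e-12
        best_cos[better] <- cj[better]
        best_j[better] <- j
      }
      qa_ok <- rep(FALSE, length(ia))
      has_pk <- alive & best_j > 0L
      qa_ok[has_pk] <- pqa[cbind(v[has_pk], best_j[has_pk])] >=
        cfg$qa_termination_threshold
      cont <- alive & best_j > 0L & best_cos >= cos_thr & qa_ok
      if (any(cont)) {
        ic <- which(cont)
        u <- matrix(pdir[cbind(rep(v[ic], 3L),
                               rep(best_j[ic], 3L),
                               rep(1:3, each = length(ic)))],
                    ncol = 3L)
        sgn <- sign(rowSums(u * d[ic, , drop = FALSE]))
        sgn[sgn == 0] <- 1
        newd <- u * sgn
        newp <- p[ic, , drop = FALSE] + cfg$step_size_mm * newd
        gi <- ia[ic]
        pos[gi, ] <- newp
        dir[gi, ] <- newd
        hist[s, gi, ] <- newp
        nsteps[gi] <- s
      }
      active[ia[!cont]] <- FALSE
      active[active & nsteps >= budget] <- FALSE   # length budget spent
    }
    list(hist = hist, nsteps = nsteps)
  }

  # shared length budget: the forward half runs first; the backward half
  # may only spend what remains, so total length never exceeds the cap
  fwd <- run_half(+1, rep(max_steps, n))
  bwd <- run_half(-1, max_steps - fwd$nsteps)

  streamlines <- vector("list", n)
  keep <- logical(n)
  min_pts <- 2L
  for (k in seq_len(n)) {
    nf <- fwd$nsteps[k]; nb <- bwd$nsteps[k]
    npts <- nf + nb + 1L
    if (npts < min_pts) next
    len <- (nf + nb) * cfg$step_size_mm
    if (len < cfg$min_length_mm) next
    pts <- matrix(NA_real_, npts, 3L)
    if (nb > 0L) pts[1:nb, ] <- bwd$hist[nb:1, k, ]
    pts[nb + 1L, ] <- seeds[k, ]
    if (nf > 0L) pts[(nb + 2L):npts, ] <- fwd$hist[1:nf, k, ]
    streamlines[[k]] <- pts
    keep[k] <- TRUE
  }
  out <- tractogram(streamlines[keep], voxel_size = vs, grid_dim = dims,
                    affine = odf_field$affine,
                    provenance = list(config = unclass(cfg), n_seeds = n))
  out$seed_index <- which(keep)   # retained streamline k came from seed
  out
}
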