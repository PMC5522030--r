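#' Tract-length band presets
#'
#' Length filters separating the short-tract ("core") and long-tract
#' ("shell") populations: 1-20 / 25-55 mm at human scale (the 20-25 mm
#' gap belongs to neither population), 1-5 / 6-25 mm at rat scale.
#'
#' @param preset `"human"` or `"rat"`.
#' @return list with `core` and `shell`, each c(lo, hi) in mm.
#' @export
band_preset <- function(preset = c("human", "rat")) {
  preset <- match.arg(preset)
  switch(preset,
         human = list(core = c(1, 20), shell = c(25, 55)),
         rat = list(core = c(1, 5), shell = c(6, 25)))
}

#' Tract-length histogram
#'
#' @param tractogram a non-empty [tractogram()].
#' @param bin_width_mm bin width (mm).
#' @param lo_mm,hi_mm histogram domain; defaults span the observed
#'   lengths. Bins are `[a, a + w)` with the last bin closed, so counts
#'   always sum to the streamline count.
#' @return list with `breaks`, `mids`, `counts`.
#' @export
tract_length_histogram <- function(tractogram, bin_width_mm = 1,
                                   lo_mm = NULL, hi_mm = NULL) {
  stopifnot(inherits(tractogram, "tractogram"))
  len <- tractogram$lengths
  if (!length(len)) stop("cannot histogram an empty tractogram")
  if (is.null(lo_mm)) lo_mm <- floor(min(len) / bin_width_mm) * bin_width_mm
  if (is.null(hi_mm)) hi_mm <- lo_mm +
      ceiling((max(len) - lo_mm) / bin_width_mm + 1e-9) * bin_width_mm
  if (hi_mm <= lo_mm) hi_mm <- lo_mm + bin_width_mm
  breaks <- seq(lo_mm,
                lo_mm + ceiling((hi_mm - lo_mm) / bin_width_mm - 1e-9) *
                  bin_width_mm, by = bin_width_mm)
  if (any(len < lo_mm - 1e-9 | len > hi_mm + 1e-9))
    stop("histogram domain does not cover all tract lengths")
  hi_mm <- breaks[length(breaks)]
  len <- pmin(pmax(len, lo_mm), hi_mm)   # guard fp round-off at the edges
  h <- graphics::hist(len, breaks = breaks, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  list(breaks = breaks, mids = h$mids, counts = h$counts)
}

#' Count modes of a histogram after moving-average smoothing
#'
#' Local maxima of the smoothed counts are found first (plateaus
#' collapse to single candidates); two neighbouring maxima then count as
#' separate modes only when the valley between them dips below
#' `valley_ratio` times the smaller of the two peaks, so sampling
#' wiggles on a monotone flank are not reported as modes. Used to check
#' the bimodality of core-shell tract-length distributions.
#'
#' @param counts integer vector of bin counts.
#' @param smooth odd moving-average window (bins).
#' @param valley_ratio separation requirement in (0, 1]; 1 reduces to
#'   plain local-maximum counting.
#' @return number of distinct modes.
#' @export
histogram_modes <- function(counts, smooth = 3L, valley_ratio = 0.5) {
  k <- rep(1 / smooth, smooth)
  s <- stats::filter(counts, k, sides = 2L)
  s[is.na(s)] <- 0
  s <- as.numeric(s)
  n <- length(s)
  if (n < 3L) return(as.integer(n > 0L && any(s > 0)))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[j]) j <- j + 1L
      if (j <= n - 1L && s[j + 1L] < s[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(peaks) < 2L) return(length(peaks))
  # merge neighbouring peaks whose separating valley is too shallow
  repeat {
    if (length(peaks) < 2L) break
    merged <- FALSE
    for (p in seq_len(length(peaks) - 1L)) {
      valley <- min(s[peaks[p]:peaks[p + 1L]])
      if (valley > valley_ratio * min(s[peaks[p]], s[peaks[p + 1L]])) {
        drop <- if (s[peaks[p]] <= s[peaks[p + 1L]]) p else p + 1L
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  length(peaks)
}

#' Two-component Gaussian mixture fit by EM
#'
#' Fits a univariate two-component Gaussian mixture to tract lengths by
#' expectation-maximization. Initialization is deterministic: the sample
#' is split at its median and each half provides a component mean and
#' standard deviation. Variances are floored at `1e-6 * range^2`; a fit
#' that hits the floor is flagged degenerate. Components are reported
#' sorted by ascending mean.
#'
#' @param lengths numeric vector (>= 10 positive observations).
#' @param seed accepted for interface stability; the median-split
#'   initialization makes the fit deterministic, so it is unused.
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param max_iter iteration cap.
#' @return object of class `gmm_fit` with `means`, `sds`, `proportions`
#'   (ascending-mean order), `loglik`, `converged`, `n_iter`,
#'   `degenerate`.
#' @export
fit_bigaussian <- function(lengths, seed = 0L, tol = 1e-8,
                           max_iter = 500L) {
  x <- as.numeric(lengths)
  if (length(x) < 10L) stop("need at least 10 observations")
  if (any(x <= 0)) stop("tract lengths must be positive")
  n <- length(x)
  var_floor <- 1e-6 * (max(x) - min(x))^2
  if (var_floor == 0) var_floor <- 1e-12
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) { lo <- x[x < med]; hi <- x[x >= med] }
  if (!length(lo) || !length(hi)) {
    # all observations identical: one effective component
    v <- x[1L]
    return(structure(list(means = c(v, v),
                          sds = rep(sqrt(var_floor), 2L),
                          proportions = c(0.5, 0.5),
                          loglik = NA_real_, converged = TRUE,
                          n_iter = 0L, degenerate = TRUE),
                     class = "gmm_fit"))
  }
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(stats::sd(lo), stats::sd(hi)), sqrt(var_floor))
  sg[is.na(sg)] <- sqrt(var_floor)
  pi_ <- c(length(lo), length(hi)) / n
  ll_old <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- pi_[1L] * stats::dnorm(x, mu[1L], sg[1L])
    d2 <- pi_[2L] * stats::dnorm(x, mu[2L], sg[2L])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    mu[1L] <- sum(g1 * x) / n1
    mu[2L] <- sum((1 - g1) * x) / n2
    v1 <- sum(g1 * (x - mu[1L])^2) / n1
    v2 <- sum((1 - g1) * (x - mu[2L])^2) / n2
    if (v1 < var_floor || v2 < var_floor) degenerate <- TRUE
    sg <- sqrt(pmax(c(v1, v2), var_floor))
    pi_ <- c(n1, n2) / n
  }
  ord <- order(mu)
  structure(list(means = mu[ord], sds = sg[ord],
                 proportions = pi_[ord] / sum(pi_),
                 loglik = ll, converged = converged, n_iter = it,
                 degenerate = degenerate),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "Bi-Gaussian fit: means %.4f / %.4f mm, sd %.4f / %.4f, prop %.3f / %.3f (%s, %d EM iterations)\n",
    x$means[1L], x$means[2L], x$sds[1L], x$sds[2L],
    x$proportions[1L], x$proportions[2L],
    if (x$converged) "converged" else "not converged", x$n_iter))
  if (x$degenerate) cat("  note: variance floor was hit\n")
  invisible(x)
}

#' Sample from a two-component Gaussian mixture
#'
#' @param n number of draws.
#' @param means,sds,proportions component parameters (length 2).
#' @param seed RNG seed.
#' @param truncate_positive resample non-positive draws (tract lengths
#'   are positive by definition; with components a few sd above zero the
#'   induced bias is far below the component means).
#' @return numeric vector of length `n`.
#' @export
sample_bigaussian <- function(n, means, sds, proportions, seed = 0L,
                              truncate_positive = FALSE) {
  stopifnot(length(means) == 2L, length(sds) == 2L,
            abs(sum(proportions) - 1) < 1e-9)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  comp <- stats::rbinom(n, 1L, proportions[2L]) + 1L
  x <- stats::rnorm(n, means[comp], sds[comp])
  if (truncate_positive) {
    while (any(x <= 0)) {
      i <- which(x <= 0)
      x[i] <- stats::rnorm(length(i), means[comp[i]], sds[comp[i]])
    }
  }
  x
}

# Resample a polyline at uniform arc-length spacing; both end points are
# always retained (the final spacing may be shorter than the step).
resample_streamline <- function(points, step_mm) {
  seg <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step_mm)
  if (s[length(s)] < total) s <- c(s, total)   # keep the end point
  sapply(1:3, function(k)
    stats::approx(cum, points[, k], xout = s, ties = "ordered")$y)
}

#' Tumor centre from tract points
#'
#' The mean tumor location: every streamline is resampled to uniform
#' arc-length spacing (1 mm at human scale, 0.1 mm at rat scale) and the
#' centre is the unweighted mean of all resampled points.
#'
#' @param tractogram a non-empty [tractogram()].
#' @param resample_step_mm resampling step (mm).
#' @return length-3 world-mm centre.
#' @export
tumor_center <- function(tractogram, resample_step_mm = 1) {
  stopifnot(inherits(tractogram, "tractogram"))
  if (!length(tractogram$streamlines)) stop("empty tractogram")
  pts <- do.call(rbind, lapply(tractogram$streamlines,
                               resample_streamline,
                               step_mm = resample_step_mm))
  colMeans(pts)
}

#' Equal-area concentric ring radii
#'
#' `r_i = R * sqrt(i / n)` for i = 1..n, so the n annuli
#' (r_{i-1}, r_i] have equal area `pi R^2 / n` under the circular model.
#'
#' @param R tumor radius (mm), > 0.
#' @param n_rings number of rings (>= 1).
#' @return numeric vector of n radii, ending at R.
#' @export
ring_radii <- function(R, n_rings = 4L) {
  if (R <= 0) stop("R must be positive")
  if (n_rings < 1L) stop("n_rings must be >= 1")
  R * sqrt(seq_len(n_rings) / n_rings)
}

#' Radial ring profile of tract length
#'
#' Restricts tract points to an axial slab around the tumor centre
#' (|z - center_z| within `z_fraction` of the tract set's z half-extent),
#' recenters x, y on the centre, and sorts tracts into concentric
#' equal-area rings using the in-plane point radius
#' `r_t = sqrt(x^2 + y^2)`. The outermost radius R is the largest `r_t`
#' in the slab. A tract is assigned to every ring whose annulus contains
#' at least one of its slab points (so ring populations overlap for
#' crossing tracts and ring means are not independent); each ring
#' reports the mean length of its assigned tracts.
#'
#' @param tractogram a non-empty [tractogram()].
#' @param center world-mm tumor centre (see [tumor_center()]).
#' @param z_fraction slab half-thickness as a fraction of the z
#'   half-extent.
#' @param n_rings number of equal-area rings.
#' @param elliptical normalize x and y by the slab's half-extents
#'   before computing point radii, turning the rings into nested
#'   ellipses for elongated tumors; off by default (the point-radius
#'   formula is circular).
#' @return object of class `ring_profile` with `center`, `R`, `radii`,
#'   `mean_length`, `count`.
#' @export
ring_profile <- function(tractogram, center, z_fraction = 0.2,
                         n_rings = 4L, elliptical = FALSE) {
  stopifnot(inherits(tractogram, "tractogram"))
  if (!length(tractogram$streamlines)) stop("empty tractogram")
  zs <- unlist(lapply(tractogram$streamlines, function(p) p[, 3L]))
  half_ext <- max(abs(zs - center[3L]))
  slab_halfwidth <- z_fraction * half_ext
  in_slab <- lapply(tractogram$streamlines, function(p)
    p[abs(p[, 3L] - center[3L]) <= slab_halfwidth, , drop = FALSE])
  npts <- vapply(in_slab, nrow, integer(1L))
  if (!any(npts > 0L)) stop("no tract points fall inside the axial slab")
  scale_xy <- c(1, 1)
  if (elliptical) {
    allp <- do.call(rbind, in_slab)
    scale_xy <- c(max(abs(allp[, 1L] - center[1L])),
                  max(abs(allp[, 2L] - center[2L])))
    scale_xy[scale_xy == 0] <- 1
  }
  rt <- lapply(in_slab, function(p)
    sqrt(((p[, 1L] - center[1L]) / scale_xy[1L])^2 +
           ((p[, 2L] - center[2L]) / scale_xy[2L])^2))
  R <- max(unlist(rt))
  if (R <= 0) stop("degenerate slab: all points at the centre")
  radii <- ring_radii(R, n_rings)
  lower <- c(0, radii[-n_rings])
  count <- integer(n_rings)
  mean_length <- rep(NA_real_, n_rings)
  assigned <- matrix(FALSE, length(rt), n_rings)
  for (i in seq_along(rt)) {
    r <- rt[[i]]
    if (!length(r)) next
    for (j in seq_len(n_rings)) {
      # ring 1 is the closed disc [0, r_1]; outer rings are (r_{j-1}, r_j]
      assigned[i, j] <- any(if (j == 1L) r <= radii[1L]
                            else r > lower[j] & r <= radii[j])
    }
  }
  for (j in seq_len(n_rings)) {
    sel <- assigned[, j]
    count[j] <- sum(sel)
    if (count[j]) mean_length[j] <- mean(tractogram$lengths[sel])
  }
  structure(list(center = center, R = R, radii = radii,
                 mean_length = mean_length, count = count,
                 z_fraction = z_fraction),
            class = "ring_profile")
}

#' @export
print.ring_profile <- function(x, ...) {
  cat("Ring profile: R = ", sprintf("%.2f", x$R), " mm\n", sep = "")
  for (j in seq_along(x$radii))
    cat(sprintf("  ring %d (r <= %.2f): %d tracts, mean length %.2f mm\n",
                j, x$radii[j], x$count[j], x$mean_length[j]))
  invisible(x)
}

#' Core/shell architecture metrics
#'
#' Applies the core and shell tract-length filters and summarizes the two
#' populations: mean band length, tract count, tract volume (number of
#' distinct voxels traversed times the voxel volume) and the c/s ratio,
#' defined as mean core-band length divided by mean shell-band length.
#' An empty band leaves the affected metrics `NA` and sets `flagged`.
#'
#' @param tractogram a [tractogram()].
#' @param core_band,shell_band c(lo, hi) length filters (mm); defaults
#'   are the human-scale bands.
#' @param voxel_size voxel dimensions (mm) for tract volumes; taken from
#'   the tractogram when available.
#' @return object of class `architecture_metrics`.
#' @export
compute_architecture <- function(tractogram,
                                 core_band = band_preset("human")$core,
                                 shell_band = band_preset("human")$shell,
                                 voxel_size = NULL) {
  stopifnot(inherits(tractogram, "tractogram"))
  if (is.null(voxel_size)) voxel_size <- tractogram$voxel_size
  core <- filter_by_length(tractogram, core_band[1L], core_band[2L])
  shell <- filter_by_length(tractogram, shell_band[1L], shell_band[2L])
  n_core <- length(core$streamlines)
  n_shell <- length(shell$streamlines)
  core_mean <- if (n_core) mean(core$lengths) else NA_real_
  shell_mean <- if (n_shell) mean(shell$lengths) else NA_real_
  cs_ratio <- if (n_core && n_shell) core_mean / shell_mean else NA_real_
  tract_volume <- function(tg) {
    if (!length(tg$streamlines) || is.null(voxel_size)) return(NA_real_)
    pts <- do.call(rbind, tg$streamlines)
    vox <- unique(cbind(floor(pts[, 1L] / voxel_size[1L]),
                        floor(pts[, 2L] / voxel_size[2L]),
                        floor(pts[, 3L] / voxel_size[3L])))
    nrow(vox) * prod(voxel_size)
  }
  structure(list(core_mean_length = core_mean,
                 shell_mean_length = shell_mean,
                 cs_ratio = cs_ratio,
                 core_count = n_core, shell_count = n_shell,
                 core_volume = tract_volume(core),
                 shell_volume = tract_volume(shell),
                 whole_mean_length = if (length(tractogram$lengths))
                   mean(tractogram$lengths) else NA_real_,
                 core_band = core_band, shell_band = shell_band,
                 flagged = n_core == 0L || n_shell == 0L),
            class = "architecture_metrics")
}

#' @export
print.architecture_metrics <- function(x, ...) {
  cat(sprintf(
    "Architecture: core %.4f mm (n=%d), shell %.4f mm (n=%d), c/s ratio %.5f%s\n",
    x$core_mean_length, x$core_count, x$shell_mean_length, x$shell_count,
    x$cs_ratio, if (x$flagged) " [flagged: empty band]" else ""))
  invisible(x)
}
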