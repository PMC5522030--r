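#' Antipodally symmetric sphere tessellation
#'
#' Subdivides the regular icosahedron `level` times (each subdivision
#' splits every face into four) and projects vertices onto the unit
#' sphere, yielding `10 * 4^level + 2` vertices. The icosahedron is
#' centrosymmetric and subdivision preserves that, so every vertex has its
#' exact antipode in the set; antipodal pairs are snapped to exact
#' negation so that orientation functions evaluated on the tessellation
#' are symmetric by construction.
#'
#' @param subdivision_level non-negative integer.
#' @return object of class `sphere_tessellation` with `vertices`
#'   (V x 3 unit vectors), `neighbors` (list of integer vectors, symmetric
#'   relation from the triangulation edges), `antipode` (index of -v for
#'   every v) and `max_edge_deg` (largest neighbor angle, degrees).
#' @export
tessellate_sphere <- function(subdivision_level = 3L) {
  if (subdivision_level < 0) stop("subdivision_level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(subdivision_level)) {
    edge_key <- new.env(hash = TRUE)
    nv <- nrow(verts)
    new_faces <- matrix(0L, nrow(faces) * 4L, 3L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_key[[key]]
      if (!is.null(m)) return(m)
      p <- verts[i, ] + verts[j, ]
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      m <- nrow(verts)
      edge_key[[key]] <- m
      m
    }
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1L]; b <- faces[f, 2L]; c_ <- faces[f, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      new_faces[(f - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    faces <- new_faces
  }
  # snap antipodal pairs to exact negation
  antipode <- integer(nrow(verts))
  done <- logical(nrow(verts))
  for (i in seq_len(nrow(verts))) {
    if (done[i]) next
    d <- rowSums(sweep(verts, 2L, -verts[i, ])^2)
    j <- which.min(d)
    if (d[j] > 1e-6)
      stop("tessellation lost antipodal symmetry")  # construction guarantee
    verts[j, ] <- -verts[i, ]
    antipode[i] <- j; antipode[j] <- i
    done[i] <- TRUE; done[j] <- TRUE
  }
  neighbors <- vector("list", nrow(verts))
  edges <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  edges <- unique(rbind(edges, edges[, 2:1]))
  nb <- split(edges[, 2L], edges[, 1L])
  for (i in seq_along(nb))
    neighbors[[as.integer(names(nb)[i])]] <- sort(unique(nb[[i]]))
  cos_edges <- rowSums(verts[edges[, 1L], ] * verts[edges[, 2L], ])
  structure(list(vertices = verts, neighbors = neighbors,
                 antipode = antipode,
                 max_edge_deg = max(acos(pmin(cos_edges, 1)) * 180 / pi)),
            class = "sphere_tessellation")
}

#' @export
print.sphere_tessellation <- function(x, ...) {
  cat("Sphere tessellation: ", nrow(x$vertices), " vertices, max edge ",
      sprintf("%.2f", x$max_edge_deg), " deg\n", sep = "")
  invisible(x)
}

#' GQI reconstruction configuration
#'
#' @param l_delta diffusion sampling length ratio of the sinc kernel
#'   (dimensionless; 1.25 is the standard choice for in-vivo data).
#' @param d0 free-water reference diffusivity (mm^2/s) used to convert
#'   b-values into sampling lengths.
#' @param subdivision_level icosphere subdivision for ODF evaluation.
#' @param qa_threshold peaks with globally normalized quantitative
#'   anisotropy below this are dropped.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(l_delta = 1.25, d0 = 2.5e-3,
                         subdivision_level = 3L, qa_threshold = 0.05) {
  if (l_delta <= 0) stop("l_delta must be positive")
  if (d0 <= 0) stop("d0 must be positive")
  structure(list(l_delta = l_delta, d0 = d0,
                 subdivision_level = as.integer(subdivision_level),
                 qa_threshold = qa_threshold),
            class = "recon_config")
}

#' GQI sinc kernel matrix
#'
#' Entry (i, v) is `sinc(l_delta * sqrt(6 * d0 * b_i) * <g_i, u_v>)` with
#' `sinc(x) = sin(x) / x`, `sinc(0) = 1`. The spin distribution function of
#' a voxel is the signal vector times this matrix. The kernel argument is
#' odd in u and sinc is even, so the resulting ODF is antipodally
#' symmetric exactly.
#'
#' @param scheme a [gradient_scheme()].
#' @param vertices V x 3 unit directions.
#' @param l_delta,d0 see [recon_config()].
#' @return N x V kernel matrix.
#' @export
gqi_kernel <- function(scheme, vertices, l_delta = 1.25, d0 = 2.5e-3) {
  scale <- l_delta * sqrt(6 * d0 * scheme$bvals)   # per-volume
  x <- (scale * scheme$bvecs) %*% t(vertices)
  k <- sin(x) / x
  k[abs(x) < 1e-12] <- 1
  k
}

#' Reconstruct per-voxel spin distribution functions
#'
#' Evaluates the GQI sinc-kernel summation at every tessellation vertex
#' for every masked voxel and extracts up to three peaks per voxel with
#' quantitative anisotropy (QA). QA of a peak is its ODF value minus the
#' voxel's ODF minimum, scaled by the maximum such difference over the
#' whole masked region so that QA lies in the unit interval. Voxels whose signal is
#' identically zero are flagged degenerate, receive a zero ODF and no
#' peaks (so tracking terminates there).
#'
#' @param dwi a [dwi_volume()].
#' @param mask a [voxel_mask()] selecting the voxels to reconstruct.
#' @param cfg a [recon_config()].
#' @return object of class `odf_field` with `voxels` (n x 3 1-based
#'   indices), `values` (n x V), `peak_dirs` (n x 3 x 3), `qa` (n x 3),
#'   `n_peaks`, `degenerate`, the tessellation and grid geometry.
#' @export
reconstruct_odf <- function(dwi, mask, cfg = recon_config()) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(mask, "voxel_mask"))
  if (!any(mask$mask)) stop("mask is empty")
  dims <- dim(dwi$data)[1:3]
  if (!all(dim(mask$mask) == dims))
    stop("mask shape does not match DWI volume")
  tess <- tessellate_sphere(cfg$subdivision_level)
  kernel <- gqi_kernel(dwi$scheme, tess$vertices, cfg$l_delta, cfg$d0)
  vox <- which(mask$mask, arr.ind = TRUE)
  nvol <- dim(dwi$data)[4L]
  sig <- matrix(aperm(dwi$data, c(4L, 1L, 2L, 3L)), nrow = nvol)
  sig <- t(sig[, as.vector(mask$mask), drop = FALSE])   # n_vox x N
  degenerate <- rowSums(sig) == 0
  values <- sig %*% kernel                         # n_vox x V
  values[values < 0] <- 0                          # numerical guard
  values[degenerate, ] <- 0
  # mirror one hemisphere onto the other so that psi(u) == psi(-u) holds
  # bitwise (optimized BLAS may round identical columns differently)
  hemi <- which(seq_len(ncol(values)) < tess$antipode)
  values[, tess$antipode[hemi]] <- values[, hemi]
  pk <- .peak_field(values, tess, cfg$qa_threshold)
  structure(list(voxels = vox, values = values,
                 peak_dirs = pk$dirs, qa = pk$qa, n_peaks = pk$n,
                 degenerate = degenerate, tessellation = tess,
                 grid_dim = dims, voxel_size = dwi$voxel_size,
                 affine = dwi$affine, config = cfg),
            class = "odf_field")
}

#' @export
print.odf_field <- function(x, ...) {
  cat("ODF field: ", nrow(x$voxels), " voxels, ",
      nrow(x$tessellation$vertices), " directions, ",
      sum(x$n_peaks > 0), " voxels with peaks\n", sep = "")
  invisible(x)
}

# Vectorized strict-local-maximum peak extraction over a matrix of ODFs
# (rows = voxels). Returns up to 3 antipodally deduplicated peaks per
# voxel, sorted by descending QA. QA is normalized by `qa_scale` (the
# maximum peak-minus-minimum difference over all rows when NULL).
.peak_field <- function(values, tess, qa_threshold, qa_scale = NULL) {
  n <- nrow(values); nv <- ncol(values)
  nbmax <- matrix(-Inf, n, nv)
  for (v in seq_len(nv)) {
    nb <- tess$neighbors[[v]]
    nbmax[, v] <- do.call(pmax, lapply(nb, function(j) values[, j]))
  }
  is_peak <- values > nbmax                         # strict local maximum
  # antipodal dedup: keep the lower vertex index of each +/- pair
  keep <- seq_len(nv) < tess$antipode
  is_peak[, !keep] <- FALSE
  odf_min <- apply(values, 1L, min)
  raw_qa <- (values - odf_min) * is_peak
  if (is.null(qa_scale)) qa_scale <- max(raw_qa)
  if (qa_scale <= 0) qa_scale <- 1
  dirs <- array(0, c(n, 3L, 3L))
  qa <- matrix(0, n, 3L)
  npk <- integer(n)
  for (i in seq_len(n)) {
    pv <- which(is_peak[i, ])
    if (!length(pv)) next
    q <- raw_qa[i, pv] / qa_scale
    ord <- order(q, decreasing = TRUE)
    pv <- pv[ord]; q <- q[ord]
    sel <- which(q >= qa_threshold)
    sel <- sel[seq_len(min(3L, length(sel)))]
    if (!length(sel)) next
    pv <- pv[sel]; q <- q[sel]
    npk[i] <- length(pv)
    dirs[i, seq_along(pv), ] <- tess$vertices[pv, , drop = FALSE]
    qa[i, seq_along(pv)] <- q
  }
  list(dirs = dirs, qa = qa, n = npk, qa_scale = qa_scale)
}

#' Extract ODF peaks for a single voxel
#'
#' A vertex is a peak iff its ODF value strictly exceeds all of its
#' neighbors' values; antipodal pairs collapse to a single direction. A
#' constant ODF therefore has no peaks. Peaks are sorted by descending
#' quantitative anisotropy (peak value minus the ODF minimum, divided by
#' `qa_scale`), peaks with QA below `qa_threshold` are dropped, and at
#' most three are retained.
#'
#' @param odf_values numeric vector, one value per tessellation vertex.
#' @param tessellation a [tessellate_sphere()] result.
#' @param qa_threshold minimum normalized QA.
#' @param qa_scale normalization constant; defaults to this voxel's
#'   largest peak-minus-minimum difference (use the field-wide maximum
#'   when comparing voxels).
#' @return list with `directions` (k x 3), `qa` (length k, descending).
#' @export
extract_peaks <- function(odf_values, tessellation, qa_threshold = 0.05,
                          qa_scale = NULL) {
  if (length(odf_values) != nrow(tessellation$vertices))
    stop("odf_values length must equal the tessellation vertex count")
  pk <- .peak_field(matrix(odf_values, nrow = 1L), tessellation,
                    qa_threshold = qa_threshold, qa_scale = qa_scale)
  k <- pk$n[1L]
  if (k == 0L)
    return(list(directions = matrix(0, 0L, 3L), qa = numeric(0)))
  dirs <- matrix(pk$dirs[1L, seq_len(k), ], ncol = 3L)
  list(directions = dirs, qa = pk$qa[1L, seq_len(k)])
}
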