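#' Diffusion-weighted volumes and masks
#'
#' A `dwi_volume` bundles a 4D signal grid (X x Y x Z x N, arbitrary signal
#' units, non-negative) with its voxel dimensions (mm), gradient scheme and
#' a voxel-to-world affine. Volume `i` always pairs with gradient entry `i`;
#' readers never reorder.
#'
#' World coordinates are millimetres. The affine maps 0-based voxel indices
#' to voxel-centre world coordinates; the default grid-aligned affine places
#' the centre of voxel (0,0,0) at `voxel_size / 2` so that the voxel
#' containing world point p is `floor(p / voxel_size)`.
#'
#' @param data 4D numeric array, no negative entries.
#' @param voxel_size length-3 positive numeric (mm).
#' @param scheme a [gradient_scheme()] with one entry per volume.
#' @param affine optional 4 x 4 voxel-to-world matrix; defaults to the
#'   grid-aligned affine described above.
#' @return object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size, scheme, affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("DWI data must be 4D, got ", length(dim(data)), "D")
  if (any(data < 0)) stop("DWI data contains negative values")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (dim(data)[4L] != length(scheme$bvals))
    stop("volume count mismatch: image has ", dim(data)[4L],
         " volumes but gradient table has ", length(scheme$bvals),
         " entries")
  if (is.null(affine)) affine <- grid_affine(voxel_size)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, voxel_size = voxel_size, scheme = scheme,
                 affine = affine),
            class = "dwi_volume")
}

grid_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4L] <- voxel_size / 2
  a
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("DWI volume: ", paste(d[1:3], collapse = " x "), " voxels x ", d[4L],
      " volumes, voxel ", paste(x$voxel_size, collapse = " x "), " mm\n",
      sep = "")
  print(x$scheme)
  invisible(x)
}

#' Binary voxel masks
#'
#' @param mask logical (or 0/1) 3D array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param voxel_size length-3 voxel dimensions (mm).
#' @return object of class `voxel_mask` (logical array plus geometry).
#' @export
voxel_mask <- function(mask, voxel_size, affine = NULL) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be 3D")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be binary (0/1)")
  if (is.null(affine)) affine <- grid_affine(voxel_size)
  structure(list(mask = array(as.logical(mask), dim(mask)),
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "voxel_mask")
}

#' Read a 4D diffusion acquisition
#'
#' Reads a NIfTI image together with FSL-style `bvals`/`bvecs` text files
#' and validates that the gradient table matches the number of volumes.
#'
#' @param image_path path to a 4D NIfTI (.nii / .nii.gz).
#' @param bvals_path,bvecs_path FSL-style gradient table paths.
#' @return a [dwi_volume()].
#' @export
read_dwi <- function(image_path, bvals_path, bvecs_path) {
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D image, got ", length(d), "D: ", image_path)
  scheme <- read_gradients(bvals_path, bvecs_path)
  if (d[4L] != length(scheme$bvals))
    stop("volume count mismatch: image has ", d[4L],
         " volumes but gradient table has ", length(scheme$bvals),
         " entries")
  vs <- RNifti::pixdim(img)[1:3]
  dwi_volume(array(as.numeric(img), d), vs, scheme)
}

#' Write a diffusion acquisition to NIfTI + gradient table
#'
#' @param dwi a [dwi_volume()].
#' @param image_path output NIfTI path (.nii or .nii.gz).
#' @param bvals_path,bvecs_path output gradient table paths.
#' @return invisibly, the image path.
#' @export
write_dwi <- function(dwi, image_path, bvals_path, bvecs_path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, image_path)
  write_gradients(dwi$scheme, bvals_path, bvecs_path)
  invisible(image_path)
}

#' Read a binary mask aligned to a companion DWI volume
#'
#' @param path 3D NIfTI path.
#' @param companion the [dwi_volume()] the mask must align with.
#' @param binarize if TRUE, any strictly positive value becomes TRUE (use
#'   for label images); if FALSE the image must already be binary.
#' @param require_nonempty error on an all-zero mask (tumor masks must
#'   select at least one voxel).
#' @return a [voxel_mask()].
#' @export
read_mask <- function(path, companion, binarize = FALSE,
                      require_nonempty = TRUE) {
  stopifnot(inherits(companion, "dwi_volume"))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) { d <- d[1:3]; dim(img) <- d }
  if (length(d) != 3L) stop("mask must be 3D: ", path)
  dc <- dim(companion$data)[1:3]
  if (!all(d == dc))
    stop("mask shape ", paste(d, collapse = "x"),
         " does not match companion volume ", paste(dc, collapse = "x"))
  m <- array(as.numeric(img), d)
  if (binarize) m <- m > 0 else if (!all(unique(as.vector(m)) %in% c(0, 1)))
    stop("mask is not binary; pass binarize = TRUE for label images")
  if (require_nonempty && !any(m > 0)) stop("mask is empty: ", path)
  voxel_mask(m > 0, companion$voxel_size, companion$affine)
}

#' Write a mask (or integer label image) as NIfTI
#'
#' @param mask a [voxel_mask()] or a 3D numeric array.
#' @param path output path.
#' @param voxel_size voxel dimensions (mm); taken from the mask object when
#'   one is supplied.
#' @return invisibly, the path.
#' @export
write_mask <- function(mask, path, voxel_size = NULL) {
  if (inherits(mask, "voxel_mask")) {
    arr <- array(as.numeric(mask$mask), dim(mask$mask))
    voxel_size <- mask$voxel_size
  } else {
    arr <- as.array(mask)
    if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TrackVis TRK tractogram format (version 2, little-endian, 1000-byte header).
# Points are stored in world millimetres; vox_to_ras carries the source
# affine. No installed R package reads TRK, so the format is implemented
# here directly against the published header layout.

#' Write a tractogram in TrackVis TRK format
#'
#' @param tractogram a [tractogram()].
#' @param path output .trk path.
#' @param dim,voxel_size spatial grid of the source volume (stored in the
#'   header); defaults come from the tractogram's provenance when present.
#' @return invisibly, the path.
#' @export
write_tractogram <- function(tractogram, path, dim = NULL,
                             voxel_size = NULL) {
  stopifnot(inherits(tractogram, "tractogram"))
  if (is.null(dim)) dim <- tractogram$grid_dim %||% c(0L, 0L, 0L)
  if (is.null(voxel_size))
    voxel_size <- tractogram$voxel_size %||% c(1, 1, 1)
  affine <- tractogram$affine %||% grid_affine(voxel_size)
  con <- file(path, "wb")
  on.exit(close(con))
  put_chars <- function(s, width) {
    b <- charToRaw(s)
    writeBin(c(b, raw(width - length(b))), con)
  }
  put_chars("TRACK", 6L)                             # id_string (6 bytes)
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(rep(0, 3), con, size = 4L, endian = "little")     # origin
  writeBin(0L, con, size = 2L, endian = "little")            # n_scalars
  writeBin(raw(200L), con)                                   # scalar names
  writeBin(0L, con, size = 2L, endian = "little")            # n_properties
  writeBin(raw(200L), con)                                   # property names
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                   # reserved
  put_chars("RAS", 4L)                                       # voxel_order
  writeBin(raw(4L), con)                                     # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  writeBin(raw(2L), con)                                     # pad1
  writeBin(raw(6L), con)                                     # invert/swap
  writeBin(length(tractogram$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")            # version
  writeBin(1000L, con, size = 4L, endian = "little")         # hdr_size
  for (pts in tractogram$streamlines) {
    writeBin(nrow(pts), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK tractogram
#'
#' @param path .trk path written by [write_tractogram()] or another tool
#'   storing world-mm coordinates.
#' @return a [tractogram()].
#' @export
read_tractogram <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id_raw <- readBin(con, raw(), 6L)
  id <- rawToChar(id_raw[id_raw != as.raw(0)])
  if (!identical(id, "TRACK")) stop("not a TRK file: ", path)
  dim <- readBin(con, integer(), 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, numeric(), 3L, size = 4L, endian = "little")
  invisible(readBin(con, numeric(), 3L, size = 4L, endian = "little"))
  n_scalars <- readBin(con, integer(), 1L, size = 2L, endian = "little")
  invisible(readBin(con, raw(), 200L))
  n_props <- readBin(con, integer(), 1L, size = 2L, endian = "little")
  invisible(readBin(con, raw(), 200L))
  affine <- matrix(readBin(con, numeric(), 16L, size = 4L,
                           endian = "little"), 4L, 4L, byrow = TRUE)
  invisible(readBin(con, raw(), 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  version <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("unsupported TRK header size: ", hdr_size)
  streamlines <- vector("list", n_count)
  for (k in seq_len(n_count)) {
    npts <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    vals <- readBin(con, numeric(), npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    if (n_props > 0L)
      invisible(readBin(con, numeric(), n_props, size = 4L,
                        endian = "little"))
    streamlines[[k]] <- m[, 1:3, drop = FALSE]
  }
  tractogram(streamlines, voxel_size = voxel_size,
             grid_dim = dim, affine = affine, validate_spacing = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Survival cohort tables (CSV, header row, RFC-4180 via read.csv/write.csv).

.cohort_columns <- c("time_months", "event", "cs_ratio", "age", "kps",
                     "idh", "necrosis")

#' Read / write survival cohort tables
#'
#' Cohort CSVs carry one subject per row with columns `time_months`
#' (positive), `event` (1 = death, 0 = censored), `cs_ratio`, `age`, `kps`,
#' `idh` (0/1 mutant flag) and `necrosis` (fraction in `[0, 1]`).
#'
#' @param path CSV path.
#' @return `read_cohort` returns a validated `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(.cohort_columns, names(df))
  if (length(missing))
    stop("cohort CSV missing column(s): ", paste(missing, collapse = ", "))
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, .cohort_columns], path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  if (any(cohort$time_months <= 0))
    stop("survival times must be positive")
  if (!all(cohort$event %in% c(0, 1)))
    stop("event flags must be 0 (censored) or 1 (death)")
  if (any(cohort$necrosis < 0 | cohort$necrosis > 1))
    stop("necrosis fraction must lie in [0, 1]")
  invisible(TRUE)
}
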