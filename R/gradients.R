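#' Diffusion gradient schemes
#'
#' A gradient scheme pairs one b-value (s/mm^2) and one unit direction vector
#' with every volume of a diffusion acquisition. Directions belonging to
#' b=0 volumes may be zero vectors. Volumes below `b0_threshold` (50 s/mm^2)
#' are treated as b=0.
#'
#' @param bvals numeric vector of b-values (s/mm^2), all >= 0.
#' @param bvecs numeric N x 3 matrix of gradient directions; rows with
#'   `bvals > 0` must have Euclidean norm within 1e-3 of 1 and are
#'   renormalized to exact unit length.
#' @return an object of class `gradient_scheme` with elements `bvals`
#'   (numeric) and `bvecs` (N x 3 matrix).
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns (x, y, z), got ", ncol(bvecs))
  if (length(bvals) != nrow(bvecs))
    stop("gradient table length mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " direction vectors")
  if (any(bvals < 0))
    stop("negative b-value in gradient table: b = ", min(bvals))
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > .qsarch_b0_threshold
  bad <- dw & abs(nrm - 1) > 1e-3
  if (any(bad))
    stop("non-unit gradient direction at volume(s) ",
         paste(which(bad), collapse = ", "),
         " (|norm - 1| > 1e-3)")
  # renormalize small deviations so downstream dot products are exact
  fix <- dw & nrm > 0
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_scheme")
}

.qsarch_b0_threshold <- 50

#' @export
print.gradient_scheme <- function(x, ...) {
  nb0 <- sum(is_b0(x))
  cat("Gradient scheme: ", length(x$bvals), " volumes (",
      length(x$bvals) - nb0, " diffusion-weighted + ", nb0, " b0), b = ",
      paste(unique(round(x$bvals[!is_b0(x)])), collapse = "/"),
      " s/mm^2\n", sep = "")
  invisible(x)
}

#' Identify b=0 volumes of a scheme
#'
#' @param scheme a [gradient_scheme()].
#' @return logical vector, TRUE for volumes with b-value below 50 s/mm^2.
#' @export
is_b0 <- function(scheme) scheme$bvals < .qsarch_b0_threshold

#' Read / write FSL-style gradient tables
#'
#' The FSL dialect stores b-values as a single whitespace-separated row and
#' directions as three rows (x, y, z), one column per volume.
#'
#' @param bvals_path,bvecs_path text file paths.
#' @return `read_gradients` returns a [gradient_scheme()].
#' @export
read_gradients <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, what = numeric(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) != 3L)
    stop("bvecs file must have exactly 3 rows (x, y, z), got ", nrow(bv))
  if (ncol(bv) != length(bvals))
    stop("gradient table length mismatch: ", length(bvals), " b-values vs ",
         ncol(bv), " direction vectors")
  gradient_scheme(bvals, t(bv))
}

#' @rdname read_gradients
#' @param scheme a [gradient_scheme()] to serialize.
#' @export
write_gradients <- function(scheme, bvals_path, bvecs_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvals_path)
  m <- t(scheme$bvecs)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' Generate a quasi-uniform gradient scheme
#'
#' Places `n_directions` unit vectors quasi-uniformly on the hemisphere by
#' electrostatic repulsion between every point and both antipodes of every
#' other point, the standard construction for diffusion sampling schemes.
#' Deterministic for a fixed seed.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6; fewer
#'   cannot constrain an orientation estimate).
#' @param b_value b-value of the weighted volumes (s/mm^2).
#' @param include_b0 prepend one b=0 volume with a zero direction.
#' @param seed RNG seed for the initial configuration.
#' @param n_iter repulsion iterations.
#' @return a [gradient_scheme()] with `n_directions` (+1 if `include_b0`)
#'   entries.
#' @export
make_gradient_scheme <- function(n_directions, b_value, include_b0 = TRUE,
                                 seed = 0L, n_iter = 200L) {
  if (n_directions < 6L)
    stop("n_directions must be >= 6 for orientation estimation, got ",
         n_directions)
  if (b_value < 0) stop("b_value must be >= 0")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  x <- matrix(stats::rnorm(3L * n_directions), ncol = 3L)
  x <- x / sqrt(rowSums(x^2))
  step <- 0.1
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n_directions, 3L)
    for (i in seq_len(n_directions)) {
      d1 <- sweep(x, 2L, x[i, ])        # x_j - x_i
      r1 <- sqrt(rowSums(d1^2)); r1[i] <- Inf
      d2 <- sweep(-x, 2L, x[i, ])       # -x_j - x_i (antipodes)
      r2 <- sqrt(rowSums(d2^2))
      r2[r2 < 1e-9] <- Inf
      frc[i, ] <- -colSums(d1 / r1^3) - colSums(d2 / r2^3)
    }
    # project onto tangent plane and take a small step
    frc <- frc - x * rowSums(frc * x)
    x <- x + step * frc / max(sqrt(rowSums(frc^2)), 1e-12)
    x <- x / sqrt(rowSums(x^2))
    step <- step * 0.985
  }
  # canonical hemisphere (z >= 0) for reproducible sign convention
  flip <- x[, 3L] < 0
  x[flip, ] <- -x[flip, , drop = FALSE]
  if (include_b0) {
    bvals <- c(0, rep(b_value, n_directions))
    bvecs <- rbind(c(0, 0, 0), x)
  } else {
    bvals <- rep(b_value, n_directions)
    bvecs <- x
  }
  gradient_scheme(bvals, bvecs)
}

# Save/restore the global RNG state so seeded generators are pure functions.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Minimum pairwise angular separation of a scheme
#'
#' Angles are computed modulo the antipodal symmetry of diffusion sampling
#' (a direction and its negation are equivalent).
#'
#' @param bvecs N x 3 matrix of unit directions (b0 rows excluded by caller).
#' @return smallest pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(bvecs) {
  g <- abs(bvecs %*% t(bvecs))
  diag(g) <- -Inf
  acos(pmin(max(g), 1)) * 180 / pi
}
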