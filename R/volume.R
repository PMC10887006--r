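#' Construct a volume
#'
#' A `volume` is a 3D scalar image together with its geometry: voxel spacing
#' (mm), world origin (mm) and a 3x3 orthonormal direction matrix mapping
#' voxel axes to world axes. World coordinates of the (0-based) voxel index
#' `i` are `origin + direction %*% (spacing * i)`.
#'
#' @param voxels 3D numeric array of intensities (arbitrary scanner units).
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, world position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal matrix (columns are voxel axis
#'   directions in world space).
#' @return An object of class `volume`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_mffc("`voxels` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_mffc("`spacing` must be 3 positive numbers")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop_mffc("`origin` must be 3 finite numbers")
  }
  direction <- as.matrix(direction)
  check_direction(direction)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume")
}

check_direction <- function(direction) {
  if (!is.matrix(direction) || !all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop_mffc("invalid geometry: direction matrix must be 3x3 orthonormal")
  }
  invisible(TRUE)
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file and extracts spacing, origin and direction
#' from its stored voxel-to-world transform.
#'
#' @param path path to a NIfTI file.
#' @return A [volume].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  lin <- xf[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(lin^2))
  spacing[spacing == 0] <- 1
  direction <- sweep(lin, 2, spacing, "/")
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  volume(vox, spacing = spacing, origin = xf[1:3, 4], direction = direction)
}

#' Write a volume to NIfTI
#'
#' @param v a [volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  img <- RNifti::asNifti(v$voxels)
  xf <- rbind(cbind(v$direction %*% diag(v$spacing), v$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Maps every voxel of the reference grid to world coordinates, pulls the
#' corresponding intensity from the moving volume by interpolation, and
#' returns a volume on exactly the reference geometry (used to bring
#' CE-T1WI onto the T2-Flair grid). Voxels that fall outside the moving
#' volume's domain are set to 0.
#'
#' @param moving [volume] supplying intensities.
#' @param reference [volume] supplying the output grid.
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @return A [volume] on the reference grid.
#' @export
resample_to_reference <- function(moving, reference,
                                  interpolation = c("linear", "nearest")) {
  stopifnot(inherits(moving, "volume"), inherits(reference, "volume"))
  interpolation <- match.arg(interpolation)
  check_direction(moving$direction)
  check_direction(reference$direction)

  rd <- dim(reference$voxels)
  idx <- as.matrix(expand.grid(i = seq_len(rd[1]) - 1,
                               j = seq_len(rd[2]) - 1,
                               k = seq_len(rd[3]) - 1))
  # world coords of reference voxels, then continuous voxel coords in moving
  world <- sweep(idx %*% diag(reference$spacing) %*% t(reference$direction),
                 2, reference$origin, "+")
  cont <- sweep(world, 2, moving$origin, "-") %*% moving$direction %*%
    diag(1 / moving$spacing)

  md <- dim(moving$voxels)
  vals <- if (interpolation == "nearest") {
    p <- round(cont)
    inside <- p[, 1] >= 0 & p[, 1] <= md[1] - 1 &
      p[, 2] >= 0 & p[, 2] <= md[2] - 1 &
      p[, 3] >= 0 & p[, 3] <= md[3] - 1
    out <- numeric(nrow(p))
    if (any(inside)) {
      lin <- p[inside, 1] + md[1] * (p[inside, 2] + md[2] * p[inside, 3]) + 1
      out[inside] <- moving$voxels[lin]
    }
    out
  } else {
    trilinear_gather(moving$voxels, cont)
  }
  volume(array(vals, dim = rd), spacing = reference$spacing,
         origin = reference$origin, direction = reference$direction)
}

# Trilinear interpolation at continuous 0-based coordinates (rows of `cont`);
# corners outside the array contribute 0.
trilinear_gather <- function(vox, cont) {
  d <- dim(vox)
  f <- floor(cont)
  w <- cont - f
  out <- numeric(nrow(cont))
  for (corner in 0:7) {
    o <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    p1 <- f[, 1] + o[1]; p2 <- f[, 2] + o[2]; p3 <- f[, 3] + o[3]
    wt <- (if (o[1] == 1) w[, 1] else 1 - w[, 1]) *
      (if (o[2] == 1) w[, 2] else 1 - w[, 2]) *
      (if (o[3] == 1) w[, 3] else 1 - w[, 3])
    inside <- p1 >= 0 & p1 <= d[1] - 1 & p2 >= 0 & p2 <= d[2] - 1 &
      p3 >= 0 & p3 <= d[3] - 1 & wt > 0
    if (any(inside)) {
      lin <- p1[inside] + d[1] * (p2[inside] + d[2] * p3[inside]) + 1
      out[inside] <- out[inside] + wt[inside] * vox[lin]
    }
  }
  out
}

#' Window intensities to mean +/- 3 sd
#'
#' Computes the mean and population standard deviation of all voxels and
#' clips every voxel into `[mu - k*sigma, mu + k*sigma]`. A constant volume
#' (sigma = 0) is returned unchanged.
#'
#' @param v a [volume] or numeric array.
#' @param nsigma half-width of the window in standard deviations (default 3).
#' @return Same type as the input, windowed.
#' @export
intensity_window <- function(v, nsigma = 3) {
  vox <- if (inherits(v, "volume")) v$voxels else v
  if (length(vox) == 0) stop_mffc("empty volume")
  mu <- mean(vox)
  sigma <- sqrt(mean((vox - mu)^2))  # population sd
  if (sigma > 0) {
    vox <- pmin(pmax(vox, mu - nsigma * sigma), mu + nsigma * sigma)
  }
  if (inherits(v, "volume")) {
    v$voxels <- vox
    v
  } else {
    vox
  }
}

#' Extract an axial slice stack from a volume
#'
#' @param v a [volume].
#' @param slice_axis which array axis indexes slices (default 3).
#' @return List of 2D matrices, one per slice.
#' @export
volume_slices <- function(v, slice_axis = 3) {
  vox <- if (inherits(v, "volume")) v$voxels else v
  stopifnot(slice_axis %in% 1:3)
  n <- dim(vox)[slice_axis]
  lapply(seq_len(n), function(k) {
    s <- switch(slice_axis,
                vox[k, , , drop = FALSE],
                vox[, k, , drop = FALSE],
                vox[, , k, drop = FALSE])
    m <- array(s, dim = dim(s)[-slice_axis])
    m
  })
}
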