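#' Dynamic image container
#'
#' A 4D block of decay-corrected activity (kBq/mL) on a voxel grid, with a
#' body mask and a reference to the frame schedule.  The frame dimension is
#' the 4th array axis and must match the schedule.
#'
#' @param data 4D numeric array (nx, ny, nz, J).
#' @param schedule a \code{frame_schedule} with \code{J} frames.
#' @param voxel_size_mm length-3 voxel edge lengths.
#' @param mask 3D logical array (default: all voxels in the body).
#' @return object of class \code{dynamic_image}.
#' @export
dynamic_image <- function(data, schedule, voxel_size_mm = c(1.65, 1.65, 1.65),
                          mask = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("data must be a 4D array")
  if (d[4] != schedule$J)
    stop(sprintf("frame dimension (%d) does not match schedule (%d frames)",
                 d[4], schedule$J))
  if (any(!is.finite(data))) stop("non-finite voxel values")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask geometry does not match data")
  structure(list(data = data, schedule = schedule,
                 voxel_size_mm = voxel_size_mm, mask = mask, dim = d[1:3]),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("dynamic_image: %s voxels x %d frames, %d in mask\n",
              paste(x$dim, collapse = " x "), x$schedule$J, sum(x$mask)))
  invisible(x)
}

#' Extract the masked voxel TAC matrix (J x N)
#'
#' Column order follows R array order restricted to the mask, so maps can be
#' rebuilt with \code{\link{map_from_vector}}.
#'
#' @param image a \code{dynamic_image}.
#' @export
image_tac_matrix <- function(image) {
  J <- image$schedule$J
  flat <- matrix(image$data, prod(image$dim), J)
  t(flat[as.vector(image$mask), , drop = FALSE])
}

#' Rebuild a 3D map from per-masked-voxel values
#'
#' @param values numeric vector, one per masked voxel.
#' @param image a \code{dynamic_image} (geometry + mask).
#' @return 3D array, NA outside the mask.
#' @export
map_from_vector <- function(values, image) {
  out <- array(NA_real_, image$dim)
  out[image$mask] <- values
  out
}

# replace the masked voxel time courses of an image with the columns of Z
image_with_tacs <- function(image, Z) {
  flat <- matrix(image$data, prod(image$dim), image$schedule$J)
  flat[as.vector(image$mask), ] <- t(Z)
  image$data <- array(flat, c(image$dim, image$schedule$J))
  image
}
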