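#' 12-parameter affine transform
#'
#' World-to-world affine mapping native space to template space,
#' parameterized by 3 translations (mm), 3 rotations (rad, about the world
#' x, y, z axes), 3 zooms (scale factors, > 0) and 3 shears. The composed
#' homogeneous matrix is `T %*% R %*% Z %*% S` with `R = Rx Ry Rz` and `S`
#' unit upper triangular carrying the (xy, xz, yz) shears. The determinant
#' of the 3x3 linear part (`DET = zx * zy * zz`) summarizes the volume
#' stretch of the native brain into template space: `DET > 1` means the
#' native brain is enlarged (i.e. was smaller than the template).
#'
#' @param translation length-3, mm.
#' @param rotation length-3, radians.
#' @param zoom length-3, positive scale factors.
#' @param shear length-3 shear factors.
#' @return An object of class `affine12`.
#' @export
affine12 <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                     zoom = c(1, 1, 1), shear = c(0, 0, 0)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  zoom <- as.numeric(zoom); shear <- as.numeric(shear)
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(zoom) == 3, length(shear) == 3)
  if (any(zoom <= 0)) stop("zooms must be > 0")
  structure(list(translation = translation, rotation = rotation,
                 zoom = zoom, shear = shear),
            class = "affine12")
}

rot_mat <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Compose an affine12 into its 4x4 homogeneous matrix
#' @param xf an `affine12` or an already-composed 4x4 matrix.
#' @return 4x4 numeric matrix.
#' @export
as_matrix4 <- function(xf) {
  if (is.matrix(xf)) {
    stopifnot(all(dim(xf) == c(4, 4)))
    return(xf)
  }
  stopifnot(inherits(xf, "affine12"))
  S <- diag(3)
  S[1, 2] <- xf$shear[1]; S[1, 3] <- xf$shear[2]; S[2, 3] <- xf$shear[3]
  A <- rot_mat(xf$rotation) %*% diag(xf$zoom) %*% S
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- xf$translation
  M
}

#' Determinant of the linear part of an affine transform
#'
#' The DET of a stereotactical normalization transform characterizes the
#' amount of stretching of the native scan into template space; a larger
#' DET indicates a smaller brain in native patient space.
#'
#' @param xf an `affine12` or 4x4 matrix.
#' @return Scalar determinant.
#' @export
det_of <- function(xf) {
  if (inherits(xf, "affine12")) return(prod(xf$zoom))
  det(as_matrix4(xf)[1:3, 1:3])
}

#' @export
print.affine12 <- function(x, ...) {
  cat("<affine12> native -> template\n")
  cat(sprintf("  translation (mm): %7.3f %7.3f %7.3f\n", x$translation[1],
              x$translation[2], x$translation[3]))
  cat(sprintf("  rotation (deg):   %7.3f %7.3f %7.3f\n",
              x$rotation[1] * 180 / pi, x$rotation[2] * 180 / pi,
              x$rotation[3] * 180 / pi))
  cat(sprintf("  zoom:             %7.4f %7.4f %7.4f\n", x$zoom[1],
              x$zoom[2], x$zoom[3]))
  cat(sprintf("  shear:            %7.4f %7.4f %7.4f\n", x$shear[1],
              x$shear[2], x$shear[3]))
  cat(sprintf("  DET: %.4f\n", det_of(x)))
  invisible(x)
}

# flat parameter vector <-> affine12 (zooms on log scale for optimization)
affine_to_par <- function(xf) {
  c(xf$translation, xf$rotation, log(xf$zoom), xf$shear)
}

par_to_affine <- function(p) {
  affine12(translation = p[1:3], rotation = p[4:6], zoom = exp(p[7:9]),
           shear = p[10:12])
}
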