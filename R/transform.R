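# ---- affine transforms between stack and atlas space ---------------------
#
# A transform maps physical micrometre coordinates (z, y, x) of the source
# (stack) space to physical micrometre coordinates of the target (atlas)
# space: target = M %*% c(source, 1), with M a 3x4 matrix.

#' Construct an affine transform
#'
#' @param matrix 3x4 numeric matrix, rows = target (z, y, x), maps
#'   source micrometre coordinates to target micrometre coordinates.
#' @param source_spacing_um length-3 source voxel spacing (z, y, x).
#' @param target_spacing_um scalar target (atlas) voxel spacing.
#' @return An `affine_transform`.
#' @export
affine_transform <- function(matrix, source_spacing_um, target_spacing_um) {
  matrix <- base::matrix(as.numeric(matrix), nrow = 3, ncol = 4)
  if (any(!is.finite(matrix))) stop("transform entries must be finite")
  lin <- matrix[, 1:3]
  if (abs(det(lin)) < 1e-12)
    stop("linear part of the transform is singular")
  structure(list(matrix = matrix,
                 source_spacing_um = as.numeric(source_spacing_um),
                 target_spacing_um = as.numeric(target_spacing_um)),
            class = "affine_transform")
}

#' Identity transform
#' @param source_spacing_um length-3 source spacing.
#' @param target_spacing_um scalar target spacing.
#' @return An `affine_transform` that leaves micrometre coordinates fixed.
#' @export
identity_transform <- function(source_spacing_um, target_spacing_um) {
  affine_transform(cbind(diag(3), 0), source_spacing_um, target_spacing_um)
}

#' Apply an affine transform to micrometre points
#' @param tx an `affine_transform`.
#' @param points_um N x 3 matrix of (z, y, x) micrometre coordinates.
#' @return N x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(tx, points_um) {
  points_um <- base::matrix(as.numeric(points_um), ncol = 3)
  t(tx$matrix %*% rbind(t(points_um), 1))
}

#' Invert an affine transform
#' @param tx an `affine_transform`.
#' @return The inverse `affine_transform` (target spacing becomes a
#'   length-3 source spacing and vice versa).
#' @export
invert_transform <- function(tx) {
  lin <- tx$matrix[, 1:3]
  linv <- solve(lin)
  m <- cbind(linv, -linv %*% tx$matrix[, 4])
  affine_transform(m, rep(tx$target_spacing_um, 3),
                   tx$source_spacing_um[1])
}

#' Write a transform as JSON
#'
#' Stores the 3x4 matrix row-major together with the spacings and an
#' explicit convention note so external tools can interpret it.
#'
#' @param tx an `affine_transform`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(tx, path) {
  jsonlite::write_json(list(
    matrix_3x4_row_major = as.numeric(t(tx$matrix)),
    source_spacing_um = tx$source_spacing_um,
    target_spacing_um = tx$target_spacing_um,
    convention = paste("maps source (z,y,x) micrometre coordinates to",
                       "target (z,y,x) micrometre coordinates;",
                       "voxel i center at (i - 0.5) * spacing, 1-based")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Import an externally produced point transform
#'
#' Reads a JSON transform file (as written by [write_transform_json()], or
#' produced by an external alignment tool following the same convention)
#' and validates it. The result is usable exactly like the output of
#' [register_affine()].
#'
#' @param path JSON file path.
#' @return An `affine_transform`.
#' @export
import_point_transform <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed transform file: ",
                                           conditionMessage(e)))
  m <- raw$matrix_3x4_row_major
  if (is.null(m) || length(m) != 12)
    stop("transform file must contain matrix_3x4_row_major with 12 entries")
  affine_transform(t(base::matrix(as.numeric(m), nrow = 4, ncol = 3)),
                   raw$source_spacing_um %||% c(1, 1, 1),
                   raw$target_spacing_um %||% 1)
}
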