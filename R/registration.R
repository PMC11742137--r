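#' Landmark correspondences between two coordinate frames
#'
#' Pairs of manually placed fiducials: the same physical feature located in
#' the fixed frame (conventionally the WSI) and the moving frame
#' (conventionally the elemental map), both in physical micrometres.
#'
#' @param fixed_xy,moving_xy Two-column matrices (or data frames) of (x, y)
#'   in micrometres; equal row counts.
#' @param fixed_frame_id,moving_frame_id Frame names.
#' @return A `landmark_pairs` tibble with columns `fixed_x`, `fixed_y`,
#'   `moving_x`, `moving_y` and frame ids as attributes.
#' @export
landmark_pairs <- function(fixed_xy, moving_xy, fixed_frame_id = "wsi",
                           moving_frame_id = "elemental") {
  fixed_xy <- as.matrix(fixed_xy); moving_xy <- as.matrix(moving_xy)
  if (nrow(fixed_xy) != nrow(moving_xy)) {
    abort_elemap(sprintf("%d fixed vs %d moving landmarks", nrow(fixed_xy), nrow(moving_xy)),
                 "elemap_bad_landmarks")
  }
  if (nrow(fixed_xy) < 1L) abort_elemap("need at least one landmark pair", "elemap_bad_landmarks")
  if (!all(is.finite(fixed_xy)) || !all(is.finite(moving_xy))) {
    abort_elemap("landmark coordinates must be finite", "elemap_bad_landmarks")
  }
  out <- tibble::tibble(fixed_x = fixed_xy[, 1], fixed_y = fixed_xy[, 2],
                        moving_x = moving_xy[, 1], moving_y = moving_xy[, 2])
  structure(out, fixed_frame_id = fixed_frame_id, moving_frame_id = moving_frame_id,
            class = c("landmark_pairs", class(out)))
}

#' Read / write landmark CSV
#'
#' Plain CSV with columns `fixed_x, fixed_y, moving_x, moving_y` in
#' micrometres.
#'
#' @param path CSV path.
#' @param fixed_frame_id,moving_frame_id Frame names to attach on read.
#' @return [landmark_pairs()] for `read_landmarks`; `path` invisibly for
#'   `write_landmarks`.
#' @export
read_landmarks <- function(path, fixed_frame_id = "wsi", moving_frame_id = "elemental") {
  df <- utils::read.csv(path)
  need <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  if (!all(need %in% names(df))) {
    abort_elemap(sprintf("landmark CSV must have columns %s", paste(need, collapse = ", ")),
                 "elemap_parse_error")
  }
  landmark_pairs(df[c("fixed_x", "fixed_y")], df[c("moving_x", "moving_y")],
                 fixed_frame_id, moving_frame_id)
}

#' @rdname read_landmarks
#' @param pairs A [landmark_pairs()] table.
#' @export
write_landmarks <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

#' Planar linear transform between physical frames
#'
#' A 2x3 matrix `[A | t]` acting on column vectors `(x, y, 1)` of physical
#' micrometre coordinates, mapping the source (moving) frame into the target
#' (fixed) frame. `model` records the family the matrix belongs to: rigid
#' (rotation + translation), similarity (+ isotropic scale) or affine.
#'
#' @param matrix Numeric 2x3 matrix.
#' @param model `"rigid"`, `"similarity"` or `"affine"`.
#' @param source_frame_id,target_frame_id Frame names.
#' @return A `planar_transform` object.
#' @export
planar_transform <- function(matrix, model = c("affine", "similarity", "rigid"),
                             source_frame_id = "elemental", target_frame_id = "wsi") {
  model <- match.arg(model)
  matrix <- base::matrix(as.numeric(matrix), 2, 3)
  A <- matrix[, 1:2]
  if (abs(det(A)) < 1e-12) {
    abort_elemap("transform is singular (det A = 0)", "elemap_singular_transform")
  }
  if (model %in% c("rigid", "similarity")) {
    s <- sqrt(abs(det(A)))
    R <- A / s
    if (max(abs(crossprod(R) - diag(2))) > 1e-6 || det(R) < 0) {
      abort_elemap(sprintf("matrix is not a proper %s transform", model),
                   "elemap_bad_transform")
    }
    if (model == "rigid" && abs(s - 1) > 1e-6) {
      abort_elemap("rigid transform must have unit scale", "elemap_bad_transform")
    }
  }
  structure(list(matrix = matrix, model = model,
                 source_frame_id = as.character(source_frame_id),
                 target_frame_id = as.character(target_frame_id)),
            class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform> %s: '%s' -> '%s'\n", x$model,
              x$source_frame_id, x$target_frame_id))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Estimate a landmark-based transform
#'
#' Least-squares fit of `T` minimizing `sum ||T(moving_i) - fixed_i||^2` over
#' the requested family. Affine is solved by the linear normal equations;
#' similarity and rigid by orthogonal Procrustes on centered coordinates
#' (cross-covariance SVD), with reflections disallowed (det forced +1) and,
#' for similarity, an isotropic positive scale.
#'
#' @param pairs A [landmark_pairs()] table. Affine needs >= 3 non-collinear
#'   pairs; similarity/rigid need >= 2 distinct pairs.
#' @param model `"affine"` (default), `"similarity"` or `"rigid"`.
#' @return A [planar_transform()] mapping moving-frame to fixed-frame
#'   micrometres.
#' @export
estimate_transform <- function(pairs, model = c("affine", "similarity", "rigid")) {
  model <- match.arg(model)
  F <- cbind(pairs$fixed_x, pairs$fixed_y)
  M <- cbind(pairs$moving_x, pairs$moving_y)
  n <- nrow(F)
  if (model == "affine") {
    if (n < 3L) {
      abort_elemap(sprintf("affine fit needs >= 3 landmark pairs, got %d", n),
                   "elemap_rank_deficient")
    }
    X <- cbind(M, 1)
    dec <- qr(X)
    if (dec$rank < 3L) {
      abort_elemap("affine fit is rank-deficient: moving landmarks are collinear",
                   "elemap_rank_deficient")
    }
    B <- qr.coef(dec, F)                           # 3x2: rows (a1, a2, t)
    mat <- rbind(c(B[1, 1], B[2, 1], B[3, 1]),
                 c(B[1, 2], B[2, 2], B[3, 2]))
  } else {
    if (n < 2L) {
      abort_elemap(sprintf("%s fit needs >= 2 landmark pairs, got %d", model, n),
                   "elemap_rank_deficient")
    }
    mc <- colMeans(M); fc <- colMeans(F)
    Mc <- sweep(M, 2, mc); Fc <- sweep(F, 2, fc)
    if (all(abs(Mc) < 1e-12) || all(abs(Fc) < 1e-12)) {
      abort_elemap(sprintf("%s fit is degenerate: landmarks are coincident", model),
                   "elemap_rank_deficient")
    }
    H <- crossprod(Mc, Fc)                         # 2x2 cross-covariance
    sv <- svd(H)
    d_sign <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, d_sign))
    R <- sv$v %*% D %*% t(sv$u)                    # proper rotation, det +1
    s <- if (model == "similarity") {
      sum(sv$d * diag(D)) / sum(Mc^2)
    } else 1
    if (s <= 0) {
      abort_elemap("similarity fit produced non-positive scale", "elemap_rank_deficient")
    }
    t_vec <- fc - s * (R %*% mc)
    mat <- cbind(s * R, t_vec)
  }
  planar_transform(mat, model,
                   source_frame_id = attr(pairs, "moving_frame_id") %||% "moving",
                   target_frame_id = attr(pairs, "fixed_frame_id") %||% "fixed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a transform to points
#' @param transform A [planar_transform()].
#' @param pts Two-column matrix (or data frame) of (x, y).
#' @return Matrix of transformed (x, y).
#' @export
apply_to_points <- function(transform, pts) {
  pts <- base::matrix(as.numeric(as.matrix(pts)), ncol = 2)
  out <- cbind(pts, 1) %*% t(transform$matrix)
  colnames(out) <- c("x", "y")
  out
}

#' Invert a planar transform
#' @param transform A [planar_transform()].
#' @return The inverse transform; frame ids are swapped.
#' @export
invert_transform <- function(transform) {
  A <- transform$matrix[, 1:2]; t_vec <- transform$matrix[, 3]
  Ai <- solve(A)
  planar_transform(cbind(Ai, -Ai %*% t_vec), transform$model,
                   source_frame_id = transform$target_frame_id,
                   target_frame_id = transform$source_frame_id)
}

#' Compose two transforms (apply `first`, then `second`)
#'
#' Frame ids must chain: `first$target_frame_id == second$source_frame_id`.
#'
#' @param second,first [planar_transform()] objects.
#' @return The composed transform.
#' @export
compose_transforms <- function(second, first) {
  if (!identical(first$target_frame_id, second$source_frame_id)) {
    abort_elemap(sprintf("frame mismatch in composition: '%s' -> '%s' then '%s' -> '%s'",
                         first$source_frame_id, first$target_frame_id,
                         second$source_frame_id, second$target_frame_id),
                 "elemap_frame_mismatch")
  }
  A2 <- second$matrix[, 1:2]; A1 <- first$matrix[, 1:2]
  t2 <- second$matrix[, 3];   t1 <- first$matrix[, 3]
  mat <- cbind(A2 %*% A1, A2 %*% t1 + t2)
  model <- if (identical(first$model, second$model)) first$model else "affine"
  planar_transform(mat, model,
                   source_frame_id = first$source_frame_id,
                   target_frame_id = second$target_frame_id)
}

#' Landmark residuals of a fitted transform
#'
#' @param transform A [planar_transform()].
#' @param pairs A [landmark_pairs()] table.
#' @return List with `rmse_um` and the per-pair `residuals_um`.
#' @export
registration_error <- function(transform, pairs) {
  pred <- apply_to_points(transform, cbind(pairs$moving_x, pairs$moving_y))
  res <- sqrt((pred[, 1] - pairs$fixed_x)^2 + (pred[, 2] - pairs$fixed_y)^2)
  list(rmse_um = sqrt(mean(res^2)), residuals_um = res)
}

#' Serialize / load a transform as JSON
#'
#' @param transform A [planar_transform()].
#' @param path JSON path.
#' @param rmse_um Optional landmark RMSE to record alongside.
#' @return `path` invisibly; `read_transform_json()` returns the transform.
#' @export
write_transform_json <- function(transform, path, rmse_um = NULL) {
  json_write(list(matrix = transform$matrix, model = transform$model,
                  source_frame_id = transform$source_frame_id,
                  target_frame_id = transform$target_frame_id,
                  rmse_um = rmse_um),
             path)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  planar_transform(x$matrix, x$model, x$source_frame_id, x$target_frame_id)
}
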