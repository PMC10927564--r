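#' Rigid transformations in 3D
#'
#' A rigid transform is a proper rotation plus a translation, applied to
#' coordinates as `x' = R x + t`.  Transforms map one subunit reference frame
#' into another and are composed along assembly trees, so closure under
#' composition and inversion is required and checked.
#'
#' @param rotation 3x3 proper rotation matrix (det = +1, orthonormal).
#' @param translation numeric length-3 translation in Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation matrix is not orthonormal within 1e-6")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation matrix is not a proper rotation (det != +1)")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() {
  structure(list(R = diag(3), t = c(0, 0, 0)), class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the function composition a after b: the returned
#' transform applies `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t) + a$t),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param a A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(a) {
  Rt <- t(a$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% a$t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param a A `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (rows are points), or a length-3 vector.
#' @return Transformed coordinates, same shape as the input.
#' @export
rt_apply <- function(a, xyz) {
  if (is.null(dim(xyz))) {
    return(as.numeric(a$R %*% xyz) + a$t)
  }
  sweep(xyz %*% t(a$R), 2L, a$t, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat("  rotation:\n")
  print(round(x$R, 6))
  cat("  translation:", paste(round(x$t, 4), collapse = " "), "\n")
  invisible(x)
}

## Rotation angle (rad) of a rotation matrix; used for group-closure checks.
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

#' Minimal-RMSD rigid superposition (Kabsch)
#'
#' Computes the rigid transform that moves point set `source` onto `target`
#' with minimal root-mean-square deviation, by the Kabsch singular-value
#' decomposition with the usual determinant correction to exclude
#' reflections.
#'
#' @param source,target n x 3 matrices of paired points (n >= 3).
#' @return A `rigid_transform` `T` minimizing RMSD between `rt_apply(T,
#'   source)` and `target`.
#' @export
kabsch <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3L, ncol(target) == 3L,
            nrow(source) == nrow(target))
  if (nrow(source) < 3L) {
    stop("degenerate alignment: fewer than 3 paired points")
  }
  cs <- colMeans(source)
  ct <- colMeans(target)
  H <- crossprod(sweep(source, 2L, cs), sweep(target, 2L, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Coordinate RMSD between two paired point sets
#'
#' @param a,b n x 3 matrices with rows in correspondence.
#' @param fit if `TRUE`, superpose `a` onto `b` (Kabsch) before measuring.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, fit = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  if (fit) a <- rt_apply(kabsch(a, b), a)
  sqrt(mean(rowSums((a - b)^2)))
}

## Uniform random rotation via normalized quaternion (draws 4 values from
## the current RNG stream).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

## Rotation about z by angle (rad)
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

## Evaluate an expression with a temporary, restored RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Stable small integer hash of a string (for per-name seed derivation).
str_seed <- function(s, base_seed = 0L) {
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(base_seed) * 7919) %% 2147483647)
}
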