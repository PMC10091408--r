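# Small numeric helpers shared across modules.

AVOGADRO <- 6.02214076e23

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` radians about the (normalised) `axis`.
#' @param axis numeric length-3 axis (need not be unit length).
#' @param theta rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rot_z <- function(theta) rot_axis(c(0, 0, 1), theta)

# Nearest orthonormal right-handed frame to M (polar decomposition).
orthonormalize <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds rotation `R` and translation `t` minimising `||P R' + t - Q||^2`,
#' i.e. mapping point set `P` onto `Q`.
#'
#' @param P,Q n x 3 coordinate matrices with matched rows.
#' @return list with `R` (3x3), `t` (length 3) and `rmsd` of the fit.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("superposition needs at least 3 points")
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  H <- t(sweep(P, 2, cP)) %*% sweep(Q, 2, cQ)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cQ - as.vector(R %*% cP)
  fitted <- sweep(P %*% t(R), 2, t, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# Evaluate code with a temporarily-seeded RNG, restoring global state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Halton quasi-random points in the unit cube
#'
#' Radical-inverse (van der Corput) sequences in coprime bases 2/3/5. Used for
#' volume integration, where low-discrepancy points give far smaller per-bin
#' error than pseudo-random sampling at equal cost.
#'
#' @param n number of points.
#' @param skip index offset into the sequence (deterministic "seeding").
#' @return n x 3 matrix in the open unit cube.
#' @keywords internal
halton3 <- function(n, skip = 0) {
  radical_inverse <- function(idx, base) {
    x <- numeric(length(idx))
    f <- 1 / base
    i <- idx
    while (any(i > 0)) {
      x <- x + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    x
  }
  idx <- skip + seq_len(n)
  cbind(radical_inverse(idx, 2), radical_inverse(idx, 3),
        radical_inverse(idx, 5))
}

# Round half away from zero (box-setup convention; round() rounds half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
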