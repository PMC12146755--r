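# Internal numerical helpers shared across modules.

# Standard atomic masses (u) for the elements that occur in protein models.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305
)

#' Atomic masses from element symbols
#'
#' Unknown elements fall back to the mass of carbon, with a warning.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in unified atomic mass units.
#' @keywords internal
element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using carbon mass", call. = FALSE)
    m[is.na(m)] <- .atomic_masses[["C"]]
  }
  unname(m)
}

# Rotation matrices about the coordinate axes; angle in radians, acting on
# column vectors (right-handed, active rotations).
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation matrix -> unit quaternion (w, x, y, z), Shepperd's method.
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Angle (radians, in [0, pi]) between the rotations two unit quaternions
# represent; the quaternion double cover is resolved with abs().
quat_angle <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}

# Weighted mean orientation: principal eigenvector of the weighted
# quaternion outer-product matrix (Markley's quaternion averaging).
mean_quaternion <- function(quats, weights) {
  M <- matrix(0, 4, 4)
  for (i in seq_along(weights)) M <- M + weights[i] * tcrossprod(quats[[i]])
  e <- eigen(M, symmetric = TRUE)
  e$vectors[, 1]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
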