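#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping the rows of `P` onto
#' the rows of `Q` in the least-squares sense, via the SVD of the
#' cross-covariance matrix with the determinant sign correction that
#' excludes reflections.
#'
#' @param P,Q n x 3 coordinate matrices with matched rows (n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3), and `rmsd` after superposition; a point `x` maps to
#'   `rotation %*% x + translation`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3)
    stopf("kabsch: P and Q must be matched n x 3 matrices")
  if (nrow(P) < 3) stopf("kabsch: need >= 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))      # H = Pc' Qc
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stopf("kabsch: degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  fit <- sweep(Pc %*% t(R), 2, cq, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((fit - Q)^2))))
}

apply_rigid <- function(state, rotation, translation) {
  xyz <- coords(state) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  state$atoms$x <- xyz[, 1]; state$atoms$y <- xyz[, 2]
  state$atoms$z <- xyz[, 3]
  state
}

#' Superpose all states on a reference subcomplex
#'
#' Each state is rigidly transformed by the least-squares fit of its
#' reference selection onto the same selection in state 1 (the first row
#' of the weight table), the analogue of aligning every conformation to
#' the binder--antigen subcomplex before measuring flexibility.
#'
#' @param ensemble a [weighted_ensemble()].
#' @param annotation an [ensemble_annotation()].
#' @param reference_role role naming the reference selection (default
#'   `"reference"`); must resolve to the same atom count in every state.
#' @return list with `ensemble` (aligned), `transforms` (per-state list
#'   of rotation/translation) and `rmsd` (per-state reference RMSD after
#'   alignment, Angstrom).
#' @export
superpose_states <- function(ensemble, annotation,
                             reference_role = "reference") {
  expr <- lookup_selection(annotation, reference_role)
  idx <- lapply(ensemble$states, resolve_selection, selection = expr,
                role = reference_role)
  n0 <- length(idx[[1]])
  if (n0 < 3)
    stopf("reference selection resolves to %d atom(s); need >= 3", n0)
  bad <- which(lengths(idx) != n0)
  if (length(bad))
    stopf("reference atom count differs in state '%s' (%d vs %d)",
          ensemble$states[[bad[1]]]$label, length(idx[[bad[1]]]), n0)
  target <- coords(ensemble$states[[1]])[idx[[1]], , drop = FALSE]
  transforms <- vector("list", n_states(ensemble))
  rmsd <- numeric(n_states(ensemble))
  aligned <- ensemble
  for (i in seq_len(n_states(ensemble))) {
    mob <- coords(ensemble$states[[i]])[idx[[i]], , drop = FALSE]
    fit <- kabsch(mob, target)
    transforms[[i]] <- fit[c("rotation", "translation")]
    rmsd[i] <- fit$rmsd
    aligned$states[[i]] <- apply_rigid(ensemble$states[[i]], fit$rotation,
                                       fit$translation)
  }
  list(ensemble = aligned, transforms = transforms, rmsd = rmsd)
}

#' Weighted spacing distribution between two landmarks
#'
#' Per-state Euclidean distance between the centroids of two annotated
#' selections, paired with the state weights and reported in nm. With the
#' paratope-tip roles this is the paratope spacing; with the anchor roles
#' it is the anchor-to-anchor (intermembrane proxy) spacing. The result
#' is invariant to any prior rigid alignment and symmetric in its roles.
#'
#' @param ensemble a [weighted_ensemble()].
#' @param annotation an [ensemble_annotation()].
#' @param role_a,role_b role/domain names or literal selection
#'   expressions.
#' @return a [weighted_distribution()] in nm.
#' @export
spacing_distribution <- function(ensemble, annotation, role_a, role_b) {
  d <- vapply(ensemble$states, function(st) {
    ca <- selection_centroid(st, role_a, annotation)
    cb <- selection_centroid(st, role_b, annotation)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  weighted_distribution(d / 10, ensemble$weights, unit = "nm")
}

# Longest principal axis (unit vector) of a set of coordinates, plus a
# degeneracy flag when the top two covariance eigenvalues are within 1%.
principal_axis <- function(xyz) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  degenerate <- ev$values[1] <= 0 ||
    (ev$values[1] - ev$values[2]) / ev$values[1] < 0.01
  list(axis = ev$vectors[, 1], degenerate = degenerate)
}

#' Weighted tilt-angle distribution of a domain
#'
#' Per-state acute angle (degrees, in \[0, 90\]) between the domain's
#' longest principal axis (largest-eigenvalue axis of the covariance of
#' its atom positions) and the axis_head -> axis_tail unit vector, e.g.
#' domain tilts relative to the antigen--binder axis. Principal axes are
#' sign-ambiguous, so angles are folded to the acute range. Near-spherical
#' domains (top two covariance eigenvalues within 1%) have an ill-defined
#' axis: they are flagged in the `degenerate` attribute and a warning is
#' raised.
#'
#' @param ensemble a [weighted_ensemble()], previously superposed on the
#'   reference.
#' @param annotation an [ensemble_annotation()].
#' @param domain domain name (or literal selection).
#' @param axis_head,axis_tail roles for the axis endpoints.
#' @return a [weighted_distribution()] in degrees with attribute
#'   `degenerate`, a logical per-state flag.
#' @export
tilt_angle_distribution <- function(ensemble, annotation, domain,
                                    axis_head = "axis_head",
                                    axis_tail = "axis_tail") {
  n <- n_states(ensemble)
  ang <- numeric(n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    st <- ensemble$states[[i]]
    h <- selection_centroid(st, axis_head, annotation)
    t <- selection_centroid(st, axis_tail, annotation)
    u <- t - h
    nu <- sqrt(sum(u^2))
    if (nu <= 0.1) stopf("axis endpoints coincide in state '%s'", st$label)
    u <- u / nu
    idx <- resolve_selection(st, lookup_selection(annotation, domain),
                             role = domain)
    pa <- principal_axis(coords(st)[idx, , drop = FALSE])
    flag[i] <- pa$degenerate
    ang[i] <- acos(min(1, abs(sum(pa$axis * u)))) * 180 / pi
  }
  if (any(flag))
    warning(sprintf("%d state(s) have a near-spherical domain '%s'; tilt axis ill-defined",
                    sum(flag), domain), call. = FALSE)
  structure(weighted_distribution(ang, ensemble$weights, unit = "degrees"),
            degenerate = flag)
}
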