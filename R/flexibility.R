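#' Radius of gyration of one state
#'
#' Mass-weighted Rg: `sqrt(sum(m_i * |r_i - rbar|^2) / sum(m_i))` with
#' `rbar` the center of mass. Masses come from the element symbols;
#' unknown elements use the carbon mass (with a warning). Reported in nm.
#'
#' @param state a [structure_state()].
#' @return radius of gyration in nm.
#' @export
state_radius_of_gyration <- function(state) {
  xyz <- coords(state)
  m <- element_mass(state$atoms$elesy)
  com <- colSums(xyz * m) / sum(m)
  dev2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * dev2) / sum(m)) / 10
}

#' Weight-adjusted radius-of-gyration distribution
#'
#' @param ensemble a [weighted_ensemble()].
#' @return a [weighted_distribution()] of per-state Rg values in nm.
#' @export
rg_distribution <- function(ensemble) {
  rg <- vapply(ensemble$states, state_radius_of_gyration, numeric(1))
  weighted_distribution(rg, ensemble$weights, unit = "nm")
}

domain_indices <- function(ensemble, annotation, domain) {
  expr <- if (is.null(domain)) NULL else lookup_selection(annotation, domain)
  lapply(ensemble$states, function(st) {
    if (is.null(expr)) seq_len(nrow(st$atoms))
    else resolve_selection(st, expr, role = domain %||% "whole")
  })
}

domain_com <- function(state, idx) {
  xyz <- coords(state)[idx, , drop = FALSE]
  m <- element_mass(state$atoms$elesy[idx])
  colSums(xyz * m) / sum(m)
}

#' Center-of-mass flexibility of a domain (CoM Flex)
#'
#' Weighted RMS dispersion of the domain's mass-weighted center of mass
#' across the aligned ensemble:
#' `sqrt(sum_i w_i * |c_i - cbar|^2)` with `cbar = sum_i w_i c_i`.
#' For two equal-weight states whose domain CoM is displaced by `d` this
#' equals `d/2`; identical states give 0.
#'
#' @param ensemble a [weighted_ensemble()], superposed on the reference.
#' @param annotation an [ensemble_annotation()] (ignored when `domain` is
#'   `NULL`).
#' @param domain domain name, literal selection, or `NULL` for the whole
#'   molecule.
#' @return CoM flexibility in nm.
#' @export
com_flexibility <- function(ensemble, annotation = NULL, domain = NULL) {
  idx <- domain_indices(ensemble, annotation, domain)
  coms <- t(mapply(domain_com, ensemble$states, idx))
  w <- ensemble$weights
  cbar <- colSums(coms * w)
  sqrt(sum(w * rowSums(sweep(coms, 2, cbar)^2))) / 10
}

#' Rotational flexibility of a domain
#'
#' Weighted RMS rotation angle of the domain about its weighted mean
#' orientation across the aligned ensemble. Per state the domain's
#' orientation (relative to state 1) is extracted by Kabsch superposition
#' of its centered atoms; the mean orientation is the principal
#' eigenvector of the weighted quaternion outer-product matrix; the
#' returned value is `sqrt(sum_i w_i * theta_i^2)` with `theta_i` the
#' rotation angle (degrees, in \[0, 180\] after resolving the quaternion
#' double cover) between state i and the mean orientation. Two
#' equal-weight states rotated by +/- theta give theta; identical states
#' give 0.
#'
#' @inheritParams com_flexibility
#' @return rotational flexibility in degrees.
#' @export
rotational_flexibility <- function(ensemble, annotation = NULL,
                                   domain = NULL) {
  idx <- domain_indices(ensemble, annotation, domain)
  n0 <- length(idx[[1]])
  if (any(lengths(idx) != n0))
    stopf("domain atom count differs across states")
  if (n0 < 3) stopf("rotational flexibility needs >= 3 domain atoms")
  ref <- coords(ensemble$states[[1]])[idx[[1]], , drop = FALSE]
  quats <- lapply(seq_len(n_states(ensemble)), function(i) {
    mob <- coords(ensemble$states[[i]])[idx[[i]], , drop = FALSE]
    rotmat_to_quat(kabsch(ref, mob)$rotation)
  })
  w <- ensemble$weights
  qbar <- mean_quaternion(quats, w)
  theta <- vapply(quats, quat_angle, numeric(1), q2 = qbar) * 180 / pi
  sqrt(sum(w * theta^2))
}

#' Effective disorder
#'
#' Product of a domain's CoM flexibility (nm) and rotational flexibility
#' (degrees) — the combined translational/orientational disorder score
#' reported per domain (referred to as a Shannon-entropy-style disorder
#' measure in the field; a true entropy over the state weights is
#' provided separately by [weight_entropy()], never conflated with this).
#'
#' @param com_flex CoM flexibility in nm (>= 0).
#' @param rot_flex rotational flexibility in degrees (>= 0).
#' @return effective disorder in nm*degrees.
#' @export
effective_disorder <- function(com_flex, rot_flex) {
  if (any(com_flex < 0) || any(rot_flex < 0))
    stopf("flexibilities must be nonnegative")
  com_flex * rot_flex
}

#' Shannon entropy of the state weights
#'
#' `-sum(w_i * log(w_i))` in nats, with `0 * log(0) := 0`. Zero for a
#' single-state ensemble, `log(K)` for uniform weights over K states.
#'
#' @param weights normalized state weights.
#' @return entropy in nats.
#' @export
weight_entropy <- function(weights) {
  w <- normalize_weights(weights)
  w <- w[w > 0]
  -sum(w * log(w))
}

#' Full flexibility report for an aligned ensemble
#'
#' Computes the weight-adjusted Rg distribution, per-domain CoM and
#' rotational flexibility with their effective-disorder product (plus a
#' whole-molecule row), and the Shannon entropy of the weights.
#'
#' @param ensemble a [weighted_ensemble()], superposed on the reference.
#' @param annotation an [ensemble_annotation()] whose `domains` are
#'   reported.
#' @return object of class `flexibility_report`: list with
#'   `rg_distribution`, `domains` (`data.frame` with columns domain,
#'   com_flex_nm, rot_flex_deg, effective_disorder), and `weight_entropy`.
#' @export
flexibility_report <- function(ensemble, annotation) {
  doms <- c(names(annotation$domains), "(whole molecule)")
  rows <- do.call(rbind, lapply(doms, function(d) {
    dd <- if (d == "(whole molecule)") NULL else d
    cf <- com_flexibility(ensemble, annotation, dd)
    rf <- rotational_flexibility(ensemble, annotation, dd)
    data.frame(domain = d, com_flex_nm = cf, rot_flex_deg = rf,
               effective_disorder = effective_disorder(cf, rf),
               stringsAsFactors = FALSE)
  }))
  structure(list(rg_distribution = rg_distribution(ensemble),
                 domains = rows,
                 weight_entropy = weight_entropy(ensemble$weights)),
            class = "flexibility_report")
}

#' @export
print.flexibility_report <- function(x, ...) {
  cat("flexibility report\n Rg (nm):\n")
  print(round(summary(x$rg_distribution), 4))
  cat(" per-domain:\n")
  print(x$domains, row.names = FALSE, digits = 4)
  cat(sprintf(" weight entropy: %.4f nats\n", x$weight_entropy))
  invisible(x)
}
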