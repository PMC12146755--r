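#' Coarse-grained Debye scattering profile of one state
#'
#' Debye formula with uniform unit form factors:
#' `I(q) = sum_ij sin(q d_ij) / (q d_ij)` with `sinc(0) := 1`, so
#' `I(0) = n^2` for n beads. Beads are either the Calpha trace
#' (one bead per residue) or all atoms with uniform weight. This is a
#' deliberately coarse engine for comparative analyses (rigid vs flexible,
#' mixture composition); it carries no atomic form factors, excluded
#' volume or hydration layer, so absolute intensities are not comparable
#' to full atomistic predictors.
#'
#' @param state a [structure_state()].
#' @param q_grid strictly increasing q values in inverse Angstrom.
#' @param bead_scheme `"calpha"` (default) or `"all-atom"`.
#' @return a [saxs_profile()] with `i0` (= n^2) attached as an attribute.
#' @export
debye_profile <- function(state, q_grid, bead_scheme = c("calpha",
                                                         "all-atom")) {
  bead_scheme <- match.arg(bead_scheme)
  xyz <- coords(state)
  if (bead_scheme == "calpha") {
    ca <- state$atoms$elety == "CA"
    if (!any(ca)) stopf("state '%s' has no CA beads", state$label)
    xyz <- xyz[ca, , drop = FALSE]
  }
  n <- nrow(xyz)
  d <- as.numeric(stats::dist(xyz))          # n(n-1)/2 pairwise distances
  intensity <- vapply(q_grid, function(q) {
    qd <- q * d
    n + 2 * sum(ifelse(qd == 0, 1, sin(qd) / qd))
  }, numeric(1))
  p <- saxs_profile(q_grid, intensity)
  attr(p, "i0") <- n^2
  p
}

#' Weighted mixture of SAXS profiles
#'
#' Pointwise weighted sum of intensities on a shared q grid — the
#' multistate model: one experimental curve explained by a weighted set
#' of conformations.
#'
#' @param profiles list of [saxs_profile()] objects on identical q grids.
#' @param weights state weights (renormalized to sum to 1).
#' @return a [saxs_profile()].
#' @export
ensemble_profile <- function(profiles, weights = NULL) {
  if (!length(profiles)) stopf("empty profile list")
  q <- profiles[[1]]$q
  for (p in profiles)
    if (length(p$q) != length(q) || any(p$q != q))
      stopf("profiles are not on a common q grid")
  if (is.null(weights)) weights <- rep(1, length(profiles))
  w <- normalize_weights(weights, n = length(profiles))
  I <- Reduce(`+`, Map(function(p, wi) wi * p$intensity, profiles, w))
  saxs_profile(q, I)
}

#' Guinier fit
#'
#' Linear fit of `ln I` against `q^2` on the largest low-q window
#' satisfying `q * Rg <= qrg_max`, found by iterating fit -> recompute
#' window until the window is stable. Returns `Rg = sqrt(-3 * slope)` and
#' `I0 = exp(intercept)`.
#'
#' @param profile a [saxs_profile()] with positive intensities in the
#'   fit window.
#' @param qrg_max Guinier validity bound on `q * Rg` (default 1.3).
#' @param min_points minimum window size (default 5).
#' @return list with `rg` (Angstrom), `i0`, `window` (point indices used),
#'   `slope`, `r_squared`, `iterations`.
#' @export
guinier_fit <- function(profile, qrg_max = 1.3, min_points = 5) {
  q <- profile$q; I <- profile$intensity
  fit_window <- function(idx) {
    if (any(I[idx] <= 0))
      stopf("nonpositive intensity inside the Guinier window")
    f <- stats::lm.fit(cbind(1, q[idx]^2), log(I[idx]))
    slope <- f$coefficients[2]
    if (!is.finite(slope) || slope >= 0)
      stopf("Guinier fit failed: non-decaying low-q intensity (slope >= 0)")
    list(rg = sqrt(-3 * slope), i0 = exp(f$coefficients[1]), slope = slope,
         resid = f$residuals)
  }
  idx <- seq_len(min(length(q), max(min_points, 8L)))
  last <- integer(0)
  fit <- NULL
  for (iter in 1:100) {
    fit <- fit_window(idx)
    new_idx <- which(q * fit$rg <= qrg_max)
    if (length(new_idx) < min_points)
      stopf("Guinier window shrank below %d points", min_points)
    new_idx <- seq_len(max(new_idx))
    if (identical(new_idx, idx) || identical(new_idx, last)) break
    last <- idx
    idx <- new_idx
  }
  y <- log(I[idx])
  r2 <- 1 - sum(fit$resid^2) / sum((y - mean(y))^2)
  list(rg = unname(fit$rg), i0 = unname(fit$i0), window = idx,
       slope = unname(fit$slope), r_squared = r2, iterations = iter)
}

#' Dimensionless Kratky transform
#'
#' `x = q * Rg`, `y = x^2 * I(q) / I0`. For a globular (Guinier-like)
#' scatterer the curve peaks at `(sqrt(3), 3/e)`; elevated amplitude at
#' larger `x` is the signature of flexibility, which is how rigid and
#' flexible ensembles are compared model-free.
#'
#' @param profile a [saxs_profile()].
#' @param rg,i0 radius of gyration (Angstrom) and forward scattering; when
#'   `NULL` they are obtained from [guinier_fit()] on `profile`.
#' @return object of class `kratky_curve` with `x`, `y`, `rg`, `i0`.
#' @export
dimensionless_kratky <- function(profile, rg = NULL, i0 = NULL) {
  if (is.null(rg) || is.null(i0)) {
    g <- guinier_fit(profile)
    rg <- rg %||% g$rg
    i0 <- i0 %||% g$i0
  }
  if (rg <= 0 || i0 <= 0) stopf("rg and i0 must be positive")
  x <- profile$q * rg
  structure(list(x = x, y = x^2 * profile$intensity / i0, rg = rg, i0 = i0),
            class = "kratky_curve")
}

#' @export
print.kratky_curve <- function(x, ...) {
  pk <- which.max(x$y)
  cat(sprintf("dimensionless Kratky curve: %d points, peak y %.4f at qRg %.4f\n",
              length(x$x), x$y[pk], x$x[pk]))
  invisible(x)
}

#' Chi goodness-of-fit between a model and an experimental profile
#'
#' The model is linearly interpolated onto the experimental grid (points
#' outside the model's q range are dropped); the scale `c` minimizing
#' `sum(((I_e - c*I_m)/sigma)^2)` is solved in closed form and
#' `chi = sqrt(mean(((I_e - c*I_m)/sigma)^2))` over the M overlapping
#' points. Chi is invariant to rescaling the model.
#'
#' @param model a [saxs_profile()] (computed).
#' @param experiment a [saxs_profile()] with uncertainties.
#' @return list with `chi`, `scale`, `n_points`.
#' @export
chi_fit <- function(model, experiment) {
  keep <- experiment$q >= min(model$q) & experiment$q <= max(model$q)
  if (!any(keep)) stopf("model and experiment q ranges do not overlap")
  qe <- experiment$q[keep]
  Ie <- experiment$intensity[keep]
  se <- experiment$sigma[keep]
  if (any(se <= 0)) stopf("experimental sigma must be positive")
  Im <- stats::approx(model$q, model$intensity, xout = qe)$y
  scale <- sum(Ie * Im / se^2) / sum(Im^2 / se^2)
  chi <- sqrt(mean(((Ie - scale * Im) / se)^2))
  list(chi = chi, scale = scale, n_points = length(qe))
}

# Lawson-Hanson active-set nonnegative least squares:
# argmin_{x >= 0} ||A x - b||^2.
nnls_solve <- function(A, b) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- as.numeric(crossprod(A, b))
  tol <- 1e-12 * max(1, max(abs(w)))
  outer_it <- 0
  while (any(!passive) && max(w[!passive]) > tol && outer_it < 30 * n) {
    outer_it <- outer_it + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      cf <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      cf[is.na(cf)] <- 0
      s[passive] <- cf
      if (all(s[passive] > 0)) {
        x <- s
        break
      }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > 0
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

# Nonnegative weights + global scale for one candidate subset. The
# objective sum(((I_e - c * sum_k w_k I_k)/sigma)^2) with w >= 0 summing
# to 1 factorizes through v = c*w, so a single nonnegative least-squares
# solve is its exact minimizer.
fit_subset_weights <- function(profiles, experiment) {
  A <- vapply(profiles,
              function(p) stats::approx(p$q, p$intensity,
                                        xout = experiment$q)$y /
                experiment$sigma,
              numeric(length(experiment$q)))
  A <- matrix(A, ncol = length(profiles))
  if (anyNA(A)) stopf("pool profile does not cover the experimental q range")
  b <- experiment$intensity / experiment$sigma
  v <- nnls_solve(A, b)
  s <- sum(v)
  if (s <= 0) return(NULL)   # degenerate: no nonnegative combination helps
  resid <- b - A %*% v
  list(weights = v / s, scale = s, chi = sqrt(mean(resid^2)))
}

#' Exhaustive small-pool multistate ensemble selection
#'
#' Desk-scale analogue of multistate SAXS fitting: for each ensemble size
#' `N = 1..n_max` every size-N subset of the candidate pool is evaluated;
#' per subset, nonnegative state weights and a global scale minimizing the
#' [chi_fit()] objective are fitted exactly, and the best subset per N and
#' the overall best by chi are returned. Ties break toward smaller N, then
#' lexicographic label order. The exhaustive search is limited to pools of
#' at most 50 profiles.
#'
#' @param pool named list of candidate [saxs_profile()] objects (names are
#'   the state labels).
#' @param experiment experimental [saxs_profile()] with uncertainties.
#' @param n_max largest ensemble size to consider (<= 5, default 4).
#' @return object of class `ensemble_fit`: list with `best` (list:
#'   `labels`, `weights`, `chi`, `scale`, `n`) and `per_n` (list of the
#'   best result for each N).
#' @export
select_multistate <- function(pool, experiment, n_max = 4) {
  if (is.null(names(pool)) || any(!nzchar(names(pool))))
    stopf("pool must be a named list of profiles")
  np <- length(pool)
  if (np > 50)
    stopf("pool of %d exceeds the exhaustive-search limit of 50; prune the pool",
          np)
  if (n_max > 5) stopf("n_max must be <= 5")
  n_max <- min(n_max, np)
  labels <- names(pool)
  per_n <- vector("list", n_max)
  best <- NULL
  for (N in seq_len(n_max)) {
    subsets <- utils::combn(np, N, simplify = FALSE)
    best_n <- NULL
    for (ss in subsets) {
      fit <- fit_subset_weights(pool[ss], experiment)
      if (is.null(fit)) next
      cand <- list(labels = labels[ss], weights = fit$weights,
                   chi = fit$chi, scale = fit$scale, n = N)
      if (is.null(best_n) || cand$chi < best_n$chi ||
          (cand$chi == best_n$chi &&
           paste(cand$labels, collapse = "\r") <
           paste(best_n$labels, collapse = "\r")))
        best_n <- cand
    }
    if (is.null(best_n))
      stopf("all size-%d subsets gave degenerate (all-zero) weights", N)
    per_n[[N]] <- best_n
    if (is.null(best) || best_n$chi < best$chi) best <- best_n
  }
  structure(list(best = best, per_n = per_n), class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf("multistate fit: best N = %d, chi = %.4g\n", b$n, b$chi))
  for (i in seq_along(b$labels))
    cat(sprintf("  %-20s w = %.4f\n", b$labels[i], b$weights[i]))
  invisible(x)
}
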