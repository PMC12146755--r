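#' Weighted scalar distributions
#'
#' A `weighted_distribution` pairs scalar observations (one per ensemble
#' state) with normalized state weights, carrying its unit as metadata.
#' All ensemble-level spacing, tilt and radius-of-gyration results are
#' returned in this form, mirroring the conformation weight-adjusted
#' distributions used throughout the analysis.
#'
#' @param values numeric vector of finite scalar values.
#' @param weights nonnegative weights, one per value; renormalized to sum
#'   to 1.
#' @param unit unit string carried as metadata (e.g. `"nm"`, `"degrees"`).
#' @return an object of class `weighted_distribution` with elements
#'   `values`, `weights` and `unit`.
#' @examples
#' d <- weighted_distribution(c(1, 3), c(1, 1), "nm")
#' weighted_quantile(d$values, d$weights, 0.5)  # 2
#' @export
weighted_distribution <- function(values, weights = NULL, unit = "") {
  values <- as.numeric(values)
  if (length(values) == 0) stopf("a weighted distribution needs >= 1 value")
  if (!all(is.finite(values))) stopf("all values must be finite")
  if (is.null(weights)) weights <- rep(1, length(values))
  weights <- normalize_weights(weights, n = length(values))
  structure(list(values = values, weights = weights, unit = unit),
            class = "weighted_distribution")
}

#' Normalize state weights
#'
#' Validates nonnegativity and renormalizes to unit sum. Idempotent.
#'
#' @param weights numeric vector of raw (possibly unnormalized) weights.
#' @param n expected length, or `NULL` to skip the length check.
#' @return weights summing to 1 (within 1e-9).
#' @export
normalize_weights <- function(weights, n = NULL) {
  weights <- as.numeric(weights)
  if (!is.null(n) && length(weights) != n)
    stopf("expected %d weights, got %d", n, length(weights))
  if (anyNA(weights) || !all(is.finite(weights)))
    stopf("weights must be finite")
  if (any(weights < 0)) stopf("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stopf("weights must not all be zero")
  weights / s
}

#' Weighted quantiles with midpoint interpolation
#'
#' Quantile of a discrete weighted sample using the midpoint cumulative
#' rule: sorted values are placed at plot positions
#' \eqn{p_i = c_i - w_i/2} (with \eqn{c_i} the cumulative weight), the
#' quantile is linearly interpolated between the two straddling values,
#' and clamped at the extremes. With two equal-weight values 1 and 3 the
#' median is 2; a single value is every quantile of itself.
#'
#' @param x numeric values.
#' @param w weights (renormalized internally).
#' @param probs quantile targets in `[0, 1]`.
#' @return numeric vector, one quantile per element of `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- normalize_weights(w, n = length(x))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  pk <- cumsum(w) - w / 2
  vapply(probs, function(p) {
    if (p <= pk[1]) return(x[1])
    if (p >= pk[length(pk)]) return(x[length(x)])
    stats::approx(pk, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' @export
print.weighted_distribution <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("weighted distribution of %d values [%s]\n",
              length(x$values), x$unit))
  print(round(s, 4))
  invisible(x)
}

#' Five-number summary of a weighted distribution
#'
#' @param object a [weighted_distribution()].
#' @param ... unused.
#' @return named numeric vector: `min`, `q1`, `median`, `q3`, `max`.
#' @export
summary.weighted_distribution <- function(object, ...) {
  q <- weighted_quantile(object$values, object$weights, c(0.25, 0.5, 0.75))
  c(min = min(object$values), q1 = q[1], median = q[2], q3 = q[3],
    max = max(object$values))
}

#' Write a tabular report of weighted distributions
#'
#' One row per (distribution, statistic) pair, in a fixed order
#' (min, q1, median, q3, max), with columns `distribution`, `statistic`,
#' `value`, `unit`. Values are written at full precision so the report
#' round-trips through [read_distribution_report()].
#'
#' @param dists a named list of [weighted_distribution()] objects.
#' @param path output CSV path.
#' @return the report `data.frame`, invisibly.
#' @export
write_distribution_report <- function(dists, path) {
  if (length(dists) == 0) stopf("empty distribution list")
  if (inherits(dists, "weighted_distribution")) dists <- list(dists)
  nms <- names(dists) %||% paste0("dist", seq_along(dists))
  if (is.null(names(dists))) names(dists) <- nms
  stats_order <- c("min", "q1", "median", "q3", "max")
  rows <- do.call(rbind, lapply(seq_along(dists), function(i) {
    s <- summary(dists[[i]])
    data.frame(distribution = nms[i], statistic = stats_order,
               value = unname(s[stats_order]), unit = dists[[i]]$unit,
               stringsAsFactors = FALSE)
  }))
  ok <- tryCatch({
    utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write report to '%s': %s", path,
                         conditionMessage(ok))
  invisible(rows)
}

#' Read back a distribution report
#'
#' @param path CSV written by [write_distribution_report()].
#' @return `data.frame` with columns distribution, statistic, value, unit.
#' @export
read_distribution_report <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows$value <- as.numeric(rows$value)
  rows
}
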