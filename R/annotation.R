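#' Ensemble annotations: named atom selections
#'
#' An annotation maps the landmarks of the analysis onto atoms: the two
#' paratope tips (heavy-chain CDR3 apexes), the two membrane anchors
#' (C-terminal sites that would tether the antigen ectodomains to their
#' cells), the superposition reference subcomplex, the head and tail of
#' the antigen--binder axis used for domain tilt angles, and any number
#' of named domains.
#'
#' Selection expressions are comma-separated terms of the form
#' `CHAIN[:RESRANGE[:ATOMNAME]]`, e.g. `"A"`, `"B:3-7"`, `"D:12:CA"`,
#' `"A:38-40:CA, B:1:CA"`. `RESRANGE` is a single residue index or
#' `lo-hi`; `*` matches everything at that position.
#'
#' @param roles named list/character vector of selection expressions for
#'   the seven required roles: `paratope_tip_1`, `paratope_tip_2`,
#'   `anchor_1`, `anchor_2`, `reference`, `axis_head`, `axis_tail`.
#' @param domains named list/character vector of domain-name -> selection.
#' @return object of class `ensemble_annotation`.
#' @export
ensemble_annotation <- function(roles, domains = list()) {
  roles <- as.list(roles)
  domains <- as.list(domains)
  required <- c("paratope_tip_1", "paratope_tip_2", "anchor_1", "anchor_2",
                "reference", "axis_head", "axis_tail")
  miss <- setdiff(required, names(roles))
  if (length(miss))
    stopf("annotation is missing required role(s): %s",
          paste(miss, collapse = ", "))
  all_sel <- c(roles, domains)
  for (nm in names(all_sel)) parse_selection(all_sel[[nm]], context = nm)
  structure(list(roles = lapply(roles, as.character),
                 domains = lapply(domains, as.character)),
            class = "ensemble_annotation")
}

#' @export
print.ensemble_annotation <- function(x, ...) {
  cat("ensemble annotation\n roles:\n")
  for (nm in names(x$roles)) cat(sprintf("   %-15s %s\n", nm, x$roles[[nm]]))
  if (length(x$domains)) {
    cat(" domains:\n")
    for (nm in names(x$domains))
      cat(sprintf("   %-15s %s\n", nm, x$domains[[nm]]))
  }
  invisible(x)
}

# Parse a selection expression into a list of term records.
parse_selection <- function(expr, context = "selection") {
  expr <- as.character(expr)
  if (length(expr) != 1 || !nzchar(trimws(expr)))
    stopf("%s: empty selection expression", context)
  terms <- trimws(strsplit(expr, ",")[[1]])
  lapply(terms, function(tm) {
    parts <- trimws(strsplit(tm, ":")[[1]])
    if (length(parts) < 1 || length(parts) > 3 || !nzchar(parts[1]))
      stopf("%s: malformed selection term '%s'", context, tm)
    res <- if (length(parts) >= 2 && parts[2] != "*") parts[2] else NULL
    rng <- NULL
    if (!is.null(res)) {
      m <- regmatches(res, regexec("^(-?[0-9]+)(-(-?[0-9]+))?$", res))[[1]]
      if (!length(m)) stopf("%s: bad residue range '%s'", context, res)
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
      rng <- c(lo, hi)
    }
    atom <- if (length(parts) == 3 && parts[3] != "*") parts[3] else NULL
    list(chain = parts[1], resno = rng, elety = atom)
  })
}

#' Resolve a selection expression to atom indices in a state
#'
#' @param state a [structure_state()].
#' @param selection selection expression string (see
#'   [ensemble_annotation()]).
#' @param role optional role name, used in error messages.
#' @return integer vector of row indices into `state$atoms`.
#' @export
resolve_selection <- function(state, selection, role = selection) {
  terms <- parse_selection(selection, context = role)
  a <- state$atoms
  hit <- rep(FALSE, nrow(a))
  for (tm in terms) {
    m <- if (tm$chain == "*") rep(TRUE, nrow(a)) else a$chain == tm$chain
    if (!is.null(tm$resno))
      m <- m & a$resno >= tm$resno[1] & a$resno <= tm$resno[2]
    if (!is.null(tm$elety)) m <- m & a$elety == tm$elety
    hit <- hit | m
  }
  idx <- which(hit)
  if (!length(idx))
    stopf("selection '%s' (role '%s') matches no atoms in state '%s'",
          selection, role, state$label)
  idx
}

lookup_selection <- function(annotation, name) {
  if (!is.null(annotation$roles[[name]])) return(annotation$roles[[name]])
  if (!is.null(annotation$domains[[name]])) return(annotation$domains[[name]])
  name  # treat as a literal selection expression
}

#' Centroid of a selection in one state
#'
#' Unweighted mean position of the selected atoms, in Angstrom. This is
#' how point landmarks ("tip of the CDR3 loop", "C-terminal anchor") are
#' realized from multi-atom selections.
#'
#' @param state a [structure_state()].
#' @param selection role/domain name (when `annotation` is given) or a
#'   literal selection expression.
#' @param annotation optional [ensemble_annotation()] used to look up
#'   `selection` by name.
#' @return length-3 numeric vector (x, y, z) in Angstrom.
#' @export
selection_centroid <- function(state, selection, annotation = NULL) {
  expr <- if (is.null(annotation)) selection
          else lookup_selection(annotation, selection)
  idx <- resolve_selection(state, expr, role = selection)
  colMeans(coords(state)[idx, , drop = FALSE])
}

#' Parse an annotation config file
#'
#' YAML with top-level maps `roles:` and (optionally) `domains:`. All
#' seven required roles must be present; their selection syntax is
#' validated at parse time, and resolution against actual states is
#' checked by [validate_annotation()].
#'
#' @param path YAML file path.
#' @return an [ensemble_annotation()].
#' @export
parse_annotation <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$roles)) stopf("annotation '%s' has no 'roles' map", path)
  ensemble_annotation(cfg$roles, cfg$domains %||% list())
}

#' Serialize an annotation to YAML
#'
#' Round-trips through [parse_annotation()].
#'
#' @param annotation an [ensemble_annotation()].
#' @param path output path.
#' @return `invisible(NULL)`.
#' @export
write_annotation <- function(annotation, path) {
  yaml::write_yaml(list(roles = annotation$roles,
                        domains = annotation$domains), path)
  invisible(NULL)
}

#' Check an annotation against every state of an ensemble
#'
#' Verifies that every role and domain resolves to at least one atom in
#' every state and that the axis head and tail centroids are distinct
#' (> 0.1 Angstrom apart) everywhere.
#'
#' @param annotation an [ensemble_annotation()].
#' @param ensemble a [weighted_ensemble()].
#' @return coverage report: `data.frame` with one row per (state, role)
#'   giving the matched atom count.
#' @export
validate_annotation <- function(annotation, ensemble) {
  sel <- c(annotation$roles, annotation$domains)
  rows <- expand.grid(state = vapply(ensemble$states, function(s) s$label, ""),
                      name = names(sel), stringsAsFactors = FALSE)
  rows$n_atoms <- mapply(function(lab, nm) {
    st <- ensemble$states[[match(lab, vapply(ensemble$states,
                                             function(s) s$label, ""))]]
    length(resolve_selection(st, sel[[nm]], role = nm))
  }, rows$state, rows$name)
  for (st in ensemble$states) {
    h <- selection_centroid(st, "axis_head", annotation)
    t <- selection_centroid(st, "axis_tail", annotation)
    if (sqrt(sum((h - t)^2)) <= 0.1)
      stopf("axis_head and axis_tail centroids coincide in state '%s'",
            st$label)
  }
  rows
}
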