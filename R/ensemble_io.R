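#' Single conformational state
#'
#' One labeled 3D conformation: a flat atom table with coordinates in
#' Angstrom. States are the unit a multistate SAXS model is built from;
#' an ensemble pairs many of them with fractional weights.
#'
#' @param atoms `data.frame` with columns `eleno` (integer atom id),
#'   `chain` (short string), `resno` (integer residue index), `resid`
#'   (residue name), `elety` (atom name), `x`, `y`, `z` (Angstrom) and
#'   optionally `elesy` (element symbol; derived from `elety` when absent).
#' @param label state label (source file or model number).
#' @return object of class `structure_state`.
#' @export
structure_state <- function(atoms, label = "state") {
  need <- c("eleno", "chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stopf("a state needs at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("state '%s': non-finite coordinates", label)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stopf("state '%s': duplicated (chain, resno, atom name) triple(s): %s",
          label, key[duplicated(key)][1])
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)) || all(atoms$elesy == ""))
    atoms$elesy <- substr(gsub("[^A-Za-z].*$", "", atoms$elety), 1, 1)
  structure(list(atoms = atoms, label = as.character(label)),
            class = "structure_state")
}

#' Coordinates of a state as an n x 3 matrix (Angstrom)
#' @param state a [structure_state()].
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(state) {
  as.matrix(state$atoms[, c("x", "y", "z")])
}

#' @export
print.structure_state <- function(x, ...) {
  cat(sprintf("structure state '%s': %d atoms, %d chain(s)\n", x$label,
              nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Weighted multistate ensemble
#'
#' States plus normalized effective weights — the unit of every ensemble
#' analysis (spacing, tilt, flexibility, mixture scattering).
#'
#' @param states list of [structure_state()] objects.
#' @param weights nonnegative state weights; renormalized to sum to 1.
#' @return object of class `weighted_ensemble` with `states` and `weights`.
#' @export
weighted_ensemble <- function(states, weights = NULL) {
  if (!length(states)) stopf("an ensemble needs >= 1 state")
  if (!all(vapply(states, inherits, logical(1), "structure_state")))
    stopf("all states must be structure_state objects")
  if (is.null(weights)) weights <- rep(1, length(states))
  if (length(weights) != length(states))
    stopf("state/weight count mismatch: %d states, %d weights",
          length(states), length(weights))
  weights <- normalize_weights(weights, n = length(states))
  structure(list(states = states, weights = weights),
            class = "weighted_ensemble")
}

#' Number of states in an ensemble
#' @param ensemble a [weighted_ensemble()].
#' @return integer state count.
#' @export
n_states <- function(ensemble) length(ensemble$states)

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat(sprintf("weighted ensemble: %d state(s), weight entropy %.4f nats\n",
              n_states(x), weight_entropy(x$weights)))
  invisible(x)
}

#' Read a state-weight table
#'
#' Two columns (state label, weight), tab- or comma-separated, `#`
#' comments allowed. Raw weights are accepted and renormalized by the
#' caller; negative weights are rejected here.
#'
#' @param path file path, or a `data.frame` with two columns passed through.
#' @return `data.frame` with character `label` and numeric `weight`.
#' @export
read_weight_table <- function(path) {
  if (is.data.frame(path)) {
    tab <- path
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stopf("weight table '%s' is empty", path)
    sep <- if (any(grepl(",", lines))) "," else "[ \t]+"
    parts <- strsplit(lines, sep)
    if (any(lengths(parts) < 2))
      stopf("weight table '%s': every row needs (label, weight)", path)
    tab <- data.frame(label = vapply(parts, function(p) trimws(p[1]), ""),
                      weight = vapply(parts, function(p) trimws(p[2]), ""),
                      stringsAsFactors = FALSE)
  }
  names(tab)[1:2] <- c("label", "weight")
  w <- suppressWarnings(as.numeric(tab$weight))
  if (anyNA(w)) stopf("weight table: non-numeric weight for label '%s'",
                      tab$label[which(is.na(w))[1]])
  if (any(w < 0)) stopf("weight table: negative weight for label '%s'",
                        tab$label[which(w < 0)[1]])
  data.frame(label = as.character(tab$label), weight = w,
             stringsAsFactors = FALSE)
}

pdb_to_states <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stopf("cannot parse PDB '%s': %s", path,
                          conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stopf("cannot parse PDB '%s': no ATOM records found", path)
  nm <- nrow(pdb$xyz)
  base <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  atoms0 <- pdb$atom[, c("eleno", "chain", "resno", "resid", "elety")]
  atoms0$elesy <- pdb$atom$elesy %||% NA_character_
  lapply(seq_len(nm), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    a <- atoms0
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    label <- if (nm > 1) as.character(m) else base
    structure_state(a, label = label)
  })
}

#' Read a multistate ensemble from PDB files plus a weight table
#'
#' Accepts either a set of single-state PDB files or one multi-model PDB
#' (MODEL/ENDMDL records map to states in file order, keyed by model
#' number). States are returned in weight-table row order and weights are
#' renormalized to sum to 1, so the table may hold raw (e.g. MultiFoXS
#' style) contributions.
#'
#' @param structure_paths character vector of PDB paths; a single path may
#'   be a multi-model file.
#' @param weight_table path to a label/weight table ([read_weight_table()]
#'   dialect) or an equivalent `data.frame`. `NULL` assigns uniform
#'   weights in file/model order.
#' @return a [weighted_ensemble()].
#' @export
read_multistate <- function(structure_paths, weight_table = NULL) {
  for (p in structure_paths)
    if (!file.exists(p)) stopf("PDB file not found: '%s'", p)
  states <- do.call(c, lapply(structure_paths, pdb_to_states))
  if (is.null(weight_table))
    return(weighted_ensemble(states))
  tab <- read_weight_table(weight_table)
  if (nrow(tab) != length(states))
    stopf("state/weight count mismatch: %d state(s) read, %d weight row(s)",
          length(states), nrow(tab))
  labels <- vapply(states, function(s) s$label, "")
  idx <- match(tab$label, labels)
  if (anyNA(idx))
    stopf("weight table labels not found among states: %s",
          paste(tab$label[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stopf("weight table repeats a state label")
  weighted_ensemble(states[idx], tab$weight)
}

# Fixed-column PDB ATOM record (columns per the wwPDB format v3.3).
format_atom_record <- function(eleno, elety, resid, chain, resno, x, y, z,
                               elesy) {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno, name, resid, chain, resno, x, y, z, 1, 0, elesy)
}

#' Write an ensemble as a multi-model PDB plus weight table
#'
#' States become MODEL/ENDMDL blocks numbered 1..n in ensemble order;
#' the companion weight table keys weights by model number, the layout
#' [read_multistate()] consumes. Coordinates are written at the PDB's
#' native 0.001 Angstrom precision.
#'
#' @param ensemble a [weighted_ensemble()].
#' @param pdb_path output multi-model PDB path.
#' @param weight_path output tab-separated weight-table path.
#' @return `invisible(NULL)`.
#' @export
write_multistate <- function(ensemble, pdb_path, weight_path) {
  con <- file(pdb_path, "w")
  on.exit(close(con))
  for (m in seq_len(n_states(ensemble))) {
    a <- ensemble$states[[m]]$atoms
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(mapply(format_atom_record, a$eleno, a$elety, a$resid, a$chain,
                      a$resno, a$x, a$y, a$z, a$elesy), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  writeLines(c("# state weights (label = model number)",
               sprintf("%d\t%.12g", seq_len(n_states(ensemble)),
                       ensemble$weights)),
             weight_path)
  invisible(NULL)
}

#' SAXS profile container
#'
#' Scattering intensity on a strictly increasing q grid, with per-point
#' uncertainties. When no uncertainties are supplied they are imputed as
#' a fixed fraction of the intensity (needed by the chi statistic).
#'
#' @param q momentum transfer grid in inverse Angstrom, strictly positive.
#' @param intensity intensities (arbitrary units), same length as `q`.
#' @param sigma optional uncertainties; imputed as
#'   `sigma_fraction * intensity` when `NULL`.
#' @param sigma_fraction imputation fraction, default 0.03.
#' @param sort sort by q if not already increasing (with a warning).
#' @return object of class `saxs_profile` with `q`, `intensity`, `sigma`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, sigma_fraction = 0.03,
                         sort = TRUE) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stopf("q/intensity length mismatch")
  if (length(q) < 5) stopf("a SAXS profile needs >= 5 points")
  if (!all(is.finite(q)) || !all(is.finite(intensity)))
    stopf("non-finite values in SAXS profile")
  if (any(q <= 0)) stopf("q must be strictly positive")
  if (all(intensity <= 0)) stopf("all intensities are nonpositive")
  if (!is.null(sigma) && length(sigma) != length(q))
    stopf("sigma length mismatch")
  if (is.unsorted(q, strictly = TRUE)) {
    if (!sort) stopf("q grid not strictly increasing")
    warning("q grid not increasing; sorting profile by q", call. = FALSE)
    o <- order(q)
    q <- q[o]; intensity <- intensity[o]
    if (!is.null(sigma)) sigma <- sigma[o]
    if (any(diff(q) == 0)) stopf("duplicated q values")
  }
  if (is.null(sigma)) sigma <- sigma_fraction * abs(intensity)
  structure(list(q = q, intensity = intensity, sigma = as.numeric(sigma)),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile: %d points, q in [%.4g, %.4g] 1/Angstrom\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Read a 3-column SAXS curve
#'
#' Whitespace-separated `q I [sigma]` text with `#` comment lines. Rows
#' are sorted by q when necessary (with a warning); a missing sigma column
#' is imputed as `sigma_fraction * I`.
#'
#' @param path input file.
#' @param sigma_fraction imputation fraction for a missing sigma column.
#' @return a [saxs_profile()].
#' @export
read_saxs_profile <- function(path, sigma_fraction = 0.03) {
  lines <- readLines(path, warn = FALSE)
  raw <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(raw)
  rows <- strsplit(raw[keep], "[ \t,]+")
  lineno <- which(keep)
  if (length(rows) < 5) stopf("'%s': fewer than 5 data rows", path)
  ncol <- lengths(rows)
  if (any(ncol < 2)) stopf("'%s': line %d has fewer than 2 columns",
                           path, lineno[which(ncol < 2)[1]])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad)) stopf("'%s': non-numeric value on line %d", path,
                         lineno[bad[1]])
  q <- vapply(vals, `[`, numeric(1), 1)
  i <- vapply(vals, `[`, numeric(1), 2)
  s <- if (all(ncol >= 3)) vapply(vals, `[`, numeric(1), 3) else NULL
  saxs_profile(q, i, s, sigma_fraction = sigma_fraction)
}

#' Write a SAXS profile as 3-column text
#'
#' Full double precision, so a written profile re-reads bit-faithfully.
#'
#' @param profile a [saxs_profile()].
#' @param path output path.
#' @return `invisible(NULL)`.
#' @export
write_saxs_profile <- function(profile, path) {
  writeLines(c("# q(1/Angstrom)  I(q)  sigma",
               sprintf("%.17g %.17g %.17g", profile$q, profile$intensity,
                       profile$sigma)),
             path)
  invisible(NULL)
}
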