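# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# Quick state from an n x 3 coordinate matrix (one chain, CA beads).
make_state <- function(xyz, chain = "A", label = "s", resno = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(chain) == 1) chain <- rep(chain, n)
  if (is.null(resno)) resno <- stats::ave(seq_len(n), chain, FUN = seq_along)
  structure_state(data.frame(
    eleno = seq_len(n), chain = chain, resno = resno, resid = "ALA",
    elety = "CA", elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), label = label)
}

# Annotation whose seven roles all resolve in states built by make_state
# with chains H (head), T (tail), D (domain of interest).
htd_annotation <- function(domain_expr = "D") {
  ensemble_annotation(
    roles = list(paratope_tip_1 = "H", paratope_tip_2 = "T",
                 anchor_1 = "H", anchor_2 = "T", reference = "H, T",
                 axis_head = "H", axis_tail = "T"),
    domains = list(dom = domain_expr))
}

# State with chains H (3 beads near head), T (3 beads near tail) and a
# rod domain D of n beads from `from` to `to`.
htd_state <- function(from, to, n = 21, head = c(0, 0, 0),
                      tail = c(0, 0, 50), label = "s", jitter = 0) {
  tri <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))
  rod <- cbind(seq(from[1], to[1], length.out = n),
               seq(from[2], to[2], length.out = n),
               seq(from[3], to[3], length.out = n))
  if (jitter > 0) rod <- rod + matrix(stats::rnorm(3 * n, 0, jitter), n, 3)
  xyz <- rbind(sweep(tri, 2, head, "+"), sweep(tri, 2, tail, "+"), rod)
  make_state(xyz, chain = rep(c("H", "T", "D"), c(3, 3, n)), label = label)
}

# Uniformly filled ball of beads (Monte Carlo), radius in Angstrom.
ball_state <- function(n, radius, seed, center = c(0, 0, 0)) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  make_state(sweep(u * r, 2, center, "+"), label = "ball")
}

# Apply one rigid transform to a state (test-side helper).
transform_state <- function(state, R, t) {
  xyz <- coords(state) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  st <- state
  st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
  st
}

rot_about_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Independent random rotation via normalized quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Shared SAXS mixture-recovery scenario: extended vs bent truth pair,
# bent decoys, dense beamline-like grid.
mixture_scenario <- function() {
  tm <- tce_template()
  q <- seq(0.005, 0.45, length.out = 2000)
  ext <- sample_conformations(tm, 1, seed = 101, kappa = 0)$ensemble$states[[1]]
  cmp <- sample_conformations(tm, 1, seed = 102, kappa = 120)$ensemble$states[[1]]
  decoys <- lapply(1:8, function(i)
    sample_conformations(tm, 1, seed = 200 + i,
                         kappa = 120)$ensemble$states[[1]])
  pool <- lapply(c(list(ext, cmp), decoys), debye_profile, q_grid = q)
  names(pool) <- c("true_ext", "true_cmp", paste0("decoy_", 1:8))
  list(template = tm, q = q, ext = ext, cmp = cmp, pool = pool)
}
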