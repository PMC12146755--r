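test_that("radius of gyration matches analytic cases", {
  # single atom
  expect_equal(state_radius_of_gyration(make_state(rbind(c(1, 2, 3)))), 0)
  # equal-mass dumbbell 2 nm apart -> 1 nm
  dumb <- make_state(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(state_radius_of_gyration(dumb), 1.0, tolerance = 1e-12)
  # uniform filled ball of radius R -> sqrt(3/5) R (Monte-Carlo filling)
  R <- 15
  ball <- ball_state(30000, R, seed = 40)
  expect_equal(state_radius_of_gyration(ball), sqrt(3 / 5) * R / 10,
               tolerance = 0.01)
})

test_that("unknown elements fall back to carbon mass with a warning", {
  st <- make_state(rbind(c(0, 0, 0), c(20, 0, 0)))
  st$atoms$elesy <- c("C", "XX")
  expect_warning(rg <- state_radius_of_gyration(st), "unknown element")
  expect_equal(rg, 1.0, tolerance = 1e-12)
})

test_that("rg distribution carries ensemble weights", {
  s2 <- make_state(rbind(c(0, 0, 0), c(20, 0, 0)))          # Rg 1 nm
  s4 <- make_state(rbind(c(0, 0, 0), c(40, 0, 0)))          # Rg 2 nm
  s4$label <- "b"
  d <- rg_distribution(weighted_ensemble(list(s2, s4)))
  expect_equal(unname(summary(d)["median"]), 1.5, tolerance = 1e-12)
  d1 <- rg_distribution(weighted_ensemble(list(s2)))
  expect_length(d1$values, 1)
})

test_that("CoM flexibility matches analytic and brute-force values", {
  base <- ball_state(30, 6, seed = 3, center = c(0, 0, 0))
  shift <- transform_state(base, diag(3), c(8, 0, 0))
  shift$label <- "s"
  # identical states -> 0
  same <- base; same$label <- "c"
  expect_equal(com_flexibility(weighted_ensemble(list(base, same))), 0,
               tolerance = 1e-12)
  # two equal-weight states displaced by d -> d/2 (0.4 nm for 8 A)
  expect_equal(com_flexibility(weighted_ensemble(list(base, shift))), 0.4,
               tolerance = 1e-9)

  # 200-state ensemble vs explicit double loop
  sim <- sample_conformations(tce_template(), n_states = 200, seed = 77,
                              kappa = 50, weight_scheme = "dirichlet")
  sup <- superpose_states(sim$ensemble, sim$annotation)
  got <- com_flexibility(sup$ensemble, sim$annotation, "binder2")
  w <- sup$ensemble$weights
  coms <- matrix(0, 200, 3)
  for (i in 1:200) {
    s <- sup$ensemble$states[[i]]
    idx <- resolve_selection(s, "D")
    coms[i, ] <- colMeans(coords(s)[idx, , drop = FALSE])
  }
  cbar <- c(sum(w * coms[, 1]), sum(w * coms[, 2]), sum(w * coms[, 3]))
  acc <- 0
  for (i in 1:200) acc <- acc + w[i] * sum((coms[i, ] - cbar)^2)
  expect_equal(got, sqrt(acc) / 10, tolerance = 1e-9)
})

test_that("rotational flexibility matches symmetry and an optimization oracle", {
  dom <- ball_state(25, 8, seed = 9)
  ann <- ensemble_annotation(
    roles = list(paratope_tip_1 = "A:1", paratope_tip_2 = "A:2",
                 anchor_1 = "A:1", anchor_2 = "A:2", reference = "A",
                 axis_head = "A:1", axis_tail = "A:2"),
    domains = list(dom = "A"))

  # identical states -> 0
  d2 <- dom; d2$label <- "b"
  expect_equal(rotational_flexibility(weighted_ensemble(list(dom, d2)),
                                      ann, "dom"), 0, tolerance = 1e-6)

  # +/- theta about a fixed axis through the CoM -> theta (theta = 90
  # itself is excluded: the two orientations are then antipodal and the
  # mean orientation is genuinely ill-defined)
  com <- colMeans(coords(dom))
  rot_about_com <- function(angle) {
    R <- rot_about_z(angle)
    transform_state(dom, R, as.numeric(com - R %*% com))
  }
  for (theta in c(10, 45, 80)) {
    a <- rot_about_com(theta * pi / 180); a$label <- "p"
    b <- rot_about_com(-theta * pi / 180); b$label <- "m"
    got <- rotational_flexibility(weighted_ensemble(list(a, b)), ann, "dom")
    expect_equal(got, theta, tolerance = 1e-6)
  }

  # random-rotation ensemble vs independent axis-angle optimization oracle:
  # states are built FROM known rotations; the oracle searches the mean
  # orientation over rotation vectors without quaternions or Kabsch
  set.seed(55)
  n <- 25
  Rs <- list(diag(3))
  for (i in 2:n) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    Rs[[i]] <- spanflex:::rot_axis(ax, stats::runif(1, 0, 0.5))
  }
  w <- normalize_weights(stats::rgamma(n, 2))
  states <- lapply(seq_len(n), function(i) {
    st <- transform_state(dom, Rs[[i]], as.numeric(com - Rs[[i]] %*% com))
    st$label <- paste0("r", i)
    st
  })
  ens <- weighted_ensemble(states, w)
  got <- rotational_flexibility(ens, ann, "dom")

  angle_between <- function(Ra, Rb) {
    Rrel <- Ra %*% t(Rb)
    acos(min(1, max(-1, (sum(diag(Rrel)) - 1) / 2)))
  }
  objective <- function(par) {
    a <- sqrt(sum(par^2))
    Rm <- if (a < 1e-12) diag(3) else spanflex:::rot_axis(par / a, a)
    sum(w * vapply(Rs, angle_between, numeric(1), Rb = Rm)^2)
  }
  opt <- stats::optim(c(0, 0, 0), objective, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  oracle <- sqrt(opt$value) * 180 / pi
  expect_equal(got, oracle, tolerance = 0.1 / max(got, 1))
})

test_that("effective disorder and weight entropy follow their closed forms", {
  expect_equal(effective_disorder(0, 123), 0)
  expect_equal(effective_disorder(2, 30), 60)
  expect_error(effective_disorder(-1, 3), "nonnegative")
  expect_equal(weight_entropy(1), 0)
  expect_equal(weight_entropy(rep(1 / 7, 7)), log(7), tolerance = 1e-12)
  expect_equal(weight_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2),
               tolerance = 1e-12)
  expect_equal(weight_entropy(c(0.5, 0.5, 0)), log(2), tolerance = 1e-12)
})

test_that("single-state ensembles have exactly zero flexibility", {
  sim <- sample_conformations(tce_template(), n_states = 1, seed = 3,
                              kappa = 45)
  sup <- superpose_states(sim$ensemble, sim$annotation)
  rep <- flexibility_report(sup$ensemble, sim$annotation)
  expect_equal(rep$domains$com_flex_nm, rep(0, nrow(rep$domains)),
               tolerance = 1e-9)
  expect_equal(rep$domains$rot_flex_deg, rep(0, nrow(rep$domains)),
               tolerance = 1e-6)
  expect_equal(rep$domains$effective_disorder,
               rep$domains$com_flex_nm * rep$domains$rot_flex_deg)
  expect_equal(rep$weight_entropy, 0)
})

test_that("metrics are invariant to post-alignment rigid motion and weight splitting", {
  sim <- sample_conformations(tce_template(), n_states = 40, seed = 23,
                              kappa = 35, weight_scheme = "dirichlet")
  sup <- superpose_states(sim$ensemble, sim$annotation)
  ens <- sup$ensemble
  cf0 <- com_flexibility(ens, sim$annotation, "fc")
  rf0 <- rotational_flexibility(ens, sim$annotation, "fc")
  rg0 <- summary(rg_distribution(ens))

  R <- random_rotation()
  moved <- ens
  moved$states <- lapply(ens$states, transform_state, R = R,
                         t = c(5, -40, 11))
  expect_equal(com_flexibility(moved, sim$annotation, "fc"), cf0,
               tolerance = 1e-9)
  expect_equal(rotational_flexibility(moved, sim$annotation, "fc"), rf0,
               tolerance = 1e-6)
  expect_equal(summary(rg_distribution(moved)), rg0, tolerance = 1e-9)

  # duplicating every state with halved weights changes nothing
  dup <- weighted_ensemble(
    c(ens$states, lapply(ens$states, function(s) {
      s$label <- paste0(s$label, "_dup"); s
    })),
    c(ens$weights / 2, ens$weights / 2))
  expect_equal(com_flexibility(dup, sim$annotation, "fc"), cf0,
               tolerance = 1e-9)
  expect_equal(rotational_flexibility(dup, sim$annotation, "fc"), rf0,
               tolerance = 1e-6)
  expect_equal(weight_entropy(dup$weights),
               weight_entropy(ens$weights) + log(2), tolerance = 1e-9)
})
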