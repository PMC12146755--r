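test_that("Debye profiles match closed forms and a brute-force double loop", {
  q <- seq(0.01, 0.6, length.out = 40)
  # single bead: I(q) = 1 everywhere
  p1 <- debye_profile(make_state(rbind(c(0, 0, 0))), q)
  expect_equal(p1$intensity, rep(1, 40), tolerance = 1e-14)
  # two beads at separation d: I(q) = 2 (1 + sin(qd)/(qd))
  d <- 17.3
  p2 <- debye_profile(make_state(rbind(c(0, 0, 0), c(d, 0, 0))), q)
  expect_equal(p2$intensity, 2 * (1 + sin(q * d) / (q * d)),
               tolerance = 1e-10)
  expect_equal(attr(p2, "i0"), 4)

  # 300-bead random coil vs naive double loop
  set.seed(12)
  xyz <- apply(matrix(stats::rnorm(900, 0, 2.5), 300, 3), 2, cumsum)
  st <- make_state(xyz)
  got <- debye_profile(st, q)
  brute <- numeric(40)
  for (i in 1:300) {
    dij <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    sm <- outer(dij, q)
    brute <- brute + colSums(ifelse(sm == 0, 1, sin(sm) / sm))
  }
  expect_equal(got$intensity, brute, tolerance = 1e-10)
})

test_that("Debye profiles are rigid-transform invariant and Guinier-bounded", {
  q <- seq(0.005, 0.3, length.out = 50)
  st <- ball_state(120, 12, seed = 5)
  p0 <- debye_profile(st, q)
  set.seed(6)
  st2 <- transform_state(st, random_rotation(), c(100, -5, 8))
  p2 <- debye_profile(st2, q)
  expect_equal(p2$intensity, p0$intensity, tolerance = 1e-10)
  # I(q) <= I(0) in the Guinier regime
  g <- guinier_fit(p0)
  low <- q * g$rg <= 1
  expect_true(all(p0$intensity[low] <= attr(p0, "i0") + 1e-9))
})

test_that("ensemble profiles are exact convex mixtures", {
  q <- seq(0.01, 0.4, length.out = 30)
  ps <- lapply(1:3, function(i)
    debye_profile(ball_state(40 + 10 * i, 8 + i, seed = i), q))
  w <- c(0.2, 0.5, 0.3)
  mix <- ensemble_profile(ps, w)
  manual <- w[1] * ps[[1]]$intensity + w[2] * ps[[2]]$intensity +
    w[3] * ps[[3]]$intensity
  expect_equal(mix$intensity, manual, tolerance = 1e-12)
  # single profile and duplicated-profile fixed points
  expect_equal(ensemble_profile(ps[1], 1)$intensity, ps[[1]]$intensity)
  expect_equal(ensemble_profile(ps[c(1, 1)], c(0.3, 0.7))$intensity,
               ps[[1]]$intensity, tolerance = 1e-12)
  bad <- saxs_profile(q + 0.001, ps[[1]]$intensity)
  expect_error(ensemble_profile(list(ps[[1]], bad), c(0.5, 0.5)),
               "common q grid")
})

test_that("Guinier fit recovers exact and spherical scatterers", {
  # exact Guinier curve: I = 7 exp(-q^2 Rg^2 / 3), Rg = 20
  q <- seq(0.002, 0.2, length.out = 150)
  p <- saxs_profile(q, 7 * exp(-q^2 * 400 / 3))
  g <- guinier_fit(p)
  expect_equal(g$rg, 20, tolerance = 1e-3)
  expect_equal(g$i0, 7, tolerance = 1e-3)

  # Debye profile of a uniform ball radius R: Rg within 2% of sqrt(3/5) R
  R <- 15
  qs <- seq(0.004, 0.35, length.out = 120)
  ball <- ball_state(800, R, seed = 14)
  pb <- debye_profile(ball, qs)
  gb <- guinier_fit(pb)
  expect_equal(gb$rg, sqrt(3 / 5) * R, tolerance = 0.02)
  expect_true(all(qs[gb$window] * gb$rg <= 1.3 + 1e-9))

  # 1% Gaussian noise moves Rg by < 5%
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(99)
  noisy <- saxs_profile(qs, pb$intensity *
                          (1 + stats::rnorm(length(qs), 0, 0.01)))
  if (has) assign(".Random.seed", old, envir = globalenv())
  gn <- guinier_fit(noisy)
  expect_equal(gn$rg, gb$rg, tolerance = 0.05)

  # rising low-q intensity has no Guinier regime
  expect_error(guinier_fit(saxs_profile(q, 1 + q^2)), "slope")
})

test_that("dimensionless Kratky transform has the globular peak and flexible limit", {
  # exact Guinier curve: peak at (sqrt(3), 3/e)
  rg <- 20
  q <- seq(0.001, 3.2 / rg, length.out = 1500)
  p <- saxs_profile(q, 5 * exp(-q^2 * rg^2 / 3))
  k <- dimensionless_kratky(p, rg = rg, i0 = 5)
  pk <- which.max(k$y)
  expect_equal(k$x[pk], sqrt(3), tolerance = 0.005)
  expect_equal(k$y[pk], 3 / exp(1), tolerance = 0.005)

  # flat profile (point scatterer): y = x^2 exactly, monotone increasing
  pf <- saxs_profile(q, rep(4, length(q)))
  kf <- dimensionless_kratky(pf, rg = rg, i0 = 4)
  expect_equal(kf$y, kf$x^2, tolerance = 1e-12)
  expect_true(all(diff(kf$y) > 0))
})

test_that("flexible ensembles show elevated Kratky amplitude beyond the peak", {
  # a heterogeneous multi-domain ensemble vs a rigid globular particle of
  # comparable size: the flexible ensemble keeps its dimensionless Kratky
  # amplitude elevated past the globular peak instead of decaying
  tm <- tce_template()
  q <- seq(0.004, 0.3, length.out = 200)
  sim <- sample_conformations(tm, n_states = 30, seed = 72, kappa = 90)
  flex_prof <- ensemble_profile(lapply(sim$ensemble$states, debye_profile,
                                       q_grid = q),
                                sim$ensemble$weights)
  glob_prof <- debye_profile(ball_state(800, 15, seed = 1), q)
  xs <- seq(2, 3, length.out = 25)
  amp <- function(p) {
    k <- dimensionless_kratky(p)
    mean(stats::approx(k$x, k$y, xout = xs)$y)
  }
  expect_gt(amp(flex_prof), amp(glob_prof))
  # and the globular reference itself peaks near the Guinier point
  kg <- dimensionless_kratky(glob_prof)
  expect_equal(kg$x[which.max(kg$y)], sqrt(3), tolerance = 0.15)
})

test_that("chi fitting matches closed forms, grid search, and is scale-invariant", {
  q <- seq(0.01, 0.3, length.out = 60)
  m <- debye_profile(ball_state(100, 10, seed = 8), q)

  # exact proportionality: chi = 0, scale = 3.7
  e <- saxs_profile(q, 3.7 * m$intensity, sigma = 0.02 * m$intensity)
  f <- chi_fit(m, e)
  expect_equal(f$chi, 0, tolerance = 1e-8)
  expect_equal(f$scale, 3.7, tolerance = 1e-10)

  # constructed +/- sigma residuals on a flat model: chi = 1
  mf <- saxs_profile(q, rep(5, 60))
  ef <- saxs_profile(q, 5 + rep(c(1, -1), 30), sigma = rep(1, 60))
  ff <- chi_fit(mf, ef)
  expect_equal(ff$chi, 1, tolerance = 1e-12)
  expect_equal(ff$scale, 1, tolerance = 1e-12)

  # random perturbation: closed-form scale beats/equals a fine grid search
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(31)
  ep <- saxs_profile(q, 2.2 * m$intensity *
                       (1 + stats::rnorm(60, 0, 0.03)),
                     sigma = 0.03 * 2.2 * m$intensity)
  if (has) assign(".Random.seed", old, envir = globalenv())
  fp <- chi_fit(m, ep)
  chi_at <- function(sc)
    sqrt(mean(((ep$intensity - sc * m$intensity) / ep$sigma)^2))
  grid <- seq(0.9 * fp$scale, 1.1 * fp$scale, length.out = 20001)
  gvals <- vapply(grid, chi_at, numeric(1))
  expect_equal(fp$chi, min(gvals), tolerance = 1e-6)
  expect_equal(fp$scale, grid[which.min(gvals)], tolerance = 1e-4)

  # chi(alpha * model) == chi(model)
  m2 <- saxs_profile(q, 123.4 * m$intensity)
  expect_equal(chi_fit(m2, ep)$chi, fp$chi, tolerance = 1e-10)

  # disjoint ranges are rejected
  e_far <- saxs_profile(q + 10, m$intensity)
  expect_error(chi_fit(m, e_far), "overlap")
})

test_that("multistate selection recovers members, mixtures and nests chi", {
  sc <- mixture_scenario()
  pool5 <- sc$pool[1:5]

  # exact member in the pool, N_max = 1
  sim1 <- simulate_saxs_experiment(sc$template,
                                   list(list(fraction = 1, state = sc$ext)),
                                   sc$q, noise_fraction = 0, seed = 1)
  f1 <- select_multistate(pool5, sim1$experiment, n_max = 1)
  expect_equal(f1$best$labels, "true_ext")
  expect_equal(f1$best$weights, 1)
  expect_lt(f1$best$chi, 1e-6)

  # noiseless 0.7/0.3 mixture recovered within 1e-3
  sim2 <- simulate_saxs_experiment(
    sc$template,
    list(list(fraction = 0.7, state = sc$ext),
         list(fraction = 0.3, state = sc$cmp)),
    sc$q, noise_fraction = 0, seed = 1)
  f2 <- select_multistate(pool5, sim2$experiment, n_max = 2)
  two <- f2$per_n[[2]]
  expect_setequal(two$labels, c("true_ext", "true_cmp"))
  expect_equal(two$weights[match("true_ext", two$labels)], 0.7,
               tolerance = 1e-3)
  expect_equal(two$weights[match("true_cmp", two$labels)], 0.3,
               tolerance = 1e-3)

  # chi is non-increasing in N on a nested pool
  simn <- simulate_saxs_experiment(
    sc$template,
    list(list(fraction = 0.7, state = sc$ext),
         list(fraction = 0.3, state = sc$cmp)),
    sc$q, noise_fraction = 0.03, seed = 7)
  fn <- select_multistate(sc$pool, simn$experiment, n_max = 3)
  chis <- vapply(fn$per_n, function(x) x$chi, numeric(1))
  expect_true(all(diff(chis) <= 1e-12))
  ws <- fn$best$weights
  expect_true(all(ws >= 0))
  expect_equal(sum(ws), 1, tolerance = 1e-9)

  # guard rails
  big <- rep(pool5, 11)
  names(big) <- paste0("p", seq_along(big))
  expect_error(select_multistate(big, sim1$experiment), "exceeds")
  expect_error(select_multistate(pool5, sim1$experiment, n_max = 6), "<= 5")
  expect_error(select_multistate(unname(pool5), sim1$experiment), "named")
})
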