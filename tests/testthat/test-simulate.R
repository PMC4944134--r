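test_that("noise-free path relaxes to the low stable state", {
  # relaxation from 1.3 crawls past the unstable point before settling
  path <- simulate_path(p_ref, noise_spec(0, 0, 2), x0 = 1.3,
                        dt = 1e-3, t_max = 30)
  expect_lt(abs(path$x[nrow(path)] - x_minus), 1e-3)
  expect_equal(diff(path$t)[1], 1e-3)
  # against an independent stiff ODE integration
  ref <- deSolve::ode(y = c(x = 1.3), times = c(0, 30), parms = NULL,
                      func = function(t, y, p)
                        list(tfa_drift(y, p_ref)))
  expect_equal(path$x[nrow(path)], unname(ref[2, "x"]), tolerance = 1e-4)
})

test_that("paths are reproducible from the seed", {
  a <- simulate_path(p_ref, noise_spec(0.05, 0, 2), 1.3, dt = 1e-2,
                     t_max = 5, seed = 99)
  b <- simulate_path(p_ref, noise_spec(0.05, 0, 2), 1.3, dt = 1e-2,
                     t_max = 5, seed = 99)
  expect_identical(a$x, b$x)
})

test_that("small-alpha jump noise produces outsized single-step increments", {
  # compare to the scale of Gaussian steps of matched intensity
  gauss_step <- 0.05 * sqrt(1e-2)
  found <- FALSE
  for (seed in 1:20) {
    path <- simulate_path(p_ref, noise_spec(0, 0.05, 0.5), 1.3,
                          dt = 1e-2, t_max = 50, seed = seed)
    if (max(abs(diff(path$x))) > 10 * gauss_step) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("first-exit ensembles respect exit-state and censoring contracts", {
  # starting outside: immediate exit
  ens0 <- mc_first_exit(p_ref, noise_spec(0.5, 0, 2), D_ref, x0 = 2,
                        n_paths = 10, seed = 1)
  expect_true(all(ens0$exit_times == 0))

  ens <- mc_first_exit(p_ref, noise_spec(0.5, 0, 2), D_ref, x0 = x_minus,
                       n_paths = 500, dt = 1e-3, t_max = 30,
                       seed = seed_default)
  expect_true(all(!in_domain(ens$exit_states, D_ref)))
  expect_equal(ens$n_censored, 0L)
  # diffusive exits hug the boundary: within 6 sigma sqrt(dt) in 99%
  d_bd <- pmin(abs(ens$exit_states - 0), abs(ens$exit_states - x_u))
  expect_gte(mean(d_bd < 6 * 0.5 * sqrt(1e-3)), 0.99)
})

test_that("ensemble summaries compute mean, proportion and their errors", {
  fake <- structure(list(exit_times = c(1, 1, 1), exit_states = c(2, 2, -1),
                         censored = rep(FALSE, 3), n_censored = 0L,
                         x0 = 0.6, domain = D_ref, dt = 1e-3, seed = 1,
                         n_paths = 3L),
                    class = "exit_ensemble")
  est <- mc_mfet(fake)
  expect_equal(est$value, 1)
  expect_equal(est$std_error, 0)

  fake$exit_times <- c(0, 2)
  fake$exit_states <- c(2, -1)
  fake$censored <- c(FALSE, FALSE)
  est2 <- mc_mfet(fake)
  expect_equal(est2$value, 1)
  expect_equal(est2$std_error, 1)

  # proportion landing right of the domain
  fep <- mc_fep(fake, c(x_u, Inf))
  expect_equal(fep$value, 0.5)
  expect_equal(fep$std_error, sqrt(0.25 / 2))
  # the whole complement always captures the exit
  fep_all <- mc_fep(fake, rbind(c(-Inf, 0), c(x_u, Inf)))
  expect_equal(fep_all$value, 1)
  expect_error(mc_fep(fake, c(0.5, 1)), "overlaps")
})

test_that("Brownian Monte Carlo MFET agrees with the quadrature oracle", {
  ens <- mc_first_exit(p_ref, noise_spec(0.5, 0, 2), D_ref, x0 = x_minus,
                       n_paths = 3000, dt = 1e-3, t_max = 40,
                       seed = seed_default)
  est <- mc_mfet(ens)
  oracle <- brownian_mfet_closed_form(p_ref, 0.5, D_ref, x_minus)
  expect_lt(abs(est$value - oracle), 3 * est$std_error)
  # Brownian paths cannot reach a non-adjacent target
  expect_equal(mc_fep(ens, c(3, 5))$value, 0)
})

test_that("stronger jump noise shortens the Monte Carlo exit time", {
  est_lo <- mc_mfet(mc_first_exit(p_ref, noise_spec(0, 0.25, 1.5), D_ref,
                                  x_minus, n_paths = 2000, dt = 1e-3,
                                  t_max = 60, seed = seed_default))
  est_hi <- mc_mfet(mc_first_exit(p_ref, noise_spec(0, 1, 1.5), D_ref,
                                  x_minus, n_paths = 2000, dt = 1e-3,
                                  t_max = 60, seed = seed_default))
  se <- sqrt(est_lo$std_error^2 + est_hi$std_error^2)
  expect_gt(est_lo$value - est_hi$value, 3 * se)
})
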