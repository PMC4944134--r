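test_that("jump-measure constant matches the Cauchy special case", {
  expect_equal(stable_c_alpha(1), 1 / pi, tolerance = 1e-12)
  expect_error(stable_c_alpha(2), "alpha")
})

test_that("generator annihilates constants across the parameter lattice", {
  ext1 <- exterior_condition("constant", value = 1)
  for (alpha in c(0.5, 1, 1.5)) {
    for (eps in c(0.25, 0.5, 1)) {
      for (sig in c(0, 0.5)) {
        gen <- assemble_generator(D_ref, p_ref,
                                  noise_spec(sig, eps, alpha), ext1, J = 64)
        res <- apply_generator(gen, rep(1, nrow(gen$matrix)))
        expect_lt(max(abs(res)), 1e-8)
      }
    }
  }
})

test_that("pure-diffusion assembly is tridiagonal", {
  gen <- assemble_generator(D_ref, p_ref, noise_spec(0.5, 0, 2),
                            exterior_condition("zero"), J = 32)
  M <- gen$matrix
  off <- abs(row(M) - col(M)) > 1
  expect_true(all(M[off] == 0))
})

test_that("drift-free closed forms reduce to textbook formulas", {
  D01 <- domain1d(0, 1)
  # u(x) = x(1-x) for f = 0, sigma = 1
  expect_equal(brownian_mfet_closed_form(p_null, 1, D01, 0.5), 0.25,
               tolerance = 1e-8)
  expect_equal(brownian_mfet_closed_form(p_null, 1, D01, 0.25), 0.1875,
               tolerance = 1e-7)
  # p(x) = x: midpoint 1/2, boundary limits 0 and 1
  expect_equal(brownian_fep_closed_form(p_null, 1, D01, 0.5), 0.5,
               tolerance = 1e-9)
  expect_equal(brownian_fep_closed_form(p_null, 1, D01, c(0, 1)), c(0, 1),
               tolerance = 1e-9)
})

test_that("Brownian solver matches the quadrature oracle", {
  ns <- noise_spec(0.5, 0, 2)
  u <- solve_mfet(D_ref, p_ref, ns, J = 400)
  u_cf <- brownian_mfet_closed_form(p_ref, 0.5, D_ref, x_minus)
  expect_lt(abs(field_eval(u, x_minus) - u_cf) / u_cf, 0.005)
  expect_true(all(u$values >= 0))
  # exterior condition: u vanishes approaching the boundary
  expect_lt(field_eval(u, x_u - 1e-4), 0.05)

  p <- solve_fep(D_ref, c(x_u, Inf), p_ref, ns, J = 400)
  p_cf <- brownian_fep_closed_form(p_ref, 0.5, D_ref, 1.2)
  expect_lt(abs(field_eval(p, 1.2) - p_cf), 1e-3)
})

test_that("solver reproduces the exact drift-free stable exit time", {
  # standard symmetric alpha-stable motion on (-1, 1):
  # u(x) = (1 - x^2)^(alpha/2) / Gamma(1 + alpha)
  Dsym <- domain1d(-1, 1)
  for (alpha in c(0.5, 1.5)) {
    u <- solve_mfet(Dsym, p_null, noise_spec(0, 1, alpha), J = 400)
    exact <- (1 - 0.3^2)^(alpha / 2) / gamma(1 + alpha)
    expect_lt(abs(field_eval(u, 0.3) - exact) / exact, 0.02)
  }
})

test_that("escape probabilities are bounded and certain for full targets", {
  for (ns in list(noise_spec(0.5, 0.5, 1.5), noise_spec(0, 0.5, 0.5))) {
    pfull <- solve_fep(D_ref, rbind(c(-Inf, 0), c(x_u, Inf)), p_ref, ns,
                       J = 200)
    expect_lt(max(abs(pfull$values - 1)), 1e-6)
    expect_gte(min(pfull$raw_range), -1e-8)
    expect_lte(max(pfull$raw_range), 1 + 1e-8)
  }
})

test_that("complementary targets partition the escape probability", {
  xs <- seq(0.1, 1.4, by = 0.1)
  for (ns in list(noise_spec(0.5, 0, 2), noise_spec(0.5, 0.5, 1.5))) {
    p_right <- solve_fep(D_ref, c(x_u, Inf), p_ref, ns, J = 200)
    p_left <- solve_fep(D_ref, c(-Inf, 0), p_ref, ns, J = 200)
    expect_lt(max(abs(field_eval(p_right, xs) + field_eval(p_left, xs) - 1)),
              1e-6)
  }
})

test_that("non-adjacent targets are unreachable by pure diffusion", {
  p2 <- solve_fep(D_ref, c(3, 5), p_ref, noise_spec(0.5, 0, 2), J = 400)
  expect_lt(max(abs(p2$values)), 1e-8)
})

test_that("Levy solver agrees with Monte Carlo at matched settings", {
  ns <- noise_spec(0, 0.5, 0.5)
  u <- solve_mfet(D_ref, p_ref, ns, J = 400)
  ens <- mc_first_exit(p_ref, ns, D_ref, x_minus, n_paths = 4000,
                       dt = 1e-3, t_max = 30, seed = seed_default)
  est <- mc_mfet(ens)
  expect_lt(abs(field_eval(u, x_minus) - est$value), 3 * est$std_error)

  pfep <- solve_fep(D_ref, c(x_u, Inf), p_ref, noise_spec(0, 0.5, 1.5),
                    J = 400)
  ens15 <- mc_first_exit(p_ref, noise_spec(0, 0.5, 1.5), D_ref, x_minus,
                         n_paths = 4000, dt = 1e-3, t_max = 30,
                         seed = seed_default)
  estf <- mc_fep(ens15, c(x_u, Inf))
  expect_lt(abs(field_eval(pfep, x_minus) - estf$value), 3 * estf$std_error)
})

test_that("grid refinement converges at the expected rate", {
  # Brownian: second-order scheme against the closed form, measured at a
  # point shared by all nested grids so interpolation does not pollute it
  x_node <- 0.4 * x_u
  u_cf <- brownian_mfet_closed_form(p_ref, 0.5, D_ref, x_node)
  errs <- vapply(c(100, 200, 400), function(J) {
    abs(field_eval(solve_mfet(D_ref, p_ref, noise_spec(0.5, 0, 2), J = J),
                   x_node) - u_cf)
  }, numeric(1))
  order_emp <- log2(errs[1] / errs[2])
  expect_gte(order_emp, 1.8)

  # jump case: successive differences contract
  ns <- noise_spec(0, 0.5, 1.5)
  us <- vapply(c(100, 200, 400), function(J) {
    field_eval(solve_mfet(D_ref, p_ref, ns, J = J), x_minus)
  }, numeric(1))
  r <- abs(us[3] - us[2]) / abs(us[2] - us[1])
  expect_lt(r, 1)

  # tol = Inf returns the first solve untouched
  s0 <- refine_until(D_ref, p_ref, ns, tol = Inf, J_init = 100)
  expect_identical(s0$J, 100L)
  s1 <- refine_until(D_ref, p_ref, noise_spec(0.5, 0, 2), tol = 1e-3,
                     J_init = 100)
  conv <- attr(s1, "convergence")
  expect_lt(conv$change[nrow(conv)], 1e-3)
})
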