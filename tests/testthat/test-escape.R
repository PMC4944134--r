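test_that("a single-setting sweep equals a direct solve", {
  ns <- noise_spec(0.5, 0.5, 1.5)
  sw <- sweep_mfet(c(0.3, x_minus), alpha = 1.5, settings = list(ns),
                   domain = D_ref, params = p_ref, J = 100)
  u <- solve_mfet(D_ref, p_ref, ns, J = 100)
  expect_equal(sw$value, field_eval(u, c(0.3, x_minus)))
  expect_true(all(sw$value > 0))
  expect_identical(unique(sw$quantity), "mfet")
})

test_that("MFET sweep covers the reference initial concentrations", {
  sw <- sweep_mfet(c(0.3, x_minus, 0.9, 1.2), alpha = 0.5,
                   settings = c(0.5, 2), domain = D_ref, params = p_ref,
                   J = 100)
  expect_equal(nrow(sw), 8L)
  expect_true(all(is.finite(sw$value) & sw$value > 0))
  # constrained settings satisfy sigma + epsilon = 1
  expect_true(all(abs(sw$sigma + sw$epsilon - 1) < 1e-12))
})

test_that("MFET decreases pointwise in the jump intensity", {
  for (alpha in c(0.5, 1.5)) {
    sw <- sweep_mfet(c(0.3, x_minus, 0.9, 1.2), alpha = alpha,
                     settings = list(c(0, 0.25), c(0, 1)),
                     domain = D_ref, params = p_ref, J = 200)
    lo <- sw$value[sw$epsilon == 0.25]
    hi <- sw$value[sw$epsilon == 1]
    expect_true(all(hi < lo))
  }
})

test_that("FEP sweeps respect scenario geometry and noise ordering", {
  # scenario 2 with a pure-Gaussian setting: probability is identically 0
  sw0 <- sweep_fep(c(0.3, x_minus, 1.2), alpha = 0.5, settings = c(0),
                   domain = D_ref, target = c(3, 5), scenario = 2,
                   params = p_ref, J = 200)
  expect_true(all(abs(sw0$value) < 1e-8))

  # larger jumps (smaller alpha) reach the distant target more readily
  v05 <- sweep_fep(0.745, alpha = 0.5, settings = list(c(0.5, 0.5)),
                   domain = D_ref, target = c(3, 5), scenario = 2,
                   params = p_ref, J = 200)$value
  v15 <- sweep_fep(0.745, alpha = 1.5, settings = list(c(0.5, 0.5)),
                   domain = D_ref, target = c(3, 5), scenario = 2,
                   params = p_ref, J = 200)$value
  expect_gt(v05, v15)

  # scenario 1 with the full complement as target: certainty
  sw1 <- sweep_fep(c(0.3, 1.2), alpha = 1.5, settings = list(c(0.5, 0.5)),
                   domain = D_ref, target = rbind(c(-Inf, 0), c(x_u, Inf)),
                   scenario = 1, params = p_ref, J = 100)
  expect_equal(sw1$value, c(1, 1), tolerance = 1e-6)

  expect_error(sweep_fep(0.5, 1.5, list(c(0.5, 0.5)), D_ref,
                         target = c(x_u, 3), scenario = 2, params = p_ref),
               "non-adjacent")
})

test_that("K extraction thresholds the residence-time profile", {
  ns <- noise_spec(0.5, 0, 2)
  u <- solve_mfet(D_ref, p_ref, ns, J = 400)
  umax <- max(u$values)
  # degenerate threshold: K collapses onto the maximiser
  k_top <- extract_k(u, umax)
  expect_lt(k_top[2] - k_top[1], 1e-8)
  # tiny threshold: K fills the domain
  k_all <- extract_k(u, 1e-9 * umax)
  expect_equal(unname(k_all), c(0, x_u), tolerance = 1e-3)
  expect_error(extract_k(u, 2 * umax), "empty K")

  # endpoints agree with the closed-form oracle's superlevel set
  u1 <- solve_mfet(D_ref, p_ref, noise_spec(1, 0, 2), J = 400)
  thr <- 0.5 * max(u1$values)
  k <- extract_k(u1, thr)
  ucf <- function(x) brownian_mfet_closed_form(p_ref, 1, D_ref, x)
  ucf_max <- stats::optimize(ucf, c(0.2, 1.2), maximum = TRUE)
  lo <- stats::uniroot(function(x) ucf(x) - thr,
                       c(1e-3, ucf_max$maximum))$root
  hi <- stats::uniroot(function(x) ucf(x) - thr,
                       c(ucf_max$maximum, x_u - 1e-3))$root
  expect_equal(unname(k), c(lo, hi), tolerance = 1e-3)
})

test_that("stochastic basin composes K and the return set M", {
  ns <- noise_spec(0.5, 0, 2)
  u <- solve_mfet(D_ref, p_ref, ns, J = 400)
  u_star <- 0.6 * max(u$values)
  sba <- stochastic_basin(p_ref, ns, window = c(0, 6), u_star = u_star,
                          p_star = 0.6, J = 400)
  # geometry: M stays inside the window and clear of K
  expect_true(all(sba$M[, 1] >= sba$K[2] | sba$M[, 2] <= sba$K[1]))
  expect_true(all(sba$M >= 0 & sba$M <= 6))
  expect_equal(sba$sba_size, sba$k_size + sba$m_size)
  # Brownian return probability decays monotonically away from K:
  # at most one component per side
  expect_lte(nrow(sba$M), 2)

  # raising p_star shrinks M (nested superlevel sets); raising u_star
  # shrinks K
  sizes_p <- vapply(c(0.5, 0.7, 0.9), function(ps) {
    stochastic_basin(p_ref, ns, c(0, 6), u_star, ps, J = 400)$m_size
  }, numeric(1))
  expect_true(all(diff(sizes_p) <= 0))
  sizes_k <- vapply(c(0.4, 0.6, 0.8) * max(u$values), function(us) {
    stochastic_basin(p_ref, ns, c(0, 6), us, 0.6, J = 400)$k_size
  }, numeric(1))
  expect_true(all(diff(sizes_k) <= 0))
})

test_that("matched-size cores give a wider return set for milder jumps", {
  # fix |K| across alpha by choosing u* per noise setting, then compare |M|
  klen <- 0.9869 - 0.4387
  m_sizes <- vapply(c(0.5, 1.5), function(alpha) {
    ns <- noise_spec(0, 0.5, alpha)
    u <- solve_mfet(D_ref, p_ref, ns, J = 400)
    us <- stats::uniroot(function(s) {
      k <- extract_k(u, s); (k[2] - k[1]) - klen
    }, c(0.05, 0.9999) * max(u$values))$root
    stochastic_basin(p_ref, ns, c(0, 6), us, 0.6, J = 400)$m_size
  }, numeric(1))
  expect_gt(m_sizes[2], m_sizes[1])
})
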