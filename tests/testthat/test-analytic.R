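test_that("fast-transport intracellular concentration has the partition limits", {
  p <- comp_params()
  expect_equal(cin_fast(0, p, 44), 0)
  lim <- 44 * p$P / (1 + p$P)
  expect_equal(cin_fast(1e9, p, 44), lim, tolerance = 1e-12)
  tt <- 10^seq(1, 7, length.out = 50)
  vals <- cin_fast(tt, p, 44)
  expect_true(all(diff(vals) >= 0))           # saturates at the plateau
  expect_true(all(diff(vals[tt < 1e5]) > 0))  # strictly rising beforehand
  expect_true(all(vals >= 0 & vals < lim + 1e-12))
  # half-saturation after one half-life of the relaxation rate (1+P)k1-
  t_half <- log(2) / ((1 + p$P) * p$k1_minus)
  expect_equal(cin_fast(t_half, p, 44), lim / 2, tolerance = 1e-12)
  expect_error(cin_fast(-1, p, 44), "non-negative")
})

test_that("production kernel saturates and matches its limits", {
  p <- comp_params()
  expect_equal(g_kernel(0, p, 44), 0)
  kmax <- p$k3 * p$r_tot
  inf_lim <- kmax * 44 / (44 + p$K_D * (1 + p$P) / p$P)
  expect_equal(g_kernel(1e10, p, 44), inf_lim, tolerance = 1e-10)
  # saturating dose recovers the maximal production rate
  expect_equal(g_kernel(1e5, p, 1e12), kmax, tolerance = 1e-6)
  expect_lt(max(g_kernel(10^seq(0, 9, 0.5), p, 44)), kmax)
  gk <- g_kernel(10^seq(0, 9, 0.5), p, 44)
  expect_true(all(diff(gk) >= -1e-12 * max(gk)))  # flat at the plateau
  expect_true(all(diff(g_kernel(10^seq(0, 4.5, 0.5), p, 44)) > 0))
})

test_that("kernel equals production off the binding isotherm at the fast-transport concentration", {
  # the quasi-steady-state logic made explicit
  for (prm in list(comp_params(), math_params())) {
    for (ctot in c(0.44, 4.4, 44, 1000)) {
      s <- 10^seq(0, 8, length.out = 60)
      expect_equal(g_kernel(s, prm, ctot),
                   prm$k3 * binding_isotherm(cin_fast(s, prm, ctot),
                                             prm$K_D, prm$r_tot),
                   tolerance = 1e-12)
    }
  }
})

test_that("integral solution has the right endpoints and basal limit", {
  p <- math_params(p0 = 20)
  expect_equal(p_integral(0, p, 44), 20)
  tt <- c(0, 1e4, 1e5, 1e6)
  expect_equal(p_integral(tt, p, 0), basal_curve(tt, p$k4, p$k5, 20))
})

test_that("integral solution tracks the ODE model closely", {
  p <- comp_params()
  tt <- 10^seq(2, 7, length.out = 30)
  # the quasi-steady-state step neglects ligand depletion by binding, so
  # its cost shrinks as the dose grows past r_tot
  for (case in list(c(1, 0.15), c(44, 0.05))) {
    po <- dsred_response(p, case[1], tt, predictor = "ode")
    pi_ <- p_integral(tt, p, case[1])
    expect_lt(max(abs(pi_ - po) / po), case[2])
  }
})

test_that("Taylor approximation reduces to basal and steady-state limits", {
  for (p in list(comp_params(p0 = 20), math_params(p0 = 20))) {
    tt <- c(0, 1e3, 1e5, 1e6)
    expect_equal(p_approx(tt, p, 0), basal_curve(tt, p$k4, p$k5, 20))
    for (ctot in c(0.1, 1, 45, 1000))
      expect_equal(p_approx(1e12, p, ctot), p_steady(p, ctot),
                   tolerance = 1e-9)
  }
})

test_that("approximation agrees with the integral solution at long times and uM doses", {
  p <- comp_params()
  tt <- 10^seq(4, 7, length.out = 25)
  for (ctot in c(1, 10, 100)) {
    pi_ <- p_integral(tt, p, ctot)
    pa <- p_approx(tt, p, ctot)
    expect_lt(max(abs(pa - pi_) / pi_), 0.01)
  }
})

test_that("steady state is a sigmoid in dose with the closed-form half point", {
  p <- math_params()
  expect_equal(p_steady(p, 0), p$k5 / p$k4)
  expect_equal(p$k5 / p$k4, 176.9, tolerance = 2e-4)
  hi <- p$k5 / p$k4 + p$k3 * p$r_tot / p$k4
  expect_equal(p_steady(p, 1e12), hi, tolerance = 1e-9)
  half_c <- p$K_D * (1 + p$P) / p$P
  expect_equal(half_c, 0.365, tolerance = 1e-3)
  expect_equal(p_steady(p, half_c), (p$k5 / p$k4 + hi) / 2)
  doses <- 10^seq(-3, 3, length.out = 40)
  resp <- vapply(doses, function(cc) p_steady(p, cc), numeric(1))
  expect_true(all(diff(resp) > 0))
  expect_true(all(diff(diff(resp) / diff(doses)) < 0))  # concave in dose
})

test_that("binding isotherm hits its textbook anchor points", {
  expect_equal(binding_isotherm(0, 0.3, 2), 0)
  expect_equal(binding_isotherm(0.3, 0.3, 2), 1)
  expect_equal(binding_isotherm(9 * 0.3, 0.3, 2), 1.8)
  expect_error(binding_isotherm(-1, 0.3, 2), "non-negative")
  expect_error(binding_isotherm(1, 0, 2), "positive")
})

test_that("the predictor front end exposes all three routes consistently", {
  p <- comp_params()
  tt <- seq(0, 86400, 7200)
  a <- dsred_response(p, 44, tt, "approx")
  i <- dsred_response(p, 44, tt, "integral")
  o <- dsred_response(p, 44, tt, "ode")
  expect_equal(a, p_approx(tt, p, 44))
  expect_equal(i, p_integral(tt, p, 44))
  expect_equal(length(o), length(tt))
  expect_error(dsred_response(p, 44, tt, "bogus"))
  # grids not anchored at zero are handled by the ODE route too
  o2 <- dsred_response(p, 44, tt[-1], "ode")
  expect_equal(o2, o[-1], tolerance = 1e-8)
})
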