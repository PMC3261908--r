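op0 <- default_oscillator_params()

test_that("nullcline points zero their component of the vector field", {
  nc <- suppressWarnings(nullclines(op0, I_range = c(1, 2000),
                                    R_range = c(1, 2000), n_grid = 25))
  for (i in seq_len(nrow(nc$luxR_nullcline))) {
    st <- c(nc$luxR_nullcline$R[i], nc$luxR_nullcline$I[i])
    f <- promoterlogic:::oscillator_field(st, op0)
    expect_lt(abs(f[1]) / (op0$gamma_R * op0$lambda_R), 1e-7)
  }
  for (i in seq_len(nrow(nc$luxI_nullcline))) {
    st <- c(nc$luxI_nullcline$R[i], nc$luxI_nullcline$I[i])
    f <- promoterlogic:::oscillator_field(st, op0)
    expect_lt(abs(f[2]) / (op0$gamma_I * op0$beta_I), 1e-7)
  }
})

test_that("disabling repression decouples LuxI at its ceiling", {
  op <- default_oscillator_params()
  op$K_L <- 1e12   # repression disabled
  nc <- suppressWarnings(nullclines(op, I_range = c(op$beta_I / 2, op$beta_I * 2),
                                    R_range = c(1, 2000), n_grid = 11))
  expect_equal(unique(round(nc$luxI_nullcline$I, 6)), op$beta_I)
  fps <- fixed_point(op)
  fp <- fps[[length(fps)]]
  expect_equal(fp$I, op$beta_I, tolerance = 1e-6)
  # R* solves the scalar LuxR-feedback equation with LuxI clamped at beta_I
  topo <- topology_spec("luxR_feedback", lambda_R = op$lambda_R,
                        luxI_fixed = op$beta_I)
  ss <- steady_states_at_density(topo, op$plf, op$density)
  expect_lt(min(abs(log(fp$R / ss$level))), 1e-5)
  # without negative feedback the system settles from any start
  set.seed(8)
  for (k in 1:5) {
    init <- c(R = 10^runif(1, 0, 3.3), I = 10^runif(1, 0, 3))
    tr <- simulate_oscillator(op, init = init, duration = 300, dt = 0.1)
    expect_false(attr(tr, "oscillating"))
    tail_R <- tr$R[tr$time > 250]
    expect_lt(diff(range(tail_R)) / mean(tail_R), 1e-3)
  }
})

test_that("the nullcline intersection is the fixed point", {
  fps <- fixed_point(op0)
  expect_length(fps, 1)
  fp <- fps[[1]]
  # both field components vanish there
  f <- promoterlogic:::oscillator_field(c(fp$R, fp$I), op0)
  expect_lt(max(abs(f)) / op0$lambda_R, 1e-8)
})

test_that("stable and unstable regimes behave as their eigenvalues say", {
  # below the Hopf boundary (~0.113): unstable focus, sustained cycle
  op_u <- default_oscillator_params(gamma_I = 0.05)
  expect_gt(fixed_point(op_u)[[1]]$max_re, 0)
  tr_u <- simulate_oscillator(op_u, duration = 2000, dt = 0.2)
  expect_true(attr(tr_u, "oscillating"))
  expect_gt(attr(tr_u, "amplitude_R"), 10)
  # phase-plane orbit runs counterclockwise in the (LuxI, LuxR) plane
  tail_tr <- tr_u[tr_u$time > 1000, ]
  fp <- fixed_point(op_u)[[1]]
  ang <- atan2(log(tail_tr$R / fp$R), log(tail_tr$I / fp$I))
  d_ang <- diff(ang)
  d_ang <- d_ang[abs(d_ang) < pi]  # drop wrap-arounds
  expect_gt(mean(d_ang > 0), 0.5)
  # above the boundary: stable, oscillation dies out
  op_s <- default_oscillator_params(gamma_I = 0.3)
  expect_lt(fixed_point(op_s)[[1]]$max_re, 0)
  tr_s <- simulate_oscillator(op_s, duration = 2000, dt = 0.2)
  expect_false(attr(tr_s, "oscillating"))
  tail_R <- tr_s$R[tr_s$time > 1500]
  expect_lt(diff(range(tail_R)) / mean(tail_R), 1e-2)
  # state variables stay nonnegative throughout
  expect_true(all(tr_u$R >= 0 & tr_u$I >= 0))
})

test_that("saturating external AHL abolishes oscillations", {
  # mimic excess synthetic AHL: drive AHL-LuxR binding to saturation
  op <- default_oscillator_params(gamma_I = 0.05)
  op$plf$ahl_luxr_halfsat <- 1e-9
  tr <- simulate_oscillator(op, duration = 600, dt = 0.2)
  expect_false(attr(tr, "oscillating"))
  tail_R <- tr$R[tr$time > 500]
  expect_lt(diff(range(tail_R)) / mean(tail_R), 1e-3)
})

test_that("the Hopf boundary is sharp, consistent and step-robust", {
  hs <- hopf_scan(op0, c(0.02, 0.5))
  expect_lt(abs(hs$max_re_at_boundary), 1e-4)
  expect_lt(diff(hs$bracket) / hs$gamma_I_hopf, 2e-4)
  # eigenvalue verdict flips across the boundary
  op_lo <- default_oscillator_params(gamma_I = hs$gamma_I_hopf * 0.9)
  op_hi <- default_oscillator_params(gamma_I = hs$gamma_I_hopf * 1.1)
  expect_gt(fixed_point(op_lo)[[1]]$max_re, 0)
  expect_lt(fixed_point(op_hi)[[1]]$max_re, 0)
  # simulation agrees just off the boundary
  tr_lo <- simulate_oscillator(op_lo, duration = 3000, dt = 0.2)
  expect_true(attr(tr_lo, "oscillating"))
  tr_hi <- simulate_oscillator(op_hi, duration = 3000, dt = 0.2)
  expect_false(attr(tr_hi, "oscillating"))
  # boundary location is robust to the Jacobian finite-difference step
  res <- vapply(c(1e-4, 1e-5, 1e-6), function(h) {
    op <- op0
    f <- function(g) {
      op$gamma_I <- g
      fp <- fixed_point(op)[[1]]
      J <- promoterlogic:::oscillator_jacobian(c(fp$R, fp$I), op, h_rel = h)
      max(Re(eigen(J, only.values = TRUE)$values))
    }
    stats::uniroot(f, c(0.05, 0.3), tol = 1e-8)$root
  }, 0)
  expect_lt(diff(range(res)) / mean(res), 1e-3)
  expect_error(hopf_scan(op0, c(0.2, 0.5)), "does not change sign")
})
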