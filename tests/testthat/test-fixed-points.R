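p_true <- default_plf_params()
grid0 <- generate_plf_grid(p_true, noise = noise_model(0, 1))

test_that("IOC slices reproduce the generating model at cv = 0", {
  # vertical cut: 7-point IOC in LuxR at fixed aTc
  io_r <- ioc_from_grid(grid0, "luxR", 4)
  expect_length(io_r$input, 7)
  expect_true(all(diff(io_r$output) >= 0))
  q <- default_induction_params()
  luxI <- hill_induction(default_inducer_levels()$aTc_ng_ml[4], q$aTc)
  expect_equal(io_r$output, 1000 * plf_eval(rep(luxI, 7), io_r$input, p_true),
               tolerance = 1e-9)
  # horizontal cut: 6-point IOC in LuxI at fixed IPTG
  io_i <- ioc_from_grid(grid0, "luxI", 5)
  expect_length(io_i$input, 6)
  expect_error(ioc_from_grid(grid0, "luxR", 99), "out of range")
})

test_that("log-log interpolation is exact at nodes and flat outside", {
  obj <- ioc(c(1, 100), c(1, 100), axis = "luxI")
  expect_equal(loglog_interp(obj, 10), 10)       # power-law midpoint
  expect_equal(loglog_interp(obj, c(1, 100)), c(1, 100))
  expect_equal(loglog_interp(obj, 0.01), 1)      # flat extrapolation below
  expect_equal(loglog_interp(obj, 1e5), 100)     # flat extrapolation above
  expect_error(loglog_interp(obj, -1), "x must be")
})

test_that("intersection enumeration handles flat, sigmoidal and tangent IOCs", {
  line <- equivalence_line(scale = 2)
  # constant IOC: single stable point at z0 / s
  flat <- ioc(c(10, 1000), c(300, 300), axis = "luxI")
  fp <- find_intersections(flat, line)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$level, 150)
  expect_equal(fp$stability, "stable")
  # sigmoidal IOC in the hysteretic regime: 3 points, middle unstable
  sig <- ioc(c(1, 10, 40, 200, 1000), c(30, 31, 35, 900, 950), axis = "luxI")
  fp3 <- find_intersections(sig, line)
  expect_equal(nrow(fp3), 3)
  expect_equal(fp3$stability, c("stable", "unstable", "stable"))
  # a segment lying exactly on the line is a single unknown-stability hit
  tang <- ioc(c(1, 10, 100), c(2, 20, 2000), axis = "luxI")
  fpt <- find_intersections(tang, line)
  expect_equal(sum(fpt$stability == "unknown"), 1)
})

test_that("intersections match the dense-scan oracle on random instances", {
  set.seed(101)
  n_checked <- 0
  for (k in 1:200) {
    obj <- random_monotone_ioc()
    line <- equivalence_line(scale = 10^runif(1, -1.5, 1.5))
    fp <- find_intersections(obj, line)
    levels_oracle <- oracle_intersections(obj, line)
    expect_equal(nrow(fp), length(levels_oracle),
                 info = sprintf("instance %d crossing count", k))
    if (nrow(fp) && length(levels_oracle) == nrow(fp)) {
      expect_equal(fp$level, levels_oracle, tolerance = 1e-6,
                   info = sprintf("instance %d locations", k))
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("stable labels alternate and match ODE basins", {
  line <- equivalence_line(scale = 1000 / 1500)
  io <- ioc_from_grid(grid0, "luxI", 4)
  fp <- find_intersections(io, line)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
  # every trajectory started between two adjacent stable points converges
  # to one of them under the generating ODE
  topo <- topology_spec("luxI_feedback", lambda_I = 1500,
                        luxR_fixed = io$regulator)
  p_g <- p_true
  stable <- fp$level[fp$stability == "stable"]
  set.seed(5)
  for (x0 in exp(runif(20, log(min(stable)), log(max(stable))))) {
    sol <- deSolve::ode(y = c(x = x0), times = c(0, 500), func = ode_rhs,
                        parms = list(topo = topo, p = p_g))
    xT <- sol[nrow(sol), "x"]
    expect_lt(min(abs(log(xT / stable))), 0.05)
  }
})

test_that("predictions from a cv = 0 grid match the true feedback states", {
  line <- equivalence_line(scale = 1000 / 1500)
  for (k in c(4, 5)) {
    io <- ioc_from_grid(grid0, "luxI", k)
    fp <- find_intersections(io, line)
    topo <- topology_spec("luxI_feedback", lambda_I = 1500,
                          luxR_fixed = io$regulator)
    truth <- steady_states_at_density(topo, p_true, p_true$density)
    pred <- fp$level[fp$stability == "stable"]
    ref <- truth$level[truth$stability == "stable"]
    expect_equal(length(pred), length(ref))
    expect_equal(pred, ref, tolerance = 0.05)
  }
})

test_that("the input-axis squeeze predicts states at a rescaled density", {
  # a LuxI-axis IOC from a grid at density rho, stretched by k, is the IOC
  # at density rho / k; its intersections must match the feedback steady
  # states computed directly at the lower density
  line <- equivalence_line(scale = 1000 / 3000)
  k_fac <- 2
  io <- ioc_from_grid(grid0, "luxI", 4, input_scale = k_fac)
  fp <- find_intersections(io, line)
  topo <- topology_spec("luxI_feedback", lambda_I = 3000,
                        luxR_fixed = io$regulator)
  truth <- steady_states_at_density(topo, p_true, p_true$density / k_fac)
  pred <- fp$level[fp$stability == "stable"]
  ref <- truth$level[truth$stability == "stable"]
  expect_equal(length(pred), length(ref))
  expect_equal(pred, ref, tolerance = 0.06)
})

test_that("Monte-Carlo ensembles collapse as noise vanishes", {
  line <- equivalence_line(scale = 1000 / 1500)
  mc0 <- mc_predict(grid0, line, "luxI", 4, noise_sd = 0, trials = 10, seed = 2)
  # all trials identical to the deterministic prediction
  for (t in 1:10)
    expect_equal(mc0$levels$level[mc0$levels$trial == t],
                 mc0$deterministic$level)
  sds <- vapply(c(0.2, 0.05, 0.01, 0.002), function(s) {
    mc <- mc_predict(grid0, line, "luxI", 4, noise_sd = s, trials = 50,
                     seed = 2)
    hi <- tapply(mc$levels$level, mc$levels$trial, max)
    stats::sd(log(hi))
  }, 0)
  expect_true(all(diff(sds) < 0))
  expect_lt(sds[4], 1e-2)
})

test_that("multistable fractions behave at and away from bifurcations", {
  line <- equivalence_line(scale = 1000 / 1500)
  # deep in the monostable regime: no trial is multistable
  mc_m <- mc_predict(grid0, line, "luxR", 1, noise_sd = 0.05, trials = 100,
                     seed = 3)
  expect_equal(mc_m$multistable_fraction, 0)
  # near the fold: some but not all trials multistable, seed-reproducible
  mc_b <- mc_predict(grid0, line, "luxI", 6, noise_sd = 0.25, trials = 200,
                     seed = 4)
  expect_gt(mc_b$multistable_fraction, 0)
  expect_lt(mc_b$multistable_fraction, 1)
  mc_b2 <- mc_predict(grid0, line, "luxI", 6, noise_sd = 0.25, trials = 200,
                      seed = 4)
  expect_equal(mc_b$multistable_fraction, mc_b2$multistable_fraction)
})

test_that("regulator interpolation is branch-wise and power-law", {
  pred <- data.frame(regulator = c(1, 100), level = c(10, 1000))
  expect_equal(interp_across_regulator(pred, 10), 100)
  expect_equal(interp_across_regulator(pred, 1), 10)
  # branch count change: partial result with a warning
  pred2 <- rbind(pred, data.frame(regulator = 100, level = 5))
  expect_warning(out <- interp_across_regulator(pred2, 10),
                 "branch count changes")
  expect_length(out, 1)
  # branch-wise interpolation tracks the model across a bistable family
  topo <- topology_spec("luxI_feedback", lambda_I = 1500, luxR_fixed = 1)
  regs <- c(500, 700, 1000, 1400, 2000)
  rows <- do.call(rbind, lapply(regs, function(r) {
    topo$luxR_fixed <- r
    ss <- steady_states_at_density(topo, p_true, 0.05)
    data.frame(regulator = r, level = ss$level, stability = ss$stability)
  }))
  target <- 850
  got <- interp_across_regulator(rows, target)
  topo$luxR_fixed <- target
  ref <- steady_states_at_density(topo, p_true, 0.05)
  ref <- ref$level[ref$stability == "stable"]
  expect_equal(length(got), length(ref))
  expect_equal(got, ref, tolerance = 0.25)
})

test_that("model-based IOCs agree with grid slices and saturate", {
  topo <- topology_spec("luxI_feedback", lambda_I = 1500, luxR_fixed = 600)
  io <- model_based_ioc(p_true, topo, input_range = c(1, 1e4),
                        output_scale = 1000)
  expect_equal(utils::tail(io$output, 1), 1000 * plf_eval(1e4, 600, p_true),
               tolerance = 1e-9)
  # with both inputs saturating, the IOC tops out at the unit rate
  t_sat <- topology_spec("luxI_feedback", lambda_I = 1500, luxR_fixed = 2e4)
  io_sat <- model_based_ioc(p_true, t_sat, input_range = c(1, 1e5),
                            output_scale = 1000)
  expect_lt(abs(utils::tail(io_sat$output, 1) / 1000 - 1), 0.05)
  # agrees with the measured slice at the grid nodes
  slice <- ioc_from_grid(grid0, "luxI", 5)
  topo$luxR_fixed <- slice$regulator
  io2 <- model_based_ioc(p_true, topo, range(slice$input),
                         output_scale = 1000)
  expect_equal(loglog_interp(io2, slice$input), slice$output,
               tolerance = 0.02)
  # lowest vs highest regulator IOCs differ >= 10x at mid input
  t_lo <- topo; t_lo$luxR_fixed <- 12
  t_hi <- topo; t_hi$luxR_fixed <- 1780
  mid <- 300
  y_lo <- loglog_interp(model_based_ioc(p_true, t_lo, c(1, 1e4),
                                        output_scale = 1000), mid)
  y_hi <- loglog_interp(model_based_ioc(p_true, t_hi, c(1, 1e4),
                                        output_scale = 1000), mid)
  expect_gt(y_hi / y_lo, 10)
})
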