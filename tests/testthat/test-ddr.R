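p_true <- default_plf_params()
topos <- default_topologies()

test_that("steady states at limiting densities are basal and saturated", {
  ti <- topos$luxI_feedback
  ss0 <- steady_states_at_density(ti, p_true, 0)
  expect_equal(nrow(ss0), 1)
  expect_equal(ss0$stability, "stable")
  expect_equal(ss0$level, ti$lambda_I * p_true$basal_fraction,
               tolerance = 1e-6)
  ss_hi <- steady_states_at_density(ti, p_true, 50)
  expect_equal(nrow(ss_hi), 1)
  # at saturating AHL the root is lambda * f with the full regulator bound
  p_sat <- p_true
  p_sat$density <- 50
  expect_equal(ss_hi$level,
               ti$lambda_I * plf_eval(ss_hi$level, ti$luxR_fixed, p_sat),
               tolerance = 1e-6)
  expect_gt(ss_hi$level, 0.8 * ti$lambda_I)
})

test_that("root sets match the dense-scan oracle on random instances", {
  set.seed(202)
  counts <- integer(0)
  for (k in 1:200) {
    p <- random_plf_params()
    kind <- sample(c("luxR_feedback", "luxI_feedback"), 1)
    lambda <- 10^runif(1, 2, 3.8)
    reg <- 10^runif(1, 1, 3.3)
    topo <- if (kind == "luxR_feedback")
      topology_spec(kind, lambda_R = lambda, luxI_fixed = reg)
    else topology_spec(kind, lambda_I = lambda, luxR_fixed = reg)
    rho <- 10^runif(1, -3, 0)
    ss <- suppressWarnings(steady_states_at_density(topo, p, rho))
    g <- promoterlogic:::feedback_map(topo, local({p$density <- rho; p}))
    ref <- oracle_roots(g, lambda, p$basal_fraction)
    expect_equal(nrow(ss), length(ref),
                 info = sprintf("instance %d root count", k))
    if (nrow(ss) == length(ref))
      expect_equal(ss$level, ref, tolerance = 1e-6,
                   info = sprintf("instance %d root locations", k))
    counts <- c(counts, nrow(ss))
  }
  # the randomized family must actually exercise multistability
  expect_gt(sum(counts >= 3), 5)
})

test_that("DDR curves have the expected fold structure", {
  # weak non-cooperative feedback: single root at every density
  p1 <- p_true
  p1$hill_m <- 1
  p1$hill_n <- 1
  t_weak <- topology_spec("luxI_feedback", lambda_I = 200, luxR_fixed = 100)
  ddr1 <- compute_ddr(t_weak, p1,
                      density_grid = exp(seq(log(1e-4), log(1), length.out = 80)),
                      rho_T = 0.05)
  expect_true(all(ddr1$counts == 1))
  expect_true(is.na(ddr1$rho_low))
  expect_equal(classify_ddr(ddr1), "M")
  # bistable configuration: exactly two folds, ordered
  ti <- topos$luxI_feedback
  ti$luxR_fixed <- 588.7
  ddr2 <- compute_ddr(ti, p_true,
                      density_grid = exp(seq(log(1e-4), log(1), length.out = 150)),
                      rho_T = 0.05)
  expect_true(is.finite(ddr2$rho_low) && is.finite(ddr2$rho_high))
  expect_lt(ddr2$rho_low, ddr2$rho_high)
  expect_equal(classify_ddr(ddr2), "B+-")
  # terminal density above / below the window changes only the class
  ddr_bplus <- ddr2; ddr_bplus$rho_T <- ddr2$rho_high * 2
  expect_equal(classify_ddr(ddr_bplus), "B+")
  ddr_bminus <- ddr2; ddr_bminus$rho_T <- ddr2$rho_low / 2
  expect_equal(classify_ddr(ddr_bminus), "B-")
})

test_that("squeezing c by k shifts fold densities by exactly 1/k", {
  ti <- topos$luxI_feedback
  ti$luxR_fixed <- 1071
  dg <- exp(seq(log(1e-4), log(1), length.out = 120))
  ddr_a <- compute_ddr(ti, p_true, density_grid = dg, rho_T = 0.05)
  k_fac <- 2.5
  p_c <- rescale_c(p_true, k_fac)
  ddr_b <- compute_ddr(ti, p_c, density_grid = dg / k_fac, rho_T = 0.05)
  expect_equal(ddr_b$rho_low, ddr_a$rho_low / k_fac, tolerance = 2e-3)
  expect_equal(ddr_b$rho_high, ddr_a$rho_high / k_fac, tolerance = 2e-3)
})

test_that("classification is stable under density-grid refinement", {
  ti <- topos$luxI_feedback
  ti$luxR_fixed <- 588.7
  dg1 <- exp(seq(log(1e-4), log(1), length.out = 200))
  dg2 <- exp(seq(log(1e-4), log(1), length.out = 400))
  d1 <- compute_ddr(ti, p_true, density_grid = dg1, rho_T = 0.05)
  d2 <- compute_ddr(ti, p_true, density_grid = dg2, rho_T = 0.05)
  expect_equal(classify_ddr(d1), classify_ddr(d2))
  expect_equal(d1$rho_low, d2$rho_low, tolerance = 0.01)
  expect_equal(d1$rho_high, d2$rho_high, tolerance = 0.01)
})

test_that("classification agrees with ON/OFF-history hysteresis simulation", {
  # random parameter draws around the defaults; discordance only allowed
  # within 1% of a fold boundary
  set.seed(77)
  dg <- exp(seq(log(1e-3), log(1), length.out = 100))
  n_checked <- 0
  for (k in 1:25) {
    p <- p_true
    p$luxr_dna_halfsat <- 300 * 10^runif(1, -0.4, 0.4)
    p$hill_n <- runif(1, 1.2, 2.2)
    lam <- 3000 * 10^runif(1, -0.4, 0.4)
    reg <- 10^runif(1, 1.5, 3.2)
    topo <- topology_spec("luxI_feedback", lambda_I = lam, luxR_fixed = reg)
    rho_T <- 0.05
    ddr <- suppressWarnings(compute_ddr(topo, p, density_grid = dg,
                                        rho_T = rho_T))
    cls <- classify_ddr(ddr)
    # skip draws within 1% of a classification boundary
    near <- is.finite(ddr$rho_low) &&
      (abs(rho_T - ddr$rho_low) < 0.01 * ddr$rho_low ||
       abs(rho_T - ddr$rho_high) < 0.01 * ddr$rho_high)
    if (near) next
    fb <- generate_feedback_dataset(topo, p, regulator_levels = reg,
                                    density_terminal = rho_T,
                                    noise = noise_model(0, k), replicates = 1)
    on <- fb$terminal[fb$history == "ON"]
    off <- fb$terminal[fb$history == "OFF"]
    hysteretic <- on / off > 3
    expect_equal(hysteretic, cls == "B+-",
                 info = sprintf("draw %d: class %s, ON/OFF ratio %.3g",
                                k, cls, on / off))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)
})

test_that("the LuxI-feedback map contains all four classes", {
  bm <- bifurcation_map(topos$luxI_feedback, p_true,
                        n_range = c(1, 4), regulator_range = c(10, 2000),
                        rho_T = 0.05, resolution = 10,
                        density_grid = exp(seq(log(1e-4), log(1),
                                               length.out = 60)))
  expect_setequal(unique(bm$class), c("M", "B+", "B+-", "B-"))
})

test_that("LuxR-feedback classes transition at most once in regulator", {
  bm <- bifurcation_map(topos$luxR_feedback, p_true,
                        n_range = c(1.2, 3.5), regulator_range = c(10, 2000),
                        rho_T = 0.05, resolution = 10,
                        density_grid = exp(seq(log(1e-4), log(1),
                                               length.out = 60)))
  for (n in unique(bm$hill_n)) {
    col <- bm[bm$hill_n == n, ]
    col <- col[order(col$regulator), ]
    is_b <- col$class != "M"
    expect_lte(sum(diff(is_b) != 0), 1,
               label = sprintf("M/B transitions at n = %.3g", n))
  }
})

test_that("map boundary agrees with the critical-point trace method", {
  # independent method: for fixed regulator, the loop is bistable at some
  # density iff the density solving lambda*f(x; rho) = x, as a function of
  # the level x, is non-monotone (its folds are the critical points)
  ti <- topos$luxI_feedback
  p_n <- p_true
  trace_is_bistable <- function(reg, n) {
    p_n$hill_n <- n
    ti$luxR_fixed <- reg
    xs <- exp(seq(log(ti$lambda_I * p_n$basal_fraction * 1.02),
                  log(ti$lambda_I * 0.98), length.out = 400))
    rho_of_x <- vapply(xs, function(x) {
      gg <- function(rho) {
        p_r <- p_n
        p_r$density <- rho
        ti$lambda_I * plf_eval(x, ti$luxR_fixed, p_r) - x
      }
      if (gg(1e-6) > 0 || gg(1e4) < 0) return(NA_real_)
      stats::uniroot(gg, c(1e-6, 1e4), tol = 1e-10)$root
    }, 0)
    ok <- is.finite(rho_of_x)
    d <- diff(log(rho_of_x[ok]))
    any(d < -1e-9) # folded back => bistable at some density
  }
  n_fix <- 1.45
  regs <- exp(seq(log(10), log(2000), length.out = 12))
  map_b <- vapply(regs, function(r) {
    ti$luxR_fixed <- r
    ddr <- suppressWarnings(
      compute_ddr(ti, p_n, density_grid = exp(seq(log(1e-4), log(10),
                                                  length.out = 100)),
                  rho_T = 0.05))
    is.finite(ddr$rho_low)
  }, TRUE)
  trace_b <- vapply(regs, trace_is_bistable, TRUE, n = n_fix)
  # boundaries agree within one grid cell
  expect_lte(sum(map_b != trace_b), 1)
})

test_that("dynamic responses lag the quasi-static DDR", {
  ti <- topos$luxI_feedback
  ti$luxR_fixed <- 1720.9
  # fast protein kinetics: dynamics track the DDR target closely
  ti_fast <- ti
  ti_fast$gamma_I <- 2000
  dr_fast <- dynamic_response(ti_fast, p_true, growth_rate = 1,
                              rho0 = 1e-4,
                              times = seq(0, 12, length.out = 80),
                              history = "OFF")
  late <- dr_fast$time > 1
  expect_lt(max(abs(dr_fast$output[late] / dr_fast$target[late] - 1)), 0.01)
  # finite kinetics, OFF start: output never overtakes the moving target
  ti_slow <- ti
  ti_slow$gamma_I <- 1
  dr_slow <- dynamic_response(ti_slow, p_true, growth_rate = 1,
                              rho0 = 1e-4,
                              times = seq(0, 12, length.out = 80),
                              history = "OFF")
  expect_true(all(dr_slow$output <= dr_slow$target * (1 + 1e-6)))
  # induction crosses 50% later than the quasi-static prediction
  half <- 0.5 * ti$lambda_I
  t_dyn <- min(dr_slow$time[dr_slow$output > half])
  t_qs <- min(dr_slow$time[dr_slow$target > half])
  expect_gt(t_dyn, t_qs)
})
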