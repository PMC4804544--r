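test_that("free growth converges to the analytic plateau and hits the day-1 volume", {
  gp <- ref_growth()
  traj <- simulate_tumour(gp, span = c(0, 300))
  vss <- steady_state_volume(gp)
  expect_lt(abs(traj$V[nrow(traj)] - vss) / vss, 1e-3)
  expect_equal(round(trajectory_interp(traj, 1)), 269)
  # trajectory invariants
  expect_true(all(diff(traj$time) > 0))
  expect_true(all(traj$V > gp$v_star) && all(traj$K > gp$v_star))
  expect_true(all(traj$I == 0))
})

test_that("terminal volumes match the steady-state formula across random parameter draws", {
  set.seed(7)
  opts <- solver_options(output_grid_step = 1)
  for (i in 1:20) {
    gp <- growth_params(lambda1 = runif(1, 0.1, 0.3), c = runif(1, 2, 8),
                        d = runif(1, 0.004, 0.02))
    vss <- steady_state_volume(gp)
    traj <- simulate_tumour(gp, span = c(0, 600), opts = opts)
    expect_lt(abs(traj$V[nrow(traj)] - vss) / vss, 1e-3)
  }
})

test_that("a zero-length span returns the initial state only", {
  traj <- simulate_tumour(ref_growth(), init = c(V = 321, K = 400),
                          span = c(5, 5))
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$V, 321)
  expect_equal(traj$K, 400)
})

test_that("simulation input validation catches inconsistent arguments", {
  expect_error(simulate_tumour(ref_growth(), regimen = ref_regimen()),
               "requires 'pk'")
  expect_error(simulate_tumour(ref_growth(), init = c(V = 0.1, K = 625)),
               "v_star")
  expect_error(simulate_tumour(ref_growth(), span = c(10, 0)), "span")
})

test_that("plateau detection follows the shared-integer-part criterion", {
  tt <- seq(0, 30, by = 0.1)
  # constant trajectory: plateau from the first sample
  pl <- detect_plateau(toy_trajectory(tt, V = rep(100.4, length(tt))))
  expect_true(pl$attained)
  expect_equal(pl$t_plateau, 0)
  expect_equal(pl$plateau_value, 100)
  # saturating curve against a shared integer band: crossing at ln(1000)
  V <- 1000 * (1 - exp(-tt))
  pl <- detect_plateau(toy_trajectory(tt, V = V, K = rep(999.5, length(tt))))
  expect_true(pl$attained)
  expect_equal(pl$plateau_value, 999)
  expect_lt(abs(pl$t_plateau - log(1000)), 0.1 + 1e-9)
  # V < 1000 throughout, so the integer parts never meet a K of exactly 1000
  pl <- detect_plateau(toy_trajectory(tt, V = V, K = rep(1000, length(tt))))
  expect_false(pl$attained)
  expect_true(is.na(pl$t_plateau))
})

test_that("reference free growth plateaus at the dormancy volume", {
  traj <- simulate_tumour(ref_growth(), span = c(0, 300))
  first <- detect_plateau(traj, rule = "first")
  conv <- detect_plateau(traj, rule = "converged")
  vss <- steady_state_volume(ref_growth())
  expect_true(first$attained && conv$attained)
  expect_lte(abs(first$plateau_value - floor(vss)), 1)
  expect_equal(conv$plateau_value, floor(vss))
  expect_lte(first$t_plateau, conv$t_plateau)
})

test_that("growth inhibition compares treated and untreated volumes pointwise", {
  tt <- seq(0, 50, 0.1)
  V <- 200 + 30 * tt
  untreated <- toy_trajectory(tt, V = V)
  expect_equal(growth_inhibition(untreated, untreated, 25), 0)
  treated <- toy_trajectory(tt, V = 0.9 * V)
  expect_equal(growth_inhibition(treated, untreated, 25), 10, tolerance = 1e-12)
  expect_error(growth_inhibition(treated, untreated, 60), "span")
})

test_that("growth delay recovers an exact time shift", {
  tt <- seq(0, 120, 0.1)
  curve <- function(t) 1500 / (1 + exp(-(t - 40) / 6))
  untreated <- toy_trajectory(tt, V = curve(tt))
  treated <- toy_trajectory(tt, V = curve(tt - 20))
  expect_equal(growth_delay(untreated, untreated, 800), 0)
  for (ref in c(400, 750, 1200)) {
    expect_equal(growth_delay(treated, untreated, ref), 20, tolerance = 1e-3)
  }
  expect_error(growth_delay(treated, untreated, 2000), "never reaches")
})

test_that("the nine-dose regimen inhibits growth and delays the plateau but not its value", {
  gp <- ref_growth()
  opts <- solver_options(output_grid_step = 0.1)
  untreated <- simulate_tumour(gp, span = c(0, 400), opts = opts)
  treated <- simulate_tumour(gp, regimen = ref_regimen(), pk = ref_pk(),
                             span = c(0, 400), opts = opts)
  expect_true(all(treated$I >= 0))
  tgi <- growth_inhibition(treated, untreated, 32)
  expect_gt(tgi, 0)
  # treatment washes out: both arms settle on the same dormancy plateau
  pl_u <- detect_plateau(untreated, rule = "converged")
  pl_t <- detect_plateau(treated, rule = "converged")
  expect_true(pl_u$attained && pl_t$attained)
  expect_lte(abs(pl_t$plateau_value - pl_u$plateau_value), 1)
  expect_gt(pl_t$t_plateau, pl_u$t_plateau)
  # the delay is positive at any reference volume below the plateau
  expect_gt(growth_delay(treated, untreated, 0.95 * pl_u$plateau_value), 0)
})

test_that("an overwhelming drug concentration drives the tumour to the avascular floor", {
  gp <- ref_growth()
  traj <- simulate_tumour(gp, span = c(0, 200),
                          conc_fn = function(t) rep(1e9, length(t)))
  expect_true(all(traj$V > gp$v_star))
  expect_true(all(traj$K > gp$v_star))
  # the volume shrinks towards (but never below) V*
  expect_lt(traj$V[nrow(traj)] - gp$v_star, 1)
  expect_lt(traj$V[nrow(traj)], traj$V[1])
})

test_that("halving the solver tolerances leaves the trajectory unchanged to 1e-4", {
  gp <- ref_growth()
  args <- list(growth = gp, regimen = ref_regimen(), pk = ref_pk(),
               span = c(0, 60))
  t1 <- do.call(simulate_tumour, c(args, list(opts = solver_options())))
  t2 <- do.call(simulate_tumour, c(args, list(
    opts = solver_options(rel_tol = 5e-9, abs_tol = 5e-11))))
  expect_equal(t1$time, t2$time)
  expect_lt(max(abs(t1$V - t2$V) / t2$V), 1e-4)
  expect_lt(max(abs(t1$K - t2$K) / t2$K), 1e-4)
})
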