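test_that("force magnitude follows the 1%-at-tau exponential decay", {
  expect_equal(force_magnitude(0, 1, 320), 1.0)
  expect_equal(force_magnitude(320, 1, 320), 0.01)
  expect_equal(force_magnitude(160, 1, 320), sqrt(0.01))
  expect_error(force_magnitude(10, 1, 0), "tau")
  expect_error(force_magnitude(-1, 1, 320), "d must")
})

test_that("force magnitude is positive, decreasing and log-linear", {
  for (tau in c(30, 140, 320)) {
    d <- seq(0, 600, by = 7)
    f <- force_magnitude(d, 2.5, tau)
    expect_true(all(f > 0))
    expect_true(all(diff(f) < 0))
    fit <- stats::lm(log(f) ~ d)
    expect_equal(unname(stats::coef(fit)[2]), log(0.01) / tau,
                 tolerance = 1e-10)
  }
})

test_that("movement freedom is a decreasing logistic hitting 0.5 at the delay", {
  sch <- stiffness_schedule(350, 300, 20)
  expect_equal(movement_freedom(300, sch), 0.5)
  expect_equal(movement_freedom(0, sch), 1, tolerance = 1e-6)
  expect_equal(movement_freedom(320, sch), 1 - exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
  k <- movement_freedom(seq(0, 350, by = 5), sch)
  expect_true(all(k > 0 & k < 1))
  expect_true(all(diff(k) <= 0))
  expect_equal(movement_freedom(-1e6, sch), 1)
  expect_lt(movement_freedom(1e4, sch), 1e-12)
})

test_that("displacement scales force by k and subtracts unscaled gravity", {
  expect_equal(displace(c(0, 0, 0), 1, 1e-4), c(0, 0, -1e-4))
  expect_equal(displace(c(7, -3, 2), 0, 0), c(0, 0, 0))
  expect_equal(displace(c(2, -1, 3), 0.5, 0), c(1, -0.5, 1.5))
})

test_that("equilibrium distance matches closed form and brute-force scan", {
  d1 <- equilibrium_distance(1, 320, 2.27, 140)
  expect_equal(d1, 44.3, tolerance = 0.01)
  d2 <- equilibrium_distance(1, 320, 2.27, 200)
  expect_equal(d2, 94.9, tolerance = 0.01)
  expect_equal(equilibrium_distance(1, 320, 1, 140), 0)
  # brute-force sign-change oracle over randomized valid parameters
  set.seed(42)
  checked <- 0
  while (checked < 20) {
    tau_a <- runif(1, 150, 400)
    tau_r <- runif(1, 50, tau_a - 20)
    A_eff <- runif(1, 0.5, 2)
    R <- A_eff * runif(1, 1.01, 6)
    d <- equilibrium_distance(A_eff, tau_a, R, tau_r)
    if (d > 450) next # outside the oracle's scan range
    scan <- oracle_equilibrium_scan(A_eff, tau_a, R, tau_r)
    expect_lt(abs(d - scan), 0.011)
    checked <- checked + 1
  }
  expect_error(equilibrium_distance(1, 320, 2.27, 320), "tau_a")
})

test_that("repulsion_for_equilibrium inverts equilibrium_distance exactly", {
  expect_equal(repulsion_for_equilibrium(70, 1, 320, 140), 3.652,
               tolerance = 1e-3)
  expect_equal(repulsion_for_equilibrium(44.3, 1, 320, 140), 2.27,
               tolerance = 1e-3)
  expect_equal(repulsion_for_equilibrium(0, 1, 320, 140), 1.0)
  set.seed(7)
  for (q in 1:25) {
    tau_a <- runif(1, 100, 400)
    tau_r <- runif(1, 30, 400)
    if (abs(tau_a - tau_r) < 5) next
    target <- runif(1, 0, 200)
    R <- repulsion_for_equilibrium(target, 1, tau_a, tau_r)
    back <- tryCatch(equilibrium_distance(1, tau_a, R, tau_r),
                     error = function(e) NA_real_)
    if (!is.na(back))
      expect_equal(back, target, tolerance = 1e-9)
  }
})

test_that("net force matches the brute-force pairwise oracle", {
  set.seed(11)
  fp <- force_parameters()
  pos <- cbind(runif(40, 0, 500), runif(40, 0, 200), runif(40, 0, 100))
  types <- sample(c("N", "A"), 40, replace = TRUE)
  anchors <- cbind(runif(15, 0, 500), runif(15, 0, 200))
  pop <- cell_population(pos, types)
  af <- anchor_field(anchors)
  for (i in c(1, 17, 40)) {
    expect_equal(unname(net_force(i, pop, af, fp)),
                 oracle_net_force(i, pos, types, anchors, fp),
                 tolerance = 1e-10)
  }
})

test_that("pairwise forces balance at the equilibrium distance and attract beyond it", {
  fp <- force_parameters(S = 0, g = 0)
  dstar <- equilibrium_distance(fp$A * fp$AS["N", "N"], fp$tau_a,
                                fp$R, fp$tau_r)
  two <- function(sep) cell_population(rbind(c(0, 0, 50), c(sep, 0, 50)),
                                       c("N", "N"))
  none <- anchor_field(matrix(numeric(0), 0, 2))
  f_eq <- net_force(1, two(dstar), none, fp)
  expect_lt(sqrt(sum(f_eq^2)), 1e-12)
  f_far <- net_force(1, two(2 * dstar), none, fp)
  expect_gt(f_far["Fx"], 0) # toward the partner
  f_near <- net_force(1, two(dstar / 2), none, fp)
  expect_lt(f_near["Fx"], 0) # pushed away
})

test_that("a lone anchored cell feels 1% of S one length constant away", {
  fp <- force_parameters(A = 0, R = 0, S = 0.01, tau_s = 30)
  pop <- cell_population(rbind(c(100, 100, 30)), "N")
  af <- anchor_field(rbind(c(100, 100)))
  f <- net_force(1, pop, af, fp)
  expect_equal(unname(f), c(0, 0, -0.01 * 0.01), tolerance = 1e-12)
})

test_that("two-cell forces are antisymmetric for symmetric AS and scale by the AS ratio otherwise", {
  none <- anchor_field(matrix(numeric(0), 0, 2))
  pop <- cell_population(rbind(c(0, 0, 10), c(80, 30, 40)), c("N", "A"))
  sym <- force_parameters(AS_NA = 0.9, AS_AN = 0.9, S = 0)
  f1 <- net_force(1, pop, none, sym)
  f2 <- net_force(2, pop, none, sym)
  expect_equal(unname(f1), -unname(f2), tolerance = 1e-12)
  asym <- force_parameters(AS_NA = 0.9, AS_AN = 0.3, S = 0, R = 0)
  g1 <- net_force(1, pop, none, asym) # neuron: attraction scaled by N-A
  g2 <- net_force(2, pop, none, asym) # astrocyte: scaled by A-N
  expect_equal(unname(g1) / -unname(g2), rep(0.9 / 0.3, 3),
               tolerance = 1e-12)
})

test_that("published presets differ only in the repulsion length constant", {
  opt <- force_preset("optimized")
  ini <- force_preset("initial")
  expect_equal(opt$tau_r, 200)
  expect_equal(ini$tau_r, 140)
  ini$tau_r <- 200
  expect_equal(unclass(opt), unclass(ini))
  expect_equal(opt$AS["N", "N"], 1)
  expect_equal(opt$AS["A", "A"], 0.7)
})

test_that("invalid force parameters are rejected", {
  expect_error(force_parameters(A = -1), "strengths")
  expect_error(force_parameters(tau_a = 0), "length constants")
  expect_error(stiffness_schedule(0), "total_time")
  expect_error(stiffness_schedule(350, 300, 0), "stiffening_constant")
})
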