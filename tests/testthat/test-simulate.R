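test_that("zero-activation configurations hit the closed-form fixed point", {
  # closed form: EIG* = 1(x) (uniform-wound case), JNK* = 1/kdeg_JNK, etc.
  q <- zero_activation_params(kdeg_JNK = 2, kdeg_JAK = 4, kdeg_UPD = 0.5)
  cfg <- model_config(n_compartments = 20, wound = c(0, 1))
  ss <- integrate_to_steady_state(q, cfg)
  expect_true(ss$converged)
  expect_lt(max(abs(ss$state$EIG - 1)), 1e-6)
  expect_lt(max(abs(ss$state$JNK - 1 / 2)), 1e-6)
  expect_lt(max(abs(ss$state$JAK - 1 / 4)), 1e-6)
  expect_lt(max(abs(ss$state$UPD - 2)), 1e-6)
})

test_that("residual meets tolerance on convergence and reruns are bit-identical", {
  q <- dimensionless_params(gamma = 50, kact_JNK = 100, Km_JNK = 0.1, n2 = 2)
  cfg <- small_cfg(30)
  a <- integrate_to_steady_state(q, cfg)
  b <- integrate_to_steady_state(q, cfg)
  expect_true(a$converged)
  expect_lte(a$residual, cfg$ss_tol)
  expect_identical(a$residual, b$residual)
  expect_identical(a$state, b$state)
})

test_that("kymograph starts at the initial state and ends at the final state", {
  q <- zero_activation_params()
  cfg <- model_config(n_compartments = 15, kymograph = TRUE, kymo_frames = 50)
  ss <- integrate_to_steady_state(q, cfg)
  k <- ss$kymograph
  expect_equal(dim(k), c(51, 15, 4))
  expect_equal(unname(k[1, , "EIG"]), rep(0.1, 15))  # initial value
  expect_equal(unname(k[1, , "JNK"]), rep(0.1, 15))
  last <- dim(k)[1]
  expect_equal(unname(k[last, , "JAK"]), ss$state$JAK)
  expect_equal(unname(k[last, , "UPD"]), ss$state$UPD)
  expect_equal(attr(k, "times")[1], 0)
})

test_that("Newton oracle recovers the closed-form fixed point from afar", {
  q <- zero_activation_params(kdeg_JNK = 3, kdeg_JAK = 2, kdeg_UPD = 1)
  cfg <- model_config(n_compartments = 10, wound = c(0, 1))
  guess <- species_state(rep(0.5, 10), rep(0.5, 10), rep(0.5, 10), rep(0.5, 10))
  nt <- steady_state_by_rootfinding(q, cfg, guess)
  expect_true(nt$converged)
  expect_lte(nt$residual, 1e-9)
  expect_lt(max(abs(nt$state$JNK - 1 / 3)), 1e-8)
  expect_lt(max(abs(nt$state$UPD - 1)), 1e-8)
})

test_that("Newton seeded at a converged endpoint stays put", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    q <- dimensionless_params(gamma = 10^runif(1, -1, 2),
                              kact_JNK = 10^runif(1, 0, 3),
                              kact_JAK = 10^runif(1, 0, 2),
                              Km_JNK = 10^runif(1, -2, 1), n2 = 2, ni2 = 2)
    cfg <- small_cfg(25)
    ss <- integrate_to_steady_state(q, cfg)
    expect_true(ss$converged)
    nt <- steady_state_by_rootfinding(q, cfg, ss$state)
    expect_true(nt$converged)
    expect_lt(max(abs(unlist(nt$state) - unlist(unclass(ss$state)))), 1e-6)
  }
})

test_that("trajectories from non-negative initial states stay non-negative", {
  set.seed(17)
  cfg <- small_cfg(20)
  for (i in 1:5) {
    q <- dimensionless_params(
      gamma = 10^runif(1, -2, 3), kdeg_JNK = 10^runif(1, -1, 2),
      kact_JNK = 10^runif(1, -1, 3), kact_JAK = 10^runif(1, -1, 3),
      Km_JNK = 10^runif(1, -2, 1), kinh_JNK_by_JAK = 10^runif(1, -1, 2),
      kinh_JAK_by_JNK = 10^runif(1, -1, 2),
      n2 = runif(1, 1, 4), ni1 = runif(1, 1, 4), ni2 = runif(1, 1, 4),
      d = runif(1, 1.5, 4))
    ss <- integrate_to_steady_state(q, cfg)
    expect_gte(min(unlist(unclass(ss$state))), -1e-9)
  }
})

test_that("tightening tolerance does not flip classification", {
  q <- dimensionless_params(gamma = 100, kact_JNK = 300, kact_JAK = 20,
                            kinh_JAK_by_JNK = 5, kinh_JNK_by_JAK = 0.2,
                            Km_JNK = 0.3, Km_JAK = 0.5, n2 = 2, n3 = 2,
                            ni1 = 2, ni2 = 2)
  ref <- generate_reference_pair(n_grid = 40)
  loose <- integrate_to_steady_state(q, small_cfg(40, ss_tol = 1e-5))
  tight <- integrate_to_steady_state(q, small_cfg(40, ss_tol = 1e-8))
  expect_equal(classify_simple(loose)$simple, classify_simple(tight)$simple)
  expect_equal(classify_observed(loose, ref)$observed,
               classify_observed(tight, ref)$observed)
})

test_that("solver breakdown is reported, not thrown", {
  # absurdly stiff corner: must come back flagged, never error
  q <- dimensionless_params(gamma = 1e4, kdeg_JNK = 1e4, kact_JNK = 1e4,
                            Km_JNK = 1e-5, n2 = 4)
  cfg <- small_cfg(10, max_steps = 50)
  expect_no_error(ss <- integrate_to_steady_state(q, cfg))
  expect_false(is.null(ss$diag))
})
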