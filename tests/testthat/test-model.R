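test_that("nondimensionalize reproduces the tabulated ratios", {
  # identity: all dimensional parameters 1 -> all dimensionless 1
  q <- nondimensionalize(dimensional_params())
  expect_equal(unname(as.numeric(q)), rep(1, 21))

  # diffusion ratio and gamma
  expect_equal(nondimensionalize(dimensional_params(D_UPD = 2))[["d"]], 2)
  q2 <- nondimensionalize(dimensional_params(kdeg_EIG = 2, L = 3, D_EIG = 0.5))
  expect_equal(q2[["gamma"]], 36)  # kdeg_EIG * L^2 / D_EIG

  # degradation and activation ratios
  q3 <- nondimensionalize(dimensional_params(kdeg_JNK = 6, kdeg_EIG = 2,
                                             kact_EIG = 5, b_EIG = 10))
  expect_equal(q3[["kdeg_JNK"]], 3)
  expect_equal(q3[["kact_EIG"]], 0.5)

  # Hill coefficients pass through unchanged
  q4 <- nondimensionalize(dimensional_params(n1 = 2, ni2 = 3.5))
  expect_equal(q4[["n1"]], 2)
  expect_equal(q4[["ni2"]], 3.5)

  # non-positive divisor rejected
  expect_error(dimensional_params(D_EIG = 0), "> 0")
})

test_that("parameter validation enforces invariants", {
  expect_error(dimensionless_params(gamma = -1), "positive")
  expect_error(dimensionless_params(n1 = 0.5), "Hill")
  expect_error(dimensionless_params(bogus = 1), "unknown")
  # kact/kinh may be exactly zero (term switched off)
  expect_silent(dimensionless_params(kact_JNK = 0, kinh_JAK_by_JNK = 0))
})

test_that("wound indicator covers exactly the configured compartments", {
  cfg <- model_config()
  ind <- wound_indicator(cfg)
  expect_equal(sum(ind), 5)          # 100 compartments, wound [0, 0.05]
  expect_equal(which(ind == 1), 1:5)
  cfg2 <- model_config(n_compartments = 20, wound = c(0, 0.25))
  expect_equal(sum(wound_indicator(cfg2)), 5)
})

test_that("rhs matches hand computation at the zero state", {
  cfg <- small_cfg(20)
  z <- rep(0, 20)
  st <- species_state(z, z, z, z)
  q <- dimensionless_params(gamma = 7)
  f <- model_rhs(st, q, cfg)
  ind <- wound_indicator(cfg)
  # all Hill numerators vanish at zero substrate; only basal terms remain
  expect_equal(f$EIG, 7 * ind)       # dEIG = gamma * 1(x) in wound, 0 outside
  expect_equal(f$JNK, rep(7, 20))
  expect_equal(f$JAK, rep(7, 20))
  expect_equal(f$UPD, rep(7, 20))
})

test_that("rhs with zero activation is the pure linear system", {
  # uniform state kills diffusion; derivative reduces to gamma*(1(x) - E)
  # and gamma*(1 - kdeg*u) per species
  cfg <- model_config(n_compartments = 10, wound = c(0, 1))
  q <- zero_activation_params(kdeg_JNK = 3, kdeg_JAK = 1, kdeg_UPD = 2)
  v <- 0.4
  st <- species_state(rep(v, 10), rep(v, 10), rep(v, 10), rep(v, 10))
  f <- model_rhs(st, q, cfg)
  expect_equal(f$EIG, rep(1 - v, 10))
  expect_equal(f$JNK, rep(1 - 3 * v, 10))
  expect_equal(f$JAK, rep(1 - 1 * v, 10))
  expect_equal(f$UPD, rep(1 - 2 * v, 10))
})

test_that("rhs matches an independent pure-R evaluation of the equations", {
  # slow reference implementation of the nondimensional system, written
  # directly from the equations; checks the compiled core on random input
  rhs_oracle <- function(st, q, cfg) {
    ind <- wound_indicator(cfg)
    hill <- function(u, K, n) u^n / (K^n + u^n)
    E <- st$EIG; J <- st$JNK; S <- st$JAK; U <- st$UPD
    A <- 1 + q[["kinh_JNK_by_JAK"]]^q[["ni1"]] * S^q[["ni1"]]
    B <- if (cfg$topology == "mutual")
      1 + q[["kinh_JAK_by_JNK"]]^q[["ni2"]] * J^q[["ni2"]] else 1
    g <- q[["gamma"]]
    list(EIG = g * (ind - E + q[["kact_EIG"]] * hill(J, q[["Km_EIG"]], q[["n1"]])) +
           laplacian(E, cfg),
         JNK = g * (1 - q[["kdeg_JNK"]] * J +
                      q[["kact_JNK"]] * hill(E, q[["Km_JNK"]], q[["n2"]]) / A),
         JAK = g * (1 - q[["kdeg_JAK"]] * S +
                      q[["kact_JAK"]] * U * hill(S, q[["Km_JAK"]], q[["n3"]]) / B),
         UPD = g * (1 - q[["kdeg_UPD"]] * U +
                      q[["kact_UPD"]] * hill(J, q[["Km_UPD"]], q[["n4"]])) +
           q[["d"]] * laplacian(U, cfg))
  }
  set.seed(3)
  for (topo in c("mutual", "unidirectional")) {
    cfg <- model_config(topo, n_compartments = 12)
    q <- dimensionless_params(gamma = 2.7, kact_JNK = 5, kact_JAK = 3,
                              Km_JNK = 0.5, n2 = 2.3, ni1 = 1.7, ni2 = 3,
                              kinh_JNK_by_JAK = 2, kinh_JAK_by_JNK = 4,
                              d = 2.2)
    st <- species_state(runif(12), runif(12), runif(12), runif(12))
    f_cpp <- model_rhs(st, q, cfg)
    f_ref <- rhs_oracle(st, q, cfg)
    expect_equal(f_cpp, f_ref, tolerance = 1e-12)
  }
})

test_that("mutual topology with zero JNK->JAK inhibition equals unidirectional", {
  set.seed(5)
  q <- dimensionless_params(kinh_JAK_by_JNK = 0, kact_JAK = 10, n3 = 2,
                            ni2 = 3)
  st <- species_state(runif(15), runif(15), runif(15), runif(15))
  f_mut <- model_rhs(st, q, model_config("mutual", n_compartments = 15))
  f_uni <- model_rhs(st, q, model_config("unidirectional", n_compartments = 15))
  expect_identical(f_mut, f_uni)
})

test_that("laplacian implements the zero-flux stencil", {
  expect_equal(laplacian(rep(3.2, 50)), rep(0, 50))          # constants
  expect_equal(laplacian(c(0, 1, 0), dx = 1), c(1, -2, 1))   # canonical
  set.seed(42)
  for (i in 1:5) {
    f <- rnorm(100)
    expect_lt(abs(sum(laplacian(f))), 1e-12 * max(abs(f)) * 1e4)
  }
  expect_error(laplacian(1), "at least 2")
  # absorbing boundary leaks flux
  cfg_abs <- model_config(boundary = "absorbing", n_compartments = 3)
  expect_lt(sum(laplacian(rep(1, 3), cfg_abs)), 0)
})

test_that("uniform production keeps a uniform state uniform", {
  cfg <- model_config(n_compartments = 30, wound = c(0, 1))
  q <- dimensionless_params(kact_JNK = 2, kact_JAK = 2, kact_UPD = 2,
                            kact_EIG = 0.5)
  ss <- integrate_to_steady_state(q, cfg)
  for (s in names(ss$state))
    expect_lt(diff(range(ss$state[[s]])), 1e-9)
})

test_that("rhs rejects inconsistent input", {
  cfg <- small_cfg(10)
  st <- species_state(rep(1, 5), rep(1, 5), rep(1, 5), rep(1, 5))
  expect_error(model_rhs(st, dimensionless_params(), cfg), "compartment count")
  expect_error(species_state(c(-1, 1), c(1, 1), c(1, 1), c(1, 1)), ">= 0")
})
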