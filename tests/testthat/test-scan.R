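test_that("sampling respects ranges, scales and determinism", {
  cfg <- sampling_config(n_sets = 2000, seed = 99)
  p <- sample_parameters(cfg)
  expect_equal(nrow(p), 2000)
  # tabulated ranges
  for (col in c("kdeg_JNK", "kdeg_JAK", "kdeg_UPD", "kact_JNK"))
    expect_true(all(p[[col]] >= 0.01 & p[[col]] <= 10000))
  expect_true(all(p$kact_EIG >= 1e-5 & p$kact_EIG <= 10))
  expect_true(all(p$Km_EIG >= 1e-5 & p$Km_EIG <= 10))
  expect_true(all(p$d >= 1.5 & p$d <= 4))
  for (h in c("n1", "n2", "n3", "n4", "ni1", "ni2"))
    expect_true(all(p[[h]] >= 1 & p[[h]] <= 4))
  # log-uniform marginal: median of log10 near range midpoint
  expect_lt(abs(median(log10(p$kdeg_JNK)) - 1), 0.25)  # mid of [-2, 4]
  # determinism
  expect_identical(p, sample_parameters(cfg))
  # different seed differs
  expect_false(identical(p$gamma,
                         sample_parameters(sampling_config(2000, seed = 100))$gamma))
})

test_that("hill sampling modes and the tied 19-parameter scheme work", {
  pi_ <- sample_parameters(sampling_config(500, seed = 3, hill_values = "integer"))
  expect_true(all(pi_$n1 %in% 1:4))
  p4 <- sample_parameters(sampling_config(500, seed = 3, hill_scheme = "four"))
  expect_identical(p4$ni1, p4$n2)
  expect_identical(p4$ni2, p4$n3)
})

test_that("diffusion regimes set the d range", {
  p <- sample_parameters(sampling_config(200, seed = 5,
                                         diffusion_regime = "upd_slower"))
  expect_true(all(p$d >= 0.25 & p$d <= 0.67))
  pe <- sample_parameters(sampling_config(50, seed = 5,
                                          diffusion_regime = "equal"))
  expect_true(all(pe$d == 1))
})

test_that("run_scan pairs topologies, records everything, and is reproducible", {
  rec <- tiny_scan()
  expect_s3_class(rec, "wf_records")
  expect_equal(nrow(rec), 16)  # 8 sets x 2 topologies
  expect_setequal(unique(rec$topology), c("mutual", "unidirectional"))
  # paired: identical set ids per topology
  expect_identical(sort(rec$set_id[rec$topology == "mutual"]),
                   sort(rec$set_id[rec$topology == "unidirectional"]))
  # non-converged rows carry both flags false
  nc <- rec[!rec$converged, ]
  if (nrow(nc)) {
    expect_true(all(!nc$simple))
    expect_true(all(!nc$observed))
  }
  # parameters are attached as columns
  expect_true(all(param_names() %in% names(rec)))
  # reproducibility
  rec2 <- run_scan(sampling_config(n_sets = 8, seed = 11),
                   model_config(n_compartments = 40, t_max = 200))
  expect_equal(as.data.frame(rec), as.data.frame(rec2))
})

test_that("zero-activation scan member is flat and never bistable", {
  params <- cbind(data.frame(set_id = 1L),
                  as.data.frame(as.list(zero_activation_params())))
  rec <- run_scan(params, model_config(n_compartments = 30))
  expect_true(all(rec$converged))
  expect_true(all(!rec$simple))
  expect_true(all(!rec$observed))
})

test_that("compare_models counts and percentages are exact", {
  # constructed record table: 3 mutual-bistable, 1 unidirectional of 10
  base <- data.frame(set_id = rep(1:10, 2),
                     topology = rep(c("mutual", "unidirectional"), each = 10),
                     converged = TRUE, observed = FALSE, simple = FALSE)
  base$simple[base$topology == "mutual"][1:3] <- TRUE
  base$simple[base$topology == "unidirectional"][1] <- TRUE
  cmp <- compare_models(base)
  s <- cmp$summary
  expect_equal(s$pct_simple[s$topology == "mutual"], 30)
  expect_equal(s$pct_simple[s$topology == "unidirectional"], 10)
  expect_equal(sum(cmp$paired_simple), 10)
  # empty and mismatched tables rejected
  expect_error(compare_models(base[0, ]), "non-empty")
  expect_error(compare_models(base[-1, ]), "identical parameter sets")
  # all-false flags give zero percentages
  base$simple <- FALSE
  expect_true(all(compare_models(base)$summary$pct_simple == 0))
})

test_that("parameter_density bins frequencies over the scanned range", {
  set.seed(12)
  n <- 400
  rec <- data.frame(set_id = 1:n, topology = "mutual", converged = TRUE,
                    kact_JNK = 10^runif(n, -2, 4))
  rec$simple <- rec$kact_JNK > median(rec$kact_JNK)
  d <- parameter_density(rec, "kact_JNK", bins = 8)
  expect_equal(sum(d$n), n)                  # counts cover all records
  expect_true(all(d$frequency[d$bin_low >= median(rec$kact_JNK)] == 1))
  expect_true(all(d$frequency[d$bin_high <= median(rec$kact_JNK)] == 0))
  # degenerate cases
  rec$simple <- TRUE
  expect_true(all(parameter_density(rec, "kact_JNK")$frequency[
    parameter_density(rec, "kact_JNK")$n > 0] == 1))
  rec$simple <- FALSE
  expect_true(all(parameter_density(rec, "kact_JNK")$frequency == 0))
  expect_error(parameter_density(rec, "not_a_parameter"), "unknown parameter")
})
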