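test_that("a noiseless block yields perfect within-block Spearman correlation", {
  spec <- synthetic_spec(
    n_samples_per_condition = 10, n_metabolites = 3,
    blocks = list(B = list(members = c("m001", "m002", "m003"),
                           loading = 1, signs = c(1, 1, -1))),
    trait_block = NULL, noise_sd = 0,
    treatment_disrupted_blocks = character(), seed = 7)
  am <- generate_dataset(spec)
  ctrl <- am$values[am$metadata$condition == "control", ]
  r <- cor(ctrl, method = "spearman")
  expect_equal(r["m001", "m002"], 1)
  # sign pattern: the -1 member is exactly anticorrelated
  expect_equal(r["m001", "m003"], -1)
  expect_equal(r["m002", "m003"], -1)
})

test_that("identical spec and seed reproduce the dataset byte-identically", {
  spec <- benchmark_spec(seed = 3)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$values,
                         generate_dataset(benchmark_spec(seed = 4))$values))
})

test_that("disrupted blocks are statistically null under treatment", {
  mean_abs <- replicate(50, {
    spec <- synthetic_spec(
      n_samples_per_condition = 10, n_metabolites = 3,
      blocks = list(B = list(members = c("m001", "m002", "m003"),
                             loading = 1)),
      trait_block = NULL, noise_sd = 0.3,
      treatment_disrupted_blocks = "B",
      seed = sample.int(1e6, 1))
    am <- generate_dataset(spec)
    tr <- am$values[am$metadata$condition == "treated", ]
    r <- cor(tr, method = "spearman")
    mean(abs(r[upper.tri(r)]))
  })
  expect_lt(mean(mean_abs), 0.4)
})

test_that("independent blocks are uncorrelated in expectation", {
  rhos <- replicate(50, {
    spec <- synthetic_spec(
      n_samples_per_condition = 10, n_metabolites = 2,
      blocks = list(A = list(members = "m001", loading = 1),
                    B = list(members = "m002", loading = 1)),
      trait_block = NULL, noise_sd = 0,
      treatment_disrupted_blocks = character(),
      seed = sample.int(1e6, 1))
    am <- generate_dataset(spec)
    ctrl <- am$values[am$metadata$condition == "control", ]
    cor(ctrl, method = "spearman")[1, 2]
  })
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("sign flips reverse a member's correlation under treatment only", {
  spec <- synthetic_spec(
    n_samples_per_condition = 10, n_metabolites = 2,
    blocks = list(B = list(members = c("m001", "m002"), loading = 1)),
    trait_block = NULL, noise_sd = 0,
    treatment_disrupted_blocks = character(),
    treatment_sign_flips = "m002", seed = 11)
  am <- generate_dataset(spec)
  ctrl <- am$values[am$metadata$condition == "control", ]
  tr <- am$values[am$metadata$condition == "treated", ]
  expect_equal(cor(ctrl, method = "spearman")[1, 2], 1)
  expect_equal(cor(tr, method = "spearman")[1, 2], -1)
})

test_that("truth_table enumerates planted edges and modules per condition", {
  spec <- synthetic_spec(
    n_samples_per_condition = 5, n_metabolites = 7,
    blocks = list(A = list(members = c("m001", "m002", "m003"), loading = 1),
                  B = list(members = c("m004", "m005", "m006", "m007"),
                           loading = 1)),
    trait_block = NULL, noise_sd = 0,
    treatment_disrupted_blocks = "A", seed = 1)
  tt <- truth_table(spec)
  expect_equal(nrow(tt$edges$control), 3 + 6)
  keys <- edge_keys(tt$edges$control$u, tt$edges$control$v)
  expect_true(all(c("m001|m002", "m001|m003", "m002|m003") %in% keys))
  # disrupted block contributes nothing under treatment
  expect_equal(nrow(tt$edges$treated), 6)
  expect_false(any(tt$edges$treated$block == "A"))
  expect_named(tt$modules$control, c("A", "B"))
  expect_named(tt$modules$treated, "B")
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_samples_per_condition = 0),
               "positive integer")
  expect_error(
    synthetic_spec(
      n_metabolites = 3,
      blocks = list(A = list(members = c("m001", "m002"), loading = 1),
                    B = list(members = c("m002", "m003"), loading = 1)),
      trait_block = NULL, treatment_disrupted_blocks = character()),
    "overlap")
  expect_error(
    synthetic_spec(
      n_metabolites = 2,
      blocks = list(A = list(members = "m001", loading = 2)),
      trait_block = NULL, treatment_disrupted_blocks = character()),
    "loading")
  expect_error(synthetic_spec(trait_block = "nope"), "not a declared block")
})

test_that("write_dataset materializes a round-trippable dataset", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_samples_per_condition = 5, n_metabolites = 10,
                         blocks = list(B = list(members = paste0("m00", 1:4),
                                                loading = 0.9)),
                         trait_block = "B",
                         treatment_disrupted_blocks = "B", seed = 5)
  paths <- write_dataset(spec, dir)
  expect_true(all(file.exists(paths)))
  am <- generate_dataset(spec)
  back <- read_abundance(paths[["abundance"]], meta = paths[["metadata"]])
  expect_equal(back$values, am$values, tolerance = 1e-12)
  expect_equal(back$metadata$condition, am$metadata$condition)
  map <- read_pathway_map(paths[["pathways"]])
  expect_equal(unname(map[["m001"]]),
               unname(spec$pathway_assignment[["m001"]]))
})
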