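test_that("single-member and rank-1 pathways explain all variance", {
  withr::local_seed(21)
  x <- rlnorm(10)
  am <- make_am(cbind(m1 = x, m2 = rlnorm(10)))
  em <- compute_eigenmetabolite(am, "all", "m1", pathway = "solo")
  expect_equal(em$variance_explained, 1)
  expect_equal(unname(em$scores), as.vector(scale(x)))
  expect_equal(unname(em$loading), 1)

  # two perfectly anticorrelated members: rank 1, opposite loadings
  y <- max(x) + 1 - x
  am2 <- make_am(cbind(up = x, down = y))
  em2 <- compute_eigenmetabolite(am2, "all", c("up", "down"), "anti")
  expect_equal(em2$variance_explained, 1)
  expect_lt(prod(em2$loading), 0)
  expect_equal(sqrt(sum(em2$loading^2)), 1)
  # the deterministic sign rule orients toward one member positively
  cors <- cor(em2$scores, scale(cbind(x, y)))
  expect_equal(sum(cors > 0), 1)
})

test_that("variance explained matches an independent eigen-decomposition", {
  withr::local_seed(22)
  for (i in 1:25) {
    n <- sample(6:12, 1); k <- sample(2:6, 1)
    vals <- matrix(rlnorm(n * k), n, k,
                   dimnames = list(NULL, paste0("m", seq_len(k))))
    am <- make_am(vals)
    em <- compute_eigenmetabolite(am, "all", colnames(vals), "rand")
    ev <- eigen(cor(vals), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(em$variance_explained, ev[1] / sum(ev), tolerance = 1e-10)
    expect_gte(em$variance_explained, 0)
    expect_lte(em$variance_explained, 1)
  }
})

test_that("the eigenmetabolite is invariant to member order and scale", {
  withr::local_seed(23)
  vals <- matrix(rlnorm(8 * 4), 8, 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  am <- make_am(vals)
  e1 <- compute_eigenmetabolite(am, "all", colnames(vals), "p")
  e2 <- compute_eigenmetabolite(am, "all", rev(colnames(vals)), "p")
  expect_equal(unname(e1$scores), unname(e2$scores), tolerance = 1e-9)
  vals2 <- vals
  vals2[, 2] <- vals2[, 2] * 1000  # rescaling is absorbed by z-scoring
  e3 <- compute_eigenmetabolite(make_am(vals2), "all", colnames(vals), "p")
  expect_equal(unname(e1$scores), unname(e3$scores), tolerance = 1e-9)
})

test_that("degenerate pathways are skipped or pruned with warnings", {
  vals <- cbind(m1 = rlnorm(6), flat = rep(2, 6))
  am <- make_am(vals)
  expect_warning(em <- compute_eigenmetabolite(am, "all", c("m1", "flat"),
                                               "pw"), "zero-variance")
  expect_equal(em$members, "m1")
  w <- capture_warnings(res <- compute_eigenmetabolite(am, "all", "absent",
                                                       "pw"))
  expect_match(w, "absent|no matched", all = TRUE)
  expect_null(res)
})

test_that("pathway correlation is symmetric with unit diagonal and checks samples", {
  spec <- synthetic_spec(
    n_samples_per_condition = 10, n_metabolites = 8,
    blocks = list(B = list(members = sprintf("m%03d", 1:8), loading = 1)),
    trait_block = NULL, noise_sd = 0,
    treatment_disrupted_blocks = character(), seed = 31)
  am <- generate_dataset(spec)
  members <- list(P1 = sprintf("m%03d", 1:4), P2 = sprintf("m%03d", 5:8))
  profs <- pathway_eigenmetabolites(am, "control", members)
  pc <- pathway_correlation(profs)
  # both pathways ride the same latent factor: |rho| = 1
  expect_equal(abs(pc$rho["P1", "P2"]), 1)
  expect_equal(pc$rho, t(pc$rho))
  expect_equal(unname(diag(pc$rho)), c(1, 1))

  mangled <- profs
  mangled$P2$scores <- mangled$P2$scores[-1]
  expect_error(pathway_correlation(mangled), "different sample sets")
})

test_that("independent pathways stay near the null correlation level", {
  withr::local_seed(44)
  vals_abs <- replicate(20, {
    spec <- synthetic_spec(
      n_samples_per_condition = 10, n_metabolites = 8,
      blocks = list(A = list(members = sprintf("m%03d", 1:4), loading = 1),
                    B = list(members = sprintf("m%03d", 5:8), loading = 1)),
      trait_block = NULL, noise_sd = 0.2,
      treatment_disrupted_blocks = character(),
      seed = sample.int(1e6, 1))
    am <- generate_dataset(spec)
    members <- list(P1 = sprintf("m%03d", 1:4), P2 = sprintf("m%03d", 5:8))
    pc <- pathway_correlation(pathway_eigenmetabolites(am, "control",
                                                       members))
    abs(pc$rho["P1", "P2"])
  })
  expect_lt(mean(vals_abs), 0.4)
})

test_that("condition_contrast reports reversals, drops, and identity", {
  mk_pc <- function(r12, r13, r23) {
    rho <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3,
                  dimnames = list(c("P1", "P2", "P3"), c("P1", "P2", "P3")))
    structure(list(pathways = c("P1", "P2", "P3"), rho = rho,
                   variance_explained = rep(1, 3), condition = "x",
                   method = "spearman"),
              class = "pathway_connectivity")
  }
  ctrl <- mk_pc(0.8, 0.9, 0.1)
  same <- condition_contrast(ctrl, ctrl)
  expect_true(all(same$n_sign_reversals == 0))
  expect_true(all(same$mean_delta_abs_rho == 0))
  expect_false(any(same$disrupted))

  # single pair +0.8 -> -0.7: one reversal, |rho| drop of 0.1
  treated <- mk_pc(-0.7, 0.9, 0.1)
  cc <- condition_contrast(ctrl, treated, focus = "P1")
  expect_equal(cc$n_sign_reversals, 1)
  p12_delta <- abs(0.8) - abs(-0.7)
  expect_equal(cc$mean_delta_abs_rho, mean(c(p12_delta, 0)))
  expect_equal(cc$mean_drop_connected, mean(c(p12_delta, 0)))
  expect_false(cc$disrupted)

  # a genuine collapse of previously connected pairs is flagged
  collapsed <- mk_pc(0.05, -0.1, 0.1)
  cc2 <- condition_contrast(ctrl, collapsed, focus = "P1")
  expect_true(cc2$disrupted)
})
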