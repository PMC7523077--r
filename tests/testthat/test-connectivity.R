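corr_fixture <- function(nodes, rho_pairs, q_pairs) {
  m <- length(nodes)
  rho <- diag(m); dimnames(rho) <- list(nodes, nodes)
  q <- matrix(0, m, m, dimnames = dimnames(rho))
  for (k in seq_along(rho_pairs)) {
    ij <- strsplit(names(rho_pairs)[k], ":")[[1]]
    rho[ij[1], ij[2]] <- rho[ij[2], ij[1]] <- rho_pairs[k]
    q[ij[1], ij[2]] <- q[ij[2], ij[1]] <- q_pairs[k]
  }
  structure(list(nodes = nodes, rho = rho, p = q, q = q,
                 n_eff = matrix(10, m, m), condition = "c",
                 n_samples = 10, trait_node = NULL),
            class = "correlation_result")
}

test_that("spearman_matrix reproduces monotone and tied-rank fixtures", {
  vals <- cbind(m1 = c(1, 2, 3, 4), m2 = c(10, 20, 30, 40),
                m3 = c(4, 3, 2, 1))
  cr <- spearman_matrix(make_am(vals), "all", include_trait = FALSE)
  expect_equal(cr$rho["m1", "m2"], 1)
  expect_equal(cr$rho["m1", "m3"], -1)
  expect_equal(cr$p["m1", "m2"], 0)

  # tied ranks: x=(1,2,2,4), y=(1,3,2,4) -> 4.5/sqrt(22.5) via average ranks
  vals2 <- cbind(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  cr2 <- spearman_matrix(make_am(vals2), "all", include_trait = FALSE)
  expect_equal(cr2$rho["x", "y"], 4.5 / sqrt(22.5), tolerance = 1e-12)
  expect_equal(cr2$rho["x", "y"], oracle_spearman(vals2[, 1], vals2[, 2]),
               tolerance = 1e-12)
})

test_that("spearman_matrix agrees with the rank-then-Pearson oracle on random vectors", {
  withr::local_seed(101)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    repeat {
      x <- sample(1:6, n, replace = TRUE) + 0.5
      y <- sample(1:6, n, replace = TRUE) + 0.5
      if (var(x) > 0 && var(y) > 0) break
    }
    cr <- spearman_matrix(make_am(cbind(a = x, b = y)), "all",
                          include_trait = FALSE)
    expect_equal(cr$rho["a", "b"], oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("correlation results are invariant to sample order and track n_eff", {
  withr::local_seed(5)
  vals <- matrix(rexp(8 * 6), 8, 6)
  vals[1, 2] <- NA; vals[3, 4] <- NA
  am <- make_am(vals, trait = runif(8))
  cr <- spearman_matrix(am, "all")
  perm <- sample(8)
  am2 <- abundance_matrix(am$values[perm, ], am$metadata[perm, ])
  cr2 <- spearman_matrix(am2, "all")
  expect_equal(cr$rho, cr2$rho)
  expect_equal(cr$q, cr2$q)
  expect_equal(cr$n_eff["m01", "m02"], 7)
  # symmetry, unit diagonal, q >= p off-diagonal
  expect_equal(cr$rho, t(cr$rho))
  expect_equal(unname(diag(cr$rho)), rep(1, 7))
  off <- upper.tri(cr$q)
  expect_true(all(cr$q[off] >= cr$p[off] - 1e-15, na.rm = TRUE))
})

test_that("undefined correlations are excluded rather than coerced", {
  vals <- cbind(m1 = c(1, 2, 3, 4, 5), m2 = rep(2, 5), m3 = c(2, 1, 4, 3, 5))
  cr <- spearman_matrix(make_am(vals), "all", include_trait = FALSE)
  expect_true(is.na(cr$rho["m1", "m2"]))
  expect_true(is.na(cr$q["m1", "m2"]))
  net <- build_network(cr, threshold = 0, fdr = 1)
  expect_false("m2" %in% c(net$edges$u, net$edges$v))
})

test_that("spearman_matrix enforces its preconditions", {
  vals <- matrix(runif(6), 3, 2)
  expect_error(spearman_matrix(make_am(vals), "all"), "at least 4")
  vals2 <- matrix(runif(10), 5, 2)
  expect_error(spearman_matrix(make_am(vals2), "nope"), "not present")
  expect_error(spearman_matrix(make_am(vals2), "all", include_trait = TRUE),
               "trait")
})

test_that("bh_fdr matches the hand step-up formula and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  withr::local_seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "within")
  expect_error(bh_fdr(c(0.5, NA)), "finite")
})

test_that("build_network applies the strict |rho| and FDR rule", {
  cr <- corr_fixture(c("m1", "m2", "m3"),
                     c("m1:m2" = 0.9, "m1:m3" = 0.5, "m2:m3" = 0.7),
                     c("m1:m2" = 0.01, "m1:m3" = 0.01, "m2:m3" = 0.2))
  net <- build_network(cr)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$u, "m1")
  expect_equal(net$edges$v, "m2")
  expect_equal(net$edges$sign, "pos")

  # boundary: rho exactly at the threshold is not an edge
  cr2 <- corr_fixture("m1", numeric(), numeric())
  cr2 <- corr_fixture(c("m1", "m2"), c("m1:m2" = 0.6), c("m1:m2" = 0.01))
  expect_equal(nrow(build_network(cr2)$edges), 0L)
  # nor is q exactly at the FDR level
  cr3 <- corr_fixture(c("m1", "m2"), c("m1:m2" = 0.9), c("m1:m2" = 0.05))
  expect_equal(nrow(build_network(cr3)$edges), 0L)

  expect_error(build_network(cr, threshold = 1), "threshold")
})

test_that("edge count is monotone in threshold and FDR level", {
  am <- generate_dataset(benchmark_spec(seed = 9))
  cr <- spearman_matrix(am, "control")
  counts_thr <- vapply(c(0, 0.3, 0.6, 0.9),
                       function(th) nrow(build_network(cr, th, 0.05)$edges),
                       numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_fdr <- vapply(c(0.2, 0.05, 0.01, 0.001),
                       function(f) nrow(build_network(cr, 0.6, f)$edges),
                       numeric(1))
  expect_true(all(diff(counts_fdr) <= 0))
})

test_that("a noiseless one-block dataset recovers exactly the planted plus trait edges", {
  spec <- synthetic_spec(
    n_samples_per_condition = 10, n_metabolites = 4,
    blocks = list(B = list(members = c("m001", "m002", "m003"),
                           loading = 1)),
    trait_block = "B", noise_sd = 0,
    treatment_disrupted_blocks = character(), seed = 2)
  am <- generate_dataset(spec)
  net <- build_network(spearman_matrix(am, "control"))
  tt <- truth_table(spec)
  expected <- c(edge_keys(tt$edges$control$u, tt$edges$control$v),
                edge_keys(rep("trait", 3), c("m001", "m002", "m003")))
  expect_setequal(edge_keys(net$edges$u, net$edges$v), expected)
})

test_that("compare_networks partitions edges and spots sign reversals", {
  mk <- function(u, v, rho, cond = "c", thr = 0.6, fdr = 0.05)
    structure(list(condition = cond, nodes = unique(c(u, v)),
                   edges = data.frame(u = u, v = v, rho = rho,
                                      q = 0.01,
                                      sign = ifelse(rho >= 0, "pos", "neg"),
                                      stringsAsFactors = FALSE),
                   threshold = thr, fdr = fdr),
              class = "connectivity_network")
  A <- mk(c("a", "b"), c("b", "c"), c(0.9, 0.8))
  B <- mk(c("b", "c"), c("c", "d"), c(-0.7, 0.9))
  cmp <- compare_networks(A, B)
  expect_equal(unname(cmp$counts["shared"]), 1)
  expect_equal(cmp$shared$u, "b")
  expect_equal(edge_keys(cmp$a_specific$u, cmp$a_specific$v), "a|b")
  expect_equal(edge_keys(cmp$b_specific$u, cmp$b_specific$v), "c|d")
  expect_equal(nrow(cmp$sign_reversals), 1L)

  same <- compare_networks(A, A)
  expect_equal(unname(same$counts[c("a_specific", "b_specific")]), c(0, 0))

  expect_warning(compare_networks(A, mk("a", "b", 0.9, thr = 0.5)),
                 "different threshold")
})

test_that("differential selection applies the fold and significance screen", {
  withr::local_seed(8)
  a <- matrix(rlnorm(5 * 3), 5, 3)
  b <- a
  b[, 2] <- b[, 2] * 4           # 4-fold up in A relative to B? scaled in B
  vals <- rbind(a, b)
  rownames(vals) <- sprintf("s%02d", 1:10)
  colnames(vals) <- c("same", "up", "other")
  am <- abundance_matrix(vals, data.frame(
    sample_id = rownames(vals),
    condition = rep(c("A", "B"), each = 5)))
  res <- select_differential(am, "A", "B", fold = 2, alpha = 0.05)
  expect_false(res$selected[res$metabolite == "same"])
  expect_equal(res$fold_change[res$metabolite == "same"], 1)

  # constant groups with different means: fold forced by the rule
  vals2 <- cbind(flat = rep(c(8, 2), each = 4))
  rownames(vals2) <- sprintf("s%d", 1:8)
  am2 <- abundance_matrix(vals2, data.frame(
    sample_id = rownames(vals2), condition = rep(c("A", "B"), each = 4)))
  res2 <- select_differential(am2, "A", "B")
  expect_true(res2$selected)
  expect_equal(res2$fold_change, 4)
})

test_that("differential selection is calibrated on null data", {
  withr::local_seed(77)
  rates <- replicate(20, {
    vals <- matrix(rlnorm(12 * 100), 12, 100,
                   dimnames = list(sprintf("s%02d", 1:12),
                                   sprintf("m%03d", 1:100)))
    am <- abundance_matrix(vals, data.frame(
      sample_id = rownames(vals), condition = rep(c("A", "B"), each = 6)))
    mean(select_differential(am, "A", "B")$selected)
  })
  expect_lte(mean(rates), 0.05)
})
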