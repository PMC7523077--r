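#' Spearman correlation matrix over metabolites and the phenotype trait
#'
#' Computes the connectivity matrix of one condition: Spearman's rho
#' between every pair of metabolites, and — when `include_trait` is set —
#' between each metabolite and the phenotype trait (tumor volume or cell
#' number), which enters the matrix as an ordinary node named `"trait"`.
#'
#' Ties receive average ranks; missing values are handled
#' pairwise-complete. Two-sided p-values come from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom (exact
#' permutation p-values are available for small samples via
#' `p_method = "exact"`, n <= 9 without ties). Pairs with fewer than 4
#' complete observations, or where either vector is constant, have rho
#' marked undefined (NA) and are excluded from FDR adjustment. q-values are
#' Benjamini-Hochberg over the strict upper triangle of the p matrix, trait
#' pairs included.
#'
#' @param data an [abundance_matrix()].
#' @param condition condition label to analyze.
#' @param include_trait add the metadata `trait` as a node.
#' @param p_method `"approx"` (t approximation, default) or `"exact"`
#'   (permutation-exact via [stats::cor.test()] where available).
#' @return An object of class `correlation_result` with elements `nodes`,
#'   `rho`, `p`, `q`, `n_eff` (all matrices share the node order),
#'   `condition` and `n_samples`.
#' @export
spearman_matrix <- function(data, condition, include_trait = TRUE,
                            p_method = c("approx", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(data, "abundance_matrix"))
  sub <- subset_condition(data, condition)
  n <- nrow(sub$values)
  if (n < 4)
    mc_stop("condition '", condition, "' has ", n,
            " samples; at least 4 are required")
  M <- sub$values
  if (include_trait) {
    if (!"trait" %in% names(sub$metadata) || all(is.na(sub$metadata$trait)))
      mc_stop("include_trait = TRUE but metadata has no trait values")
    M <- cbind(M, trait = sub$metadata$trait)
  }
  nodes <- colnames(M)
  m <- length(nodes)

  n_eff <- crossprod(!is.na(M))
  rho <- suppressWarnings(
    stats::cor(M, method = "spearman", use = "pairwise.complete.obs"))
  # constant vectors give NaN; too few complete pairs are undefined as well
  rho[!is.finite(rho)] <- NA_real_
  rho[n_eff < 4] <- NA_real_
  diag(rho) <- 1

  p <- spearman_p_approx(rho, n_eff)
  if (p_method == "exact") {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      ok <- stats::complete.cases(M[, i], M[, j])
      if (sum(ok) >= 4 && sum(ok) <= 9 && !is.na(rho[i, j])) {
        pv <- suppressWarnings(
          stats::cor.test(M[ok, i], M[ok, j], method = "spearman",
                          exact = TRUE)$p.value)
        p[i, j] <- p[j, i] <- pv
      }
    }
  }

  q <- matrix(NA_real_, m, m, dimnames = dimnames(p))
  ut <- upper.tri(p)
  keep <- ut & !is.na(p)
  q[keep] <- bh_fdr(p[keep])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(p) <- 0
  diag(q) <- 0

  structure(list(nodes = nodes, rho = rho, p = p, q = q, n_eff = n_eff,
                 condition = condition, n_samples = n,
                 trait_node = if (include_trait) "trait" else NULL),
            class = "correlation_result")
}

# two-sided p from the t approximation; rho = +/-1 maps to p = 0
spearman_p_approx <- function(rho, n_eff) {
  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  df <- n_eff - 2
  ok <- !is.na(rho) & df >= 2
  sat <- ok & abs(rho) >= 1
  p[sat] <- 0
  mid <- ok & !sat
  tt <- rho[mid] * sqrt(df[mid] / (1 - rho[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tt), df[mid])
  p
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation_result:", length(x$nodes), "nodes, condition '",
      x$condition, "', n =", x$n_samples, "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' order statistic is `min over j >= i of m * p_(j) / j`, capped at 1.
#' Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p finite p-values in \[0,1\].
#' @return q-values, same order as `p`, with `q >= p` elementwise.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) mc_stop("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    mc_stop("p-values must be finite and within [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Build a signed connectivity network from a correlation matrix
#'
#' A link joins two nodes when the absolute Spearman correlation of their
#' abundance profiles exceeds the threshold (strictly) and the association
#' is significant at the chosen FDR level (strictly, `q < fdr`). Edge sign
#' is the sign of rho. Pairs with undefined rho never form edges. The
#' network records the threshold and FDR level it was built with.
#'
#' @param corr a `correlation_result`.
#' @param threshold absolute-correlation cutoff in \[0,1) (default 0.6).
#' @param fdr FDR level (default 0.05).
#' @return An object of class `connectivity_network`: `condition`, `nodes`,
#'   `edges` (data frame `u`,`v`,`rho`,`q`,`sign`), `threshold`, `fdr`.
#' @export
build_network <- function(corr, threshold = 0.6, fdr = 0.05) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    mc_stop("threshold must lie in [0, 1)")
  rho <- corr$rho; q <- corr$q
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[upper.tri(rho)]
  qq <- q[upper.tri(q)]
  pass <- !is.na(r) & !is.na(qq) & abs(r) > threshold & qq < fdr
  edges <- data.frame(
    u = corr$nodes[ut[pass, 1]],
    v = corr$nodes[ut[pass, 2]],
    rho = r[pass],
    q = qq[pass],
    sign = ifelse(r[pass] >= 0, "pos", "neg"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(condition = corr$condition, nodes = corr$nodes,
                 edges = edges, threshold = threshold, fdr = fdr),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat("connectivity_network '", x$condition, "': ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges (|rho| > ", x$threshold,
      ", FDR < ", x$fdr, ")\n", sep = "")
  invisible(x)
}

#' Contrast two connectivity networks
#'
#' Matches edges by unordered node pair and splits them into shared and
#' condition-specific sets — the operation behind "keep only the
#' connections not shared between the two tissues" differential-network
#' figures. Shared pairs whose correlation signs differ between the two
#' networks are listed as sign reversals.
#'
#' @param a,b `connectivity_network` objects. If they were built with
#'   different threshold/FDR settings a warning is raised and recorded in
#'   the result.
#' @return List with data frames `shared`, `a_specific`, `b_specific`,
#'   `sign_reversals`, a `counts` vector, and `settings_match`.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "connectivity_network"),
            inherits(b, "connectivity_network"))
  settings_match <- isTRUE(a$threshold == b$threshold && a$fdr == b$fdr)
  if (!settings_match)
    mc_warn("networks were built with different threshold/FDR settings")
  ka <- pair_key(a$edges$u, a$edges$v)
  kb <- pair_key(b$edges$u, b$edges$v)
  shared_keys <- intersect(ka, kb)
  ea <- a$edges[match(shared_keys, ka), , drop = FALSE]
  eb <- b$edges[match(shared_keys, kb), , drop = FALSE]
  shared <- data.frame(u = pmin(ea$u, ea$v), v = pmax(ea$u, ea$v),
                       rho_a = ea$rho, rho_b = eb$rho,
                       sign_a = ea$sign, sign_b = eb$sign,
                       stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  a_specific <- a$edges[!ka %in% shared_keys, , drop = FALSE]
  b_specific <- b$edges[!kb %in% shared_keys, , drop = FALSE]
  rownames(a_specific) <- rownames(b_specific) <- NULL
  sign_reversals <- shared[shared$sign_a != shared$sign_b, , drop = FALSE]
  rownames(sign_reversals) <- NULL
  list(shared = shared, a_specific = a_specific, b_specific = b_specific,
       sign_reversals = sign_reversals,
       counts = c(shared = nrow(shared), a_specific = nrow(a_specific),
                  b_specific = nrow(b_specific),
                  sign_reversals = nrow(sign_reversals)),
       settings_match = settings_match)
}

#' Select differentially abundant metabolites between two groups
#'
#' Two-sided two-sample t-test on log-transformed abundances; a metabolite
#' is kept when its fold change (ratio of group geometric means, in either
#' direction) is at least `fold` and the p-value is at most `alpha` — the
#' "at least 2-fold and statistically significant" screen.
#'
#' Zero abundances are offset by the smallest positive value in the table
#' before the log transform (logged). Metabolites constant in both groups
#' get p = 1 when equal and p = 0 when the two constants differ.
#'
#' @param data an [abundance_matrix()].
#' @param group_a,group_b condition labels to compare (fold change is
#'   reported as A over B).
#' @param fold minimum fold change (default 2).
#' @param alpha significance cutoff (default 0.05).
#' @return Data frame `metabolite`, `fold_change` (geometric-mean ratio
#'   A/B), `log2_fc`, `p`, `selected`, ordered by p.
#' @export
select_differential <- function(data, group_a, group_b, fold = 2,
                                alpha = 0.05) {
  stopifnot(inherits(data, "abundance_matrix"), fold >= 1)
  A <- subset_condition(data, group_a)$values
  B <- subset_condition(data, group_b)$values
  if (nrow(A) < 3 || nrow(B) < 3)
    mc_stop("need at least 3 samples per group")
  vals <- rbind(A, B)
  if (any(vals <= 0, na.rm = TRUE)) {
    offset <- min(vals[vals > 0], na.rm = TRUE)
    mc_log("non-positive abundances offset by ", signif(offset, 3),
           " before log transform")
    A <- A + offset; B <- B + offset
  }
  lA <- log(A); lB <- log(B)
  res <- lapply(colnames(A), function(mt) {
    x <- lA[, mt]; y <- lB[, mt]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    dm <- mean(x) - mean(y)
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
      stats::t.test(x, y)$p.value
    }
    data.frame(metabolite = mt, fold_change = exp(dm),
               log2_fc = dm / log(2), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$selected <- pmax(out$fold_change, 1 / out$fold_change) >= fold &
    out$p <= alpha
  out <- out[order(out$p, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}
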