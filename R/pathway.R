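#' Pathway eigenmetabolite
#'
#' Condenses a pathway into one representative profile: the first principal
#' component of the z-scored abundance profiles of its member metabolites
#' (the metabolite analogue of a WGCNA eigengene). Standardizing the
#' members first makes the summary invariant to the arbitrary per-
#' metabolite scale of relative MS abundances.
#'
#' The eigenvector sign is fixed so the mean correlation between the
#' eigenmetabolite and its members is non-negative; an exact tie (mean 0)
#' is resolved toward a positive loading on the lexicographically first
#' member, so results are reproducible across runs and platforms.
#'
#' @param data an [abundance_matrix()].
#' @param condition condition label.
#' @param members metabolite ids belonging to the pathway. Members missing
#'   from the data, or with zero variance, are dropped with a warning; a
#'   pathway with no usable member returns `NULL` with a warning.
#' @param pathway name carried in the result.
#' @return Object of class `eigenmetabolite`: `pathway`, `members` (those
#'   used), `loading` (unit Euclidean norm), `scores` (per sample),
#'   `variance_explained` (top eigenvalue over trace of the member
#'   correlation matrix), `condition`; or `NULL`.
#' @export
compute_eigenmetabolite <- function(data, condition, members,
                                    pathway = "pathway") {
  stopifnot(inherits(data, "abundance_matrix"))
  sub <- subset_condition(data, condition)
  if (nrow(sub$values) < 3) mc_stop("need at least 3 samples")
  present <- intersect(members, colnames(sub$values))
  if (length(present) < length(members))
    mc_warn("pathway '", pathway, "': ",
            length(members) - length(present),
            " member(s) absent from the data, dropped")
  if (!length(present)) {
    mc_warn("pathway '", pathway, "' has no matched metabolites; skipped")
    return(NULL)
  }
  X <- sub$values[, present, drop = FALSE]
  complete <- stats::complete.cases(X)
  if (!all(complete)) {
    mc_log("pathway '", pathway, "': ", sum(!complete),
           " sample(s) with missing members dropped")
    X <- X[complete, , drop = FALSE]
  }
  if (nrow(X) < 3) mc_stop("fewer than 3 complete samples for '", pathway, "'")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    mc_warn("pathway '", pathway, "': zero-variance member(s) dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!ncol(X)) {
    mc_warn("pathway '", pathway, "' has no variable member; skipped")
    return(NULL)
  }
  Z <- scale(X)
  sv <- svd(Z)
  loading <- sv$v[, 1]
  names(loading) <- colnames(X)
  scores <- drop(Z %*% loading)
  ve <- sv$d[1]^2 / sum(sv$d^2)

  memb_cor <- suppressWarnings(stats::cor(scores, Z))
  mean_cor <- mean(memb_cor, na.rm = TRUE)
  flip <- if (abs(mean_cor) > 1e-12) {
    mean_cor < 0
  } else {
    first <- sort(colnames(X))[1]
    loading[first] < 0
  }
  if (flip) {
    loading <- -loading
    scores <- -scores
  }
  names(scores) <- rownames(sub$values)[complete]
  structure(list(pathway = pathway, members = colnames(X),
                 loading = loading, scores = scores,
                 variance_explained = ve, condition = condition),
            class = "eigenmetabolite")
}

#' @export
print.eigenmetabolite <- function(x, ...) {
  cat(sprintf("eigenmetabolite '%s' (%s): %d members, %.1f%% variance\n",
              x$pathway, x$condition, length(x$members),
              100 * x$variance_explained))
  invisible(x)
}

#' Eigenmetabolites for every pathway of a map
#'
#' @param data an [abundance_matrix()].
#' @param condition condition label.
#' @param members_by_pathway named list pathway -> member metabolite ids
#'   (see [pathway_members()]).
#' @return Named list of `eigenmetabolite` objects (skipped pathways
#'   omitted).
#' @export
pathway_eigenmetabolites <- function(data, condition, members_by_pathway) {
  out <- lapply(names(members_by_pathway), function(pw)
    compute_eigenmetabolite(data, condition, members_by_pathway[[pw]], pw))
  names(out) <- names(members_by_pathway)
  out[!vapply(out, is.null, logical(1))]
}

#' Pathway-pathway connectivity for one condition
#'
#' Correlates every pair of pathway eigenmetabolites (Spearman by default,
#' Pearson by flag), producing the pathway-level connectivity matrix the
#' condition-contrast heatmaps are drawn from. Matrices are unthresholded:
#' the |rho| > 0.6 / FDR edge rule applies only to metabolite-level
#' networks.
#'
#' @param profiles list of `eigenmetabolite` objects computed on the same
#'   samples (an error otherwise).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param pathway_order optional explicit row/column order.
#' @return Object of class `pathway_connectivity`: `pathways`, `rho`
#'   (symmetric, unit diagonal), `variance_explained`, `condition`,
#'   `method`.
#' @export
pathway_correlation <- function(profiles, method = c("spearman", "pearson"),
                                pathway_order = NULL) {
  method <- match.arg(method)
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  if (length(profiles) < 2) mc_stop("need at least 2 pathway profiles")
  samp <- lapply(profiles, function(p) names(p$scores))
  if (!all(vapply(samp, identical, logical(1), samp[[1]])))
    mc_stop("eigenmetabolite profiles cover different sample sets")
  pw <- vapply(profiles, `[[`, character(1), "pathway")
  S <- do.call(cbind, lapply(profiles, `[[`, "scores"))
  colnames(S) <- pw
  if (!is.null(pathway_order)) {
    if (!setequal(pathway_order, pw))
      mc_stop("pathway_order must be a permutation of the profile pathways")
    S <- S[, pathway_order, drop = FALSE]
    pw <- pathway_order
  }
  rho <- stats::cor(S, method = method)
  diag(rho) <- 1
  structure(list(pathways = pw, rho = rho,
                 variance_explained =
                   vapply(profiles, `[[`, numeric(1),
                          "variance_explained")[match(pw, vapply(profiles, `[[`, character(1), "pathway"))],
                 condition = profiles[[1]]$condition, method = method),
            class = "pathway_connectivity")
}

#' @export
print.pathway_connectivity <- function(x, ...) {
  cat("pathway_connectivity (", x$condition, "): ", length(x$pathways),
      " pathways, ", x$method, " correlation\n", sep = "")
  invisible(x)
}

#' Contrast pathway connectivity between control and treated conditions
#'
#' For each focus pathway, summarizes how treatment rewires its
#' correlations with every other pathway: the number of pairs whose
#' correlation sign reverses (color reversal in a heatmap) and the mean
#' decrease in |rho| (loss of shade intensity). A pathway is flagged
#' "disrupted" when, averaged over the partner pathways it was connected
#' to in the control condition (|rho| > `baseline`), its |rho| drops by
#' more than `drop_cutoff` — i.e., treatment dismantles connectivity that
#' was actually there, rather than shuffling near-zero correlations.
#'
#' @param control,treated `pathway_connectivity` objects. Pathways present
#'   in only one condition are excluded with a log message.
#' @param focus pathways to summarize (default: all shared).
#' @param baseline control |rho| above which a pathway pair counts as
#'   connected (default 0.6, the metabolite-level edge threshold).
#' @param drop_cutoff mean |rho| drop over connected pairs beyond which a
#'   pathway is flagged disrupted (default 0.3).
#' @return Data frame: `pathway`, `n_pairs`, `n_sign_reversals`,
#'   `mean_abs_rho_control`, `mean_abs_rho_treated`, `mean_delta_abs_rho`
#'   (over all pairs), `n_connected_control`, `mean_drop_connected`,
#'   `disrupted`.
#' @export
condition_contrast <- function(control, treated, focus = NULL,
                               baseline = 0.6, drop_cutoff = 0.3) {
  stopifnot(inherits(control, "pathway_connectivity"),
            inherits(treated, "pathway_connectivity"))
  common <- intersect(control$pathways, treated$pathways)
  dropped <- setdiff(union(control$pathways, treated$pathways), common)
  if (length(dropped))
    mc_log("pathways present in only one condition excluded: ",
           paste(dropped, collapse = ", "))
  if (length(common) < 2) mc_stop("fewer than 2 shared pathways")
  rc <- control$rho[common, common]
  rt <- treated$rho[common, common]
  focus <- focus %||% common
  bad <- setdiff(focus, common)
  if (length(bad))
    mc_stop("focus pathways not shared by both conditions: ",
            paste(bad, collapse = ", "))
  rows <- lapply(focus, function(pw) {
    others <- setdiff(common, pw)
    c0 <- rc[pw, others]; c1 <- rt[pw, others]
    delta <- abs(c0) - abs(c1)
    connected <- abs(c0) > baseline
    mean_drop_conn <- if (any(connected)) mean(delta[connected]) else NA_real_
    data.frame(
      pathway = pw,
      n_pairs = length(others),
      n_sign_reversals = sum(sign(c0) != sign(c1) & c0 != 0 & c1 != 0),
      mean_abs_rho_control = mean(abs(c0)),
      mean_abs_rho_treated = mean(abs(c1)),
      mean_delta_abs_rho = mean(delta),
      n_connected_control = sum(connected),
      mean_drop_connected = mean_drop_conn,
      disrupted = isTRUE(mean_drop_conn > drop_cutoff),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
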