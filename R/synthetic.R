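#' Specify a synthetic metabolomics dataset with planted correlation blocks
#'
#' The generator emulates the statistical structure a connectivity analysis
#' assumes in a two-condition (control vs. drug-treated) metabolomics study:
#' groups of metabolites driven by a shared latent factor (planted
#' correlation blocks), a phenotype trait (tumor volume or cell number)
#' coupled to one block, and a treatment perturbation that removes the
#' latent coupling of chosen blocks and/or flips the loading sign of chosen
#' members.
#'
#' On the log scale each block member is
#' \code{sign * loading * factor + noise_sd * eps}, with the latent factor
#' and the noise standard normal per sample; metabolites not assigned to any
#' block are pure standard normal noise. Values are exponentiated before
#' output so abundances are positive and log-normal like relative MS
#' abundances (Spearman statistics are rank-invariant to this). Under the
#' treated condition, blocks listed in \code{treatment_disrupted_blocks}
#' have their loading set to 0 and members listed in
#' \code{treatment_sign_flips} have their loading sign reversed.
#'
#' The default scale mirrors a small xenograft metabolomics study: two
#' conditions with 8 samples each, 100 metabolites of which 4 blocks of 8
#' are coordinately regulated, the trait driven by the first block, and the
#' treatment disrupting that same (trait-linked) block.
#'
#' @param n_samples_per_condition samples per condition (positive integer).
#' @param n_metabolites total number of metabolites (positive integer).
#' @param blocks named list; each element is a list with `members`
#'   (character vector of metabolite ids), `loading` (in \[0,1\]) and
#'   optionally `signs` (+1/-1 per member, default all +1).
#' @param trait_block name of the block whose latent factor drives the
#'   trait, or `NULL` for a pure-noise trait.
#' @param noise_sd standard deviation of the member-level noise (>= 0).
#' @param treatment_disrupted_blocks block names whose latent coupling is
#'   removed under the "treated" condition.
#' @param treatment_sign_flips character vector of metabolite ids (block
#'   members) whose loading sign reverses under treatment.
#' @param pathway_assignment named list metabolite id -> character vector of
#'   pathway names. The default maps each block to two 4-member pathways
#'   (coordinated processes typically span more than one KEGG pathway, so
#'   cross-pathway correlation is part of the structure being emulated);
#'   unassigned metabolites go to pathway "unassigned".
#' @param seed integer seed; the same spec and seed reproduce the dataset
#'   byte-identically.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [truth_table()]
#' @export
synthetic_spec <- function(n_samples_per_condition = 8,
                           n_metabolites = 100,
                           blocks = NULL,
                           trait_block = "B1",
                           noise_sd = 0.3,
                           treatment_disrupted_blocks = "B1",
                           treatment_sign_flips = character(),
                           pathway_assignment = NULL,
                           seed = 1L) {
  if (!is_count(n_samples_per_condition))
    mc_stop("n_samples_per_condition must be a positive integer")
  if (!is_count(n_metabolites))
    mc_stop("n_metabolites must be a positive integer")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    mc_stop("noise_sd must be a single non-negative number")

  met_ids <- sprintf("m%03d", seq_len(n_metabolites))

  if (is.null(blocks)) {
    blocks <- default_blocks(met_ids, n_blocks = 4L, block_size = 8L,
                             loading = 0.95)
  }
  blocks <- lapply(blocks, function(b) {
    b$signs <- b$signs %||% rep(1, length(b$members))
    b
  })
  validate_blocks(blocks, met_ids)

  if (!is.null(trait_block) && !trait_block %in% names(blocks))
    mc_stop("trait_block '", trait_block, "' is not a declared block")
  bad <- setdiff(treatment_disrupted_blocks, names(blocks))
  if (length(bad))
    mc_stop("treatment_disrupted_blocks not declared: ",
            paste(bad, collapse = ", "))
  all_members <- unlist(lapply(blocks, `[[`, "members"), use.names = FALSE)
  bad <- setdiff(treatment_sign_flips, all_members)
  if (length(bad))
    mc_stop("treatment_sign_flips must name block members; unknown: ",
            paste(bad, collapse = ", "))

  if (is.null(pathway_assignment))
    pathway_assignment <- default_pathways(blocks, met_ids)

  structure(
    list(n_samples_per_condition = as.integer(n_samples_per_condition),
         n_metabolites = as.integer(n_metabolites),
         metabolite_ids = met_ids,
         blocks = blocks,
         trait_block = trait_block,
         noise_sd = noise_sd,
         treatment_disrupted_blocks = treatment_disrupted_blocks,
         treatment_sign_flips = treatment_sign_flips,
         pathway_assignment = pathway_assignment,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

default_blocks <- function(met_ids, n_blocks, block_size, loading) {
  stopifnot(n_blocks * block_size <= length(met_ids))
  blocks <- list()
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):(b * block_size)
    signs <- rep(1, block_size)
    signs[block_size] <- -1  # one anti-regulated member per block
    blocks[[paste0("B", b)]] <-
      list(members = met_ids[idx], loading = loading, signs = signs)
  }
  blocks
}

# each block is split across two pathways; noise metabolites -> "unassigned"
default_pathways <- function(blocks, met_ids) {
  pw <- list()
  for (bn in names(blocks)) {
    mem <- blocks[[bn]]$members
    half <- ceiling(length(mem) / 2)
    for (i in seq_along(mem)) {
      pw[[mem[i]]] <- paste0(bn, if (i <= half) "_pathA" else "_pathB")
    }
  }
  for (m in setdiff(met_ids, names(pw))) pw[[m]] <- "unassigned"
  pw[met_ids]
}

validate_blocks <- function(blocks, met_ids) {
  if (length(blocks) == 0) return(invisible(TRUE))
  if (is.null(names(blocks)) || any(names(blocks) == "") ||
      anyDuplicated(names(blocks)))
    mc_stop("blocks must be a uniquely named list")
  seen <- character()
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    if (!all(b$members %in% met_ids))
      mc_stop("block '", bn, "' has members outside the metabolite ids")
    overlap <- intersect(b$members, seen)
    if (length(overlap))
      mc_stop("blocks overlap on: ", paste(overlap, collapse = ", "))
    seen <- c(seen, b$members)
    if (!is.numeric(b$loading) || length(b$loading) != 1L ||
        b$loading < 0 || b$loading > 1)
      mc_stop("block '", bn, "' loading must be in [0,1]")
    if (length(b$signs) != length(b$members) || !all(b$signs %in% c(-1, 1)))
      mc_stop("block '", bn, "' signs must be +1/-1, one per member")
  }
  invisible(TRUE)
}

#' Generate a synthetic abundance matrix under both conditions
#'
#' Draws one dataset from the generative model of [synthetic_spec()]: for
#' each of the "control" and "treated" conditions an independent latent
#' factor per block, member abundances as signed loadings on the factor plus
#' Gaussian noise (exponentiated to the abundance scale), and a trait equal
#' to the trait block's latent factor plus noise (pure noise when no trait
#' block is set). Disrupted blocks lose their latent coupling under
#' treatment; sign-flipped members reverse their loading sign.
#'
#' @param spec a `synthetic_spec`.
#' @return An [abundance_matrix()] containing both conditions, with sample
#'   metadata (`sample_id`, `condition`, `trait`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples_per_condition
  withr::with_seed(spec$seed, {
    parts <- lapply(c("control", "treated"), function(cond) {
      X <- matrix(stats::rnorm(n * spec$n_metabolites), nrow = n,
                  dimnames = list(NULL, spec$metabolite_ids))
      trait_latent <- NULL
      for (bn in names(spec$blocks)) {
        b <- spec$blocks[[bn]]
        latent <- stats::rnorm(n)
        if (!is.null(spec$trait_block) && bn == spec$trait_block)
          trait_latent <- latent
        loading <- b$loading
        if (cond == "treated" && bn %in% spec$treatment_disrupted_blocks)
          loading <- 0
        for (i in seq_along(b$members)) {
          s <- b$signs[i]
          if (cond == "treated" && b$members[i] %in% spec$treatment_sign_flips)
            s <- -s
          X[, b$members[i]] <- s * loading * latent +
            spec$noise_sd * stats::rnorm(n)
        }
      }
      trait <- if (is.null(trait_latent)) stats::rnorm(n) else
        trait_latent + spec$noise_sd * stats::rnorm(n)
      list(values = exp(X), trait = exp(trait), condition = cond)
    })
    values <- do.call(rbind, lapply(parts, `[[`, "values"))
    meta <- data.frame(
      sample_id = sprintf("s%02d", seq_len(2L * n)),
      condition = rep(c("control", "treated"), each = n),
      trait = unlist(lapply(parts, `[[`, "trait")),
      stringsAsFactors = FALSE)
    rownames(values) <- meta$sample_id
    abundance_matrix(values, meta)
  })
}

#' Ground truth of the planted structure
#'
#' Returns the edges and modules the generator plants: every within-block
#' metabolite pair is an expected edge, every block an expected module.
#' Blocks listed as treatment-disrupted contribute neither edges nor a
#' module under the treated condition.
#'
#' @param spec a `synthetic_spec`.
#' @return List with `edges` (per condition, a data frame `u`,`v`,`block`)
#'   and `modules` (per condition, named list of member vectors).
#' @export
truth_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  block_edges <- function(active) {
    rows <- lapply(active, function(bn) {
      mem <- sort(spec$blocks[[bn]]$members)
      if (length(mem) < 2) return(NULL)
      cp <- t(combn(mem, 2))
      data.frame(u = cp[, 1], v = cp[, 2], block = bn,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(u = character(), v = character(),
                        block = character(), stringsAsFactors = FALSE)
    out
  }
  active_treated <- setdiff(names(spec$blocks),
                            spec$treatment_disrupted_blocks)
  mods <- function(active)
    lapply(spec$blocks[active], function(b) sort(b$members))
  list(
    edges = list(control = block_edges(names(spec$blocks)),
                 treated = block_edges(active_treated)),
    modules = list(control = mods(names(spec$blocks)),
                   treated = mods(active_treated)))
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Materializes the abundance table, sample metadata, pathway map and the
#' planted ground truth as plain-text files, the on-disk layout the rest of
#' the pipeline reads.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  am <- generate_dataset(spec)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    metadata  = file.path(dir, "metadata.tsv"),
    pathways  = file.path(dir, "pathway_map.tsv"),
    truth     = file.path(dir, "truth.json"))
  write_abundance(am, paths[["abundance"]], paths[["metadata"]])
  write_pathway_map(spec$pathway_assignment, paths[["pathways"]])
  jsonlite::write_json(truth_table(spec), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
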