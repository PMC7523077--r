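#' Configuration for a full connectivity-profiling run
#'
#' @param abundance,metadata,pathway_map input file paths (delimited text;
#'   see [read_abundance()], [read_pathway_map()]). Alternatively pass an
#'   in-memory dataset via `data`.
#' @param data optional [abundance_matrix()]; overrides the file inputs.
#' @param map optional in-memory pathway map (named list).
#' @param conditions condition labels to analyze, in order; with two or
#'   more, the first two are contrasted.
#' @param threshold,fdr edge rule of the metabolite networks.
#' @param mcode an [mcode_params()] object.
#' @param focus_pathways pathways to summarize in the condition contrast
#'   (default: all shared).
#' @param include_trait correlate the phenotype trait alongside the
#'   metabolites.
#' @param out_dir output directory for all artifacts.
#' @param seed integer seed for any resampling options.
#' @return Object of class `run_config`.
#' @export
run_config <- function(abundance = NULL, metadata = NULL,
                       pathway_map = NULL, data = NULL, map = NULL,
                       conditions, threshold = 0.6, fdr = 0.05,
                       mcode = mcode_params(), focus_pathways = NULL,
                       include_trait = TRUE, out_dir, seed = 1L) {
  if (is.null(data) && (is.null(abundance) || is.null(metadata)))
    mc_stop("provide either `data` or both `abundance` and `metadata` paths")
  if (!length(conditions)) mc_stop("at least one condition is required")
  structure(list(abundance = abundance, metadata = metadata,
                 pathway_map = pathway_map, data = data, map = map,
                 conditions = conditions, threshold = threshold, fdr = fdr,
                 mcode = mcode, focus_pathways = focus_pathways,
                 include_trait = isTRUE(include_trait),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full metabolic connectivity-profiling workflow
#'
#' Per condition: Spearman correlation matrix (metabolites + trait),
#' signed thresholded network, ranked MCODE modules, pathway
#' eigenmetabolites and pathway-pathway connectivity. Across the first two
#' conditions: shared/specific edges, sign reversals, disrupted-pathway
#' flags, and trait-neighbor changes (which metabolites gain, lose, or
#' flip the sign of their edge with the trait — the generic form of a
#' glucose-vs-tumor-volume polarity inversion).
#'
#' Every stage's output is materialized under `out_dir` so each summary
#' number can be audited against the table it came from, plus a
#' machine-readable `summary.json` and a `run.log` recording parameters
#' and package version. Reruns with identical inputs and config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, the report bundle (a list with one element per
#'   stage).
#' @export
run_profiling <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("metconnect run",
                 paste0("package version: ",
                        as.character(utils::packageVersion("metconnect"))),
                 paste0("threshold: ", config$threshold),
                 paste0("fdr: ", config$fdr),
                 paste0("conditions: ", paste(config$conditions,
                                              collapse = ", ")),
                 paste0("seed: ", config$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      mc_stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  data <- stage("load_abundance",
                config$data %||% read_abundance(config$abundance,
                                                meta = config$metadata))
  map <- stage("load_pathway_map", {
    if (!is.null(config$map)) config$map
    else if (!is.null(config$pathway_map)) read_pathway_map(config$pathway_map)
    else NULL
  })
  members <- if (!is.null(map))
    stage("pathway_members",
          suppressWarnings(pathway_members(map, colnames(data$values))))

  per_condition <- list()
  for (cond in config$conditions) {
    res <- list()
    res$correlation <- stage(paste0("spearman[", cond, "]"),
                             spearman_matrix(data, cond,
                                             include_trait = config$include_trait))
    res$network <- stage(paste0("network[", cond, "]"),
                         build_network(res$correlation, config$threshold,
                                       config$fdr))
    res$modules <- stage(paste0("mcode[", cond, "]"),
                         find_modules(res$network, config$mcode))
    if (!is.null(members)) {
      res$eigenmetabolites <- stage(paste0("eigenmetabolites[", cond, "]"),
                                    suppressWarnings(
                                      pathway_eigenmetabolites(data, cond, members)))
      res$pathway_connectivity <-
        if (length(res$eigenmetabolites) >= 2)
          stage(paste0("pathway_correlation[", cond, "]"),
                pathway_correlation(res$eigenmetabolites))
    }
    write_network(res$network,
                  file.path(config$out_dir,
                            paste0("network_", cond, ".tsv")), "tsv")
    utils::write.table(modules_table(res$modules),
                       file.path(config$out_dir,
                                 paste0("modules_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$pathway_connectivity))
      utils::write.table(
        format(res$pathway_connectivity$rho, digits = 15, trim = TRUE),
        file.path(config$out_dir, paste0("pathway_rho_", cond, ".tsv")),
        sep = "\t", quote = FALSE)
    per_condition[[cond]] <- res
  }

  cross <- NULL
  if (length(config$conditions) >= 2) {
    c1 <- config$conditions[1]; c2 <- config$conditions[2]
    cross <- list()
    cross$edges <- stage("compare_networks",
                         compare_networks(per_condition[[c1]]$network,
                                          per_condition[[c2]]$network))
    pc1 <- per_condition[[c1]]$pathway_connectivity
    pc2 <- per_condition[[c2]]$pathway_connectivity
    if (!is.null(pc1) && !is.null(pc2))
      cross$pathways <- stage("condition_contrast",
                              condition_contrast(pc1, pc2,
                                                 focus = config$focus_pathways))
    if (config$include_trait)
      cross$trait <- trait_neighbor_changes(per_condition[[c1]]$network,
                                            per_condition[[c2]]$network)
    if (!is.null(cross$pathways))
      utils::write.table(cross$pathways,
                         file.path(config$out_dir, "pathway_contrast.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- build_summary(config, per_condition, cross)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(data = data, per_condition = per_condition, cross = cross,
                 summary = summary, config = config))
}

# which metabolites gain/lose/flip their edge with the trait node
trait_neighbor_changes <- function(net_a, net_b) {
  trait_edges <- function(net) {
    e <- net$edges
    keep <- e$u == "trait" | e$v == "trait"
    e <- e[keep, , drop = FALSE]
    data.frame(metabolite = ifelse(e$u == "trait", e$v, e$u),
               rho = e$rho, sign = e$sign, stringsAsFactors = FALSE)
  }
  ta <- trait_edges(net_a); tb <- trait_edges(net_b)
  both <- intersect(ta$metabolite, tb$metabolite)
  flips <- both[ta$sign[match(both, ta$metabolite)] !=
                  tb$sign[match(both, tb$metabolite)]]
  list(a_neighbors = ta, b_neighbors = tb,
       lost = sort(setdiff(ta$metabolite, tb$metabolite)),
       gained = sort(setdiff(tb$metabolite, ta$metabolite)),
       sign_flips = sort(flips))
}

build_summary <- function(config, per_condition, cross) {
  s <- list(
    parameters = list(threshold = config$threshold, fdr = config$fdr,
                      conditions = config$conditions,
                      include_trait = config$include_trait,
                      seed = config$seed),
    conditions = lapply(per_condition, function(res) {
      out <- list(n_samples = res$correlation$n_samples,
                  n_nodes = length(res$network$nodes),
                  n_edges = nrow(res$network$edges),
                  n_modules = length(res$modules),
                  top_module_score =
                    if (length(res$modules)) res$modules[[1]]$score else NULL)
      if (!is.null(res$pathway_connectivity))
        out$n_pathways <- length(res$pathway_connectivity$pathways)
      out
    }))
  if (!is.null(cross)) {
    s$contrast <- list(edge_counts = as.list(cross$edges$counts))
    if (!is.null(cross$pathways))
      s$contrast$disrupted_pathways <-
        cross$pathways$pathway[cross$pathways$disrupted]
    if (!is.null(cross$trait))
      s$contrast$trait <- list(lost = cross$trait$lost,
                               gained = cross$trait$gained,
                               sign_flips = cross$trait$sign_flips)
  }
  s
}
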