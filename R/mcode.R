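#' MCODE parameters
#'
#' Parameter set of the Molecular Complex Detection algorithm. Defaults
#' match the common Cytoscape-plugin configuration used for correlation
#' networks: degree cutoff 2, node score cutoff 0.2, k-core 2, max depth
#' 100, haircut on, fluff off.
#'
#' `degree_cutoff` is the minimum degree for a vertex to be scored at all;
#' `node_score_cutoff` controls expansion (a neighbor joins when its weight
#' is within that fraction of the seed's weight); `k_core` discards modules
#' that contain no maximally interconnected subgraph of minimum degree k;
#' `max_depth` bounds the search distance from the seed. `haircut` removes
#' singly connected vertices from finished modules; `fluff` adds boundary
#' neighbors whose closed-neighborhood density exceeds `fluff_density`.
#'
#' `density_denominator` selects how module density is normalized:
#' `"module"` (default) divides the module's edge count by the maximal
#' possible edge count n(n-1)/2 of the module subgraph, keeping density in
#' \[0,1\]; `"network"` divides by the whole network's edge count instead,
#' for comparison with that alternative convention.
#'
#' @param degree_cutoff integer >= 1.
#' @param node_score_cutoff real in \[0,1\].
#' @param k_core integer >= 2.
#' @param max_depth integer >= 1.
#' @param haircut,fluff logicals.
#' @param fluff_density density threshold for fluffing.
#' @param density_denominator `"module"` or `"network"`.
#' @return Object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.1,
                         density_denominator = c("module", "network")) {
  density_denominator <- match.arg(density_denominator)
  if (!is_count(degree_cutoff))
    mc_stop("degree_cutoff must be a positive integer")
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    mc_stop("node_score_cutoff must lie in [0,1]")
  if (!is_count(k_core) || k_core < 2) mc_stop("k_core must be >= 2")
  if (!is_count(max_depth)) mc_stop("max_depth must be >= 1")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density,
                 density_denominator = density_denominator),
            class = "mcode_params")
}

# accept a connectivity_network or an igraph; always return a simple
# undirected igraph with named vertices
as_mcode_graph <- function(graph) {
  if (inherits(graph, "connectivity_network")) {
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("u", "v"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = graph$nodes))
  } else if (igraph::is_igraph(graph)) {
    g <- igraph::as_undirected(graph, mode = "collapse")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  } else {
    mc_stop("graph must be a connectivity_network or an igraph object")
  }
  igraph::simplify(g)
}

# density of the highest k-core of the closed neighborhood, times its k
core_clustering_weight <- function(g, v, degree_cutoff) {
  deg <- igraph::degree(g, v)
  if (deg < degree_cutoff) return(0)
  nb <- c(v, as.integer(igraph::neighbors(g, v)))
  sub <- igraph::induced_subgraph(g, nb)
  cores <- igraph::coreness(sub)
  kmax <- max(cores)
  if (kmax == 0) return(0)
  core_sub <- igraph::induced_subgraph(sub, which(cores == kmax))
  kmax * igraph::edge_density(core_sub)
}

#' MCODE vertex weights
#'
#' Scores every vertex by the core-clustering coefficient: the density of
#' the highest k-core of the vertex's closed neighborhood, multiplied by
#' that core's k. This favors vertices sitting inside densely
#' interconnected regions while being less sensitive than the plain
#' clustering coefficient to single spurious edges. Vertices with degree
#' below `degree_cutoff` (and isolated vertices) get weight 0.
#'
#' @param graph a `connectivity_network` or an undirected igraph.
#' @param degree_cutoff minimum degree to be scored.
#' @return Named numeric vector of weights.
#' @export
vertex_weights <- function(graph, degree_cutoff = 2L) {
  g <- as_mcode_graph(graph)
  w <- vapply(seq_len(igraph::vcount(g)),
              function(v) core_clustering_weight(g, v, degree_cutoff),
              numeric(1))
  names(w) <- igraph::V(g)$name
  w
}

#' Density and score of a candidate module
#'
#' Module density D is the number of edges within the node set divided by
#' the maximal possible number n(n-1)/2; the module score is D times the
#' number of vertices, so larger and denser modules score higher.
#'
#' @param nodes character vector of at least 2 vertex names.
#' @param graph a `connectivity_network` or an undirected igraph.
#' @param density_denominator see [mcode_params()].
#' @return List with `density` and `score`.
#' @export
module_score <- function(nodes, graph,
                         density_denominator = c("module", "network")) {
  density_denominator <- match.arg(density_denominator)
  g <- as_mcode_graph(graph)
  if (length(nodes) < 2) mc_stop("a module needs at least 2 vertices")
  if (!all(nodes %in% igraph::V(g)$name))
    mc_stop("module nodes absent from graph: ",
            paste(setdiff(nodes, igraph::V(g)$name), collapse = ", "))
  sub <- igraph::induced_subgraph(g, nodes)
  n <- length(nodes)
  denom <- if (density_denominator == "module") n * (n - 1) / 2 else
    igraph::ecount(g)
  D <- igraph::ecount(sub) / denom
  list(density = D, score = D * n)
}

#' Find locally dense modules with the MCODE algorithm
#'
#' Three stages. (1) Vertex weighting by [vertex_weights()]. (2) Seeded
#' greedy expansion: the highest-weight unvisited vertex seeds a module and
#' the search moves outward breadth-first, admitting a neighbor whose
#' weight is at least `seed_weight * (1 - node_score_cutoff)`, never deeper
#' than `max_depth` from the seed; every vertex belongs to at most one
#' module, and visited vertices cannot seed again. (3) Post-processing:
#' optional haircut (iterated removal of singly connected vertices),
#' optional fluff, and a filter discarding modules without an internal
#' k-core of order `k_core`.
#'
#' Modules are ranked by descending score (density x size), ties broken by
#' larger size and then by lexicographically smallest seed id, which makes
#' the output independent of vertex input order.
#'
#' @param graph a `connectivity_network` or an undirected igraph.
#' @param params an [mcode_params()] object.
#' @return List of modules, each of class `mcode_module` with `nodes`,
#'   `seed`, `density`, `score`, `rank`.
#' @export
find_modules <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  g <- as_mcode_graph(graph)
  nv <- igraph::vcount(g)
  if (nv == 0) return(list())
  vnames <- igraph::V(g)$name
  w <- vapply(seq_len(nv),
              function(v) core_clustering_weight(g, v, params$degree_cutoff),
              numeric(1))

  adj <- igraph::as_adj_list(g)
  visited <- rep(FALSE, nv)
  seed_order <- order(-w, vnames)
  raw <- list()

  for (s in seed_order) {
    if (visited[s] || w[s] <= 0) next
    cutoff_w <- w[s] * (1 - params$node_score_cutoff)
    members <- s
    visited[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!visited[u] && w[u] >= cutoff_w) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    raw[[length(raw) + 1L]] <- list(seed = s, members = members)
  }

  mods <- list()
  for (cand in raw) {
    nodes <- cand$members
    if (params$haircut) nodes <- haircut_nodes(g, nodes)
    if (length(nodes) < 2) next
    sub <- igraph::induced_subgraph(g, nodes)
    if (max(igraph::coreness(sub)) < params$k_core) next
    if (params$fluff) {
      nodes <- fluff_nodes(g, nodes, params$fluff_density)
      sub <- igraph::induced_subgraph(g, nodes)
    }
    sc <- module_score(vnames[nodes], g, params$density_denominator)
    mods[[length(mods) + 1L]] <- structure(
      list(nodes = sort(vnames[nodes]), seed = vnames[cand$seed],
           density = sc$density, score = sc$score, rank = NA_integer_),
      class = "mcode_module")
  }
  if (!length(mods)) return(mods)
  ord <- order(-vapply(mods, `[[`, numeric(1), "score"),
               -lengths(lapply(mods, `[[`, "nodes")),
               vapply(mods, `[[`, character(1), "seed"))
  mods <- mods[ord]
  for (i in seq_along(mods)) mods[[i]]$rank <- i
  mods
}

# iterated removal of vertices singly connected within the module
haircut_nodes <- function(g, nodes) {
  repeat {
    if (length(nodes) == 0) return(nodes)
    sub <- igraph::induced_subgraph(g, nodes)
    deg <- igraph::degree(sub)
    if (all(deg >= 2)) return(nodes)
    nodes <- nodes[deg >= 2]
  }
}

fluff_nodes <- function(g, nodes, fluff_density) {
  boundary <- setdiff(unique(unlist(
    igraph::adjacent_vertices(g, nodes))), nodes)
  add <- integer()
  for (v in boundary) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    dens <- igraph::edge_density(igraph::induced_subgraph(g, nb))
    if (isTRUE(dens > fluff_density)) add <- c(add, v)
  }
  union(nodes, add)
}

#' @export
print.mcode_module <- function(x, ...) {
  cat(sprintf("mcode_module rank %d: %d nodes, density %.3f, score %.3f, seed %s\n",
              x$rank, length(x$nodes), x$density, x$score, x$seed))
  invisible(x)
}

#' Tabulate a module list
#' @param modules list returned by [find_modules()].
#' @return Data frame with one row per module.
#' @export
modules_table <- function(modules) {
  if (!length(modules))
    return(data.frame(rank = integer(), score = numeric(),
                      density = numeric(), n = integer(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    rank = vapply(modules, `[[`, integer(1), "rank"),
    score = vapply(modules, `[[`, numeric(1), "score"),
    density = vapply(modules, `[[`, numeric(1), "density"),
    n = lengths(lapply(modules, `[[`, "nodes")),
    seed = vapply(modules, `[[`, character(1), "seed"),
    members = vapply(modules, function(m) paste(m$nodes, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
}
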