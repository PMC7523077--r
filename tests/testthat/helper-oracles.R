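# Independent oracles, deliberately hand-rolled (no rank(), cor(),
# p.adjust() or igraph logic) so they stay independent of the code paths
# they check.

# average ranks by explicit sorting and tie-run averaging
oracle_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Pearson on oracle ranks, via the raw sum formula
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  dx <- rx - sum(rx) / length(rx)
  dy <- ry - sum(ry) / length(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# literal BH step-up: q_i = min over j with p_(j) >= p_(i) of m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[o][i])
    q[o[i]] <- min(1, min(m * p[o][js] / js))
  }
  q
}

# does the node set contain a 2-core? iterative pruning on a plain edge list
oracle_has_2core <- function(nodes, edges) {
  repeat {
    if (length(nodes) < 3) return(FALSE)
    keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
    ends <- c(edges[keep, 1], edges[keep, 2])
    deg <- vapply(nodes, function(v) sum(ends == v), numeric(1))
    if (all(deg >= 2)) return(TRUE)
    nodes <- nodes[deg >= 2]
  }
}

oracle_module_density <- function(nodes, edges) {
  keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
  sum(keep) / (length(nodes) * (length(nodes) - 1) / 2)
}

# small random connected graph as an igraph with letter names
random_connected_graph <- function(n_max = 8) {
  repeat {
    n <- sample(3:n_max, 1)
    g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.9))
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- letters[seq_len(n)]
      return(g)
    }
  }
}

graph_edge_matrix <- function(g) {
  e <- igraph::as_edgelist(g)
  if (!nrow(e)) matrix(character(), ncol = 2) else e
}

# a tiny abundance matrix around a values matrix, single condition "all"
make_am <- function(values, trait = NULL, condition = "all") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  md <- data.frame(sample_id = rownames(values),
                   condition = rep(condition, length.out = nrow(values)),
                   stringsAsFactors = FALSE)
  if (!is.null(trait)) md$trait <- trait
  abundance_matrix(values, md)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

edge_keys <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")

# the acceptance-scale benchmark spec: four 8-metabolite blocks, the first
# trait-linked and treatment-disrupted
benchmark_spec <- function(seed) {
  synthetic_spec(n_samples_per_condition = 10, n_metabolites = 32,
                 seed = seed)
}
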