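# Independent brute-force oracles used to cross-check the implementation.
# All of them work from first principles (boolean matrix closure, exhaustive
# enumeration) and never call the code paths they validate.

# reflexive-transitive closure by Floyd-Warshall on a logical adjacency matrix
bf_closure <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) {
    reach <- reach | outer(reach[, k], reach[k, ], `&`)
  }
  reach
}

adjacency_of <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) adj[cbind(net$edges$from, net$edges$to)] <- TRUE
  adj
}

# seed candidates from first principles: nodes reached only from within
# their own mutual-reachability class
bf_seed_nodes <- function(net) {
  if (length(net$nodes) == 0L) return(character(0))
  reach <- bf_closure(adjacency_of(net))
  same_scc <- reach & t(reach)
  is_seed <- vapply(seq_len(nrow(reach)), function(i) {
    reaches_i <- which(reach[, i])
    all(same_scc[i, reaches_i])
  }, logical(1))
  net$nodes[is_seed]
}

# mutual-reachability partition as a canonical list of sorted member sets
bf_scc_partition <- function(net) {
  if (length(net$nodes) == 0L) return(list())
  reach <- bf_closure(adjacency_of(net))
  same <- reach & t(reach)
  groups <- unique(apply(same, 1, function(r) paste(net$nodes[r], collapse = ",")))
  sort(groups)
}

random_digraph <- function(n, p = 2 / n, id = "rand") {
  nodes <- sprintf("n%02d", seq_len(n))
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  metabolic_network(id, nodes,
                    data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]]))
}

# a random model ready for index computation (guaranteed non-empty seed set:
# every finite digraph has at least one source SCC, and we cap its size)
random_model_pairable <- function(id, n = 12, p = 0.15) {
  net <- random_digraph(n, p, id = id)
  seeds <- detect_seed_set(net, threshold = 1 / n)
  list(network = net, seeds = seeds)
}

# distances between two leaves by generic weighted shortest path on the
# tree seen as an undirected graph (igraph is the oracle here, never used
# by patristic_distances itself, which goes through cophenetic distances)
bf_tree_distance <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  igraph::distances(g, v = as.character(match(a, tree$tip.label)),
                    to = as.character(match(b, tree$tip.label)),
                    weights = tree$edge.length)[1, 1]
}
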