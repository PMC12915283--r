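#' Configuration for a simulated connectome
#'
#' Weighted directed random graph with planted communities (denser within
#' modules than between) and optional planted hub/authority structure: each
#' planted hub sends strong out-edges to every planted authority.
#'
#' @param n_nodes number of regions; must equal `sum(module_sizes)`.
#' @param module_sizes sizes of the planted communities.
#' @param p_within,p_between directed edge probabilities inside / across
#'   modules, with `0 <= p_between <= p_within <= 1`.
#' @param weight_scale multiplicative scale of edge weights (> 0).
#' @param planted_hub_nodes,planted_authority_nodes node index sets for the
#'   planted hub -> authority edges (may be empty).
#' @param hub_weight weight of each planted hub -> authority edge, in units
#'   of `weight_scale`.
#' @param seed integer seed.
#' @return object of class `network_sim_config`.
#' @export
network_sim_config <- function(n_nodes = 88,
                               module_sizes = c(30, 30, 28),
                               p_within = 0.3,
                               p_between = 0.05,
                               weight_scale = 1,
                               planted_hub_nodes = integer(0),
                               planted_authority_nodes = integer(0),
                               hub_weight = 3,
                               seed = 1L) {
  n_nodes <- .check_count(n_nodes, "n_nodes")
  if (sum(module_sizes) != n_nodes) {
    stop("`module_sizes` must sum to `n_nodes`", call. = FALSE)
  }
  if (p_between < 0 || p_within > 1 || p_between > p_within) {
    stop("need 0 <= p_between <= p_within <= 1", call. = FALSE)
  }
  if (weight_scale <= 0) stop("`weight_scale` must be > 0", call. = FALSE)
  ok <- function(x) length(x) == 0 || (min(x) >= 1 && max(x) <= n_nodes)
  if (!ok(planted_hub_nodes) || !ok(planted_authority_nodes)) {
    stop("planted node sets must lie within 1..n_nodes", call. = FALSE)
  }
  structure(
    list(
      n_nodes = n_nodes, module_sizes = as.integer(module_sizes),
      p_within = p_within, p_between = p_between,
      weight_scale = weight_scale,
      planted_hub_nodes = as.integer(planted_hub_nodes),
      planted_authority_nodes = as.integer(planted_authority_nodes),
      hub_weight = hub_weight, seed = as.integer(seed)
    ),
    class = "network_sim_config"
  )
}

#' Simulate a weighted directed connectome
#'
#' @param config a [network_sim_config()].
#' @return an igraph connectome (see [build_network()]) with vertex
#'   attribute `module` giving the planted community of each node.
#' @export
simulate_connectome <- function(config) {
  if (!inherits(config, "network_sim_config")) {
    stop("`config` must be a network_sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_nodes
  module <- rep(seq_along(config$module_sizes), times = config$module_sizes)
  same <- outer(module, module, "==")
  p <- ifelse(same, config$p_within, config$p_between)
  diag(p) <- 0
  present <- matrix(runif(n * n) < p, n, n)
  W <- matrix(0, n, n)
  ne <- sum(present)
  if (ne > 0) {
    W[present] <- config$weight_scale * rlnorm(ne, meanlog = 0, sdlog = 0.5)
  }
  if (length(config$planted_hub_nodes) > 0 &&
      length(config$planted_authority_nodes) > 0) {
    for (h in config$planted_hub_nodes) {
      tgt <- setdiff(config$planted_authority_nodes, h)
      W[h, tgt] <- config$weight_scale * config$hub_weight
    }
  }
  diag(W) <- 0
  nodes <- sprintf("N%03d", seq_len(n))
  idx <- which(W > 0, arr.ind = TRUE)
  edges <- data.frame(
    source = nodes[idx[, 1]], target = nodes[idx[, 2]],
    weight = W[idx]
  )
  g <- build_network(nodes, edges)
  igraph::V(g)$module <- module
  g
}

#' Read / write weighted edge lists
#'
#' Plain CSV with columns `source`, `target`, `weight`.
#'
#' @param edges data.frame edge list.
#' @param path file path.
#' @export
write_edge_list <- function(edges, path) {
  write.csv(edges[, c("source", "target", "weight")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
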