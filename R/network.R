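#' Build a weighted directed connectome
#'
#' Constructs the anatomical network from a region list and a weighted
#' directed edge list (e.g. normalized connection densities). Edges whose
#' source equals their target are removed (connections from and to the same
#' structure carry no information here) and the removal count is recorded;
#' regions without edges are retained as isolated nodes.
#'
#' @param regions character vector of region acronyms (the node set), or a
#'   data.frame with a `region` column plus optional annotation columns
#'   (e.g. `activated_in`) which become vertex attributes.
#' @param edges data.frame with columns `source`, `target`, `weight`
#'   (weights >= 0, endpoints within `regions`).
#' @return an igraph directed weighted graph; the number of removed
#'   self-loops is attached as graph attribute `self_loops_removed`.
#' @export
build_network <- function(regions, edges) {
  ann <- NULL
  if (is.data.frame(regions)) {
    ann <- regions
    if (!"region" %in% names(ann)) {
      stop("`regions` data.frame needs a `region` column", call. = FALSE)
    }
    regions <- ann$region
  }
  if (anyDuplicated(regions)) stop("duplicate region names", call. = FALSE)
  req <- c("source", "target", "weight")
  if (!all(req %in% names(edges))) {
    stop("`edges` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(edges$weight < 0)) stop("negative edge weights", call. = FALSE)
  outside <- setdiff(unique(c(edges$source, edges$target)), regions)
  if (length(outside) > 0) {
    stop("edge endpoints outside region list: ",
         paste(head(outside, 5), collapse = ", "), call. = FALSE)
  }
  self <- edges$source == edges$target
  edges <- edges[!self, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, req], directed = TRUE,
    vertices = data.frame(name = regions)
  )
  if (!is.null(ann)) {
    for (col in setdiff(names(ann), "region")) {
      g <- igraph::set_vertex_attr(g, col, value = ann[[col]][match(igraph::V(g)$name, ann$region)])
    }
  }
  g <- igraph::set_graph_attr(g, "self_loops_removed", sum(self))
  g
}

#' Leiden partition of the connectome
#'
#' Community detection by the Leiden algorithm, maximizing modularity on
#' the connection-density weights. igraph's Leiden implementation operates
#' on undirected graphs, so the directed connectome is symmetrized first by
#' summing the weights of reciprocal edges; the partition is deterministic
#' under `seed`.
#'
#' @param g connectome from [build_network()] (nonempty).
#' @param resolution modularity resolution parameter.
#' @param seed integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return list with `membership` (named community id per node) and
#'   `quality` (modularity of the partition).
#' @export
partition_leiden <- function(g, resolution = 1, seed = 1L, n_iterations = 10) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "sum"))
  set.seed(seed)
  cl <- igraph::cluster_leiden(
    gu, objective_function = "modularity",
    resolution = resolution, n_iterations = n_iterations,
    weights = if (igraph::ecount(gu) > 0) igraph::E(gu)$weight else NULL
  )
  memb <- igraph::membership(cl)
  quality <- if (igraph::ecount(gu) > 0) {
    igraph::modularity(gu, memb, weights = igraph::E(gu)$weight,
                       resolution = resolution)
  } else NA_real_
  list(membership = memb, quality = quality)
}

# HITS power iteration on a dense weight matrix. Score vectors are L1
# normalized (each kind sums to 1). Returns zeros if the matrix has no
# edges and `zero_ok` is TRUE.
.hits_matrix <- function(W, tol = 1e-12, max_iter = 10000L, zero_ok = FALSE,
                         fallback_eigen = FALSE) {
  n <- nrow(W)
  if (all(W == 0)) {
    if (zero_ok) {
      return(list(hub = numeric(n), authority = numeric(n),
                  iterations = 0L, converged = TRUE))
    }
    stop("graph has no edges; HITS scores undefined", call. = FALSE)
  }
  tW <- t(W)
  h <- rep(1 / n, n)
  a <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    a_new <- as.vector(tW %*% h)
    sa <- sum(a_new)
    if (sa > 0) a_new <- a_new / sa
    h_new <- as.vector(W %*% a_new)
    sh <- sum(h_new)
    if (sh > 0) h_new <- h_new / sh
    delta <- max(abs(a_new - a), abs(h_new - h))
    a <- a_new
    h <- h_new
    if (delta < tol) {
      return(list(hub = h, authority = a, iterations = it, converged = TRUE))
    }
  }
  if (fallback_eigen) {
    # near-degenerate dominant spectrum: take the exact principal
    # eigenvectors of the symmetric products instead
    l1 <- function(v) { v <- abs(Re(v)); s <- sum(v); if (s > 0) v / s else v }
    a <- l1(eigen(tW %*% W, symmetric = TRUE)$vectors[, 1])
    h <- l1(eigen(W %*% tW, symmetric = TRUE)$vectors[, 1])
    return(list(hub = h, authority = a, iterations = max_iter, converged = TRUE))
  }
  stop(sprintf("HITS did not converge within %d iterations", max_iter),
       call. = FALSE)
}

.weight_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE))
}

#' HITS hub and authority scores
#'
#' Iteratively updates hub and authority scores on the weighted directed
#' graph until they converge to the mutually reinforcing fixed point: a
#' node is a good hub if it points to good authorities and a good authority
#' if good hubs point to it. Each score vector is normalized to sum to 1.
#'
#' @param g connectome from [build_network()] (>= 1 edge), or a weight
#'   matrix.
#' @param tol convergence tolerance on the score change per iteration.
#' @param max_iter iteration cap.
#' @param fallback when the iteration stalls (a numerically degenerate
#'   dominant eigengap, e.g. symmetric disconnected components), fall back
#'   to the exact principal eigenvectors of the symmetric products
#'   (default). With `fallback = FALSE` non-convergence is an error
#'   reporting the iteration count, never a silent result.
#' @return list with `hub` and `authority` (named numeric vectors summing
#'   to 1) and `iterations`.
#' @export
hits_scores <- function(g, tol = 1e-12, max_iter = 10000L, fallback = TRUE) {
  W <- if (is.matrix(g)) g else .weight_matrix(g)
  res <- .hits_matrix(W, tol = tol, max_iter = max_iter,
                      fallback_eigen = fallback)
  nm <- rownames(W) %||% colnames(W)
  if (!is.null(nm)) {
    names(res$hub) <- nm
    names(res$authority) <- nm
  }
  res[c("hub", "authority", "iterations")]
}

#' Bootstrap significance of hub/authority scores
#'
#' For a target region, generates `n_iter` random networks of the same size
#' as the observed network: the target is kept in every iteration while the
#' remaining nodes are resampled from the region pool, and the subgraph is
#' induced from the full connectivity table (self-loops removed). The
#' target's hub and authority scores over these random networks form the
#' null distribution; significance is the z-score of the observed score and
#' the one-tailed p from the upper tail of the standard normal.
#'
#' Random subsets can induce edgeless networks; there the target's scores
#' are defined as 0 (no importance without connections).
#'
#' @param target region acronym of interest.
#' @param observed_nodes node set of the observed network (must contain
#'   `target`).
#' @param full_edges complete weighted directed edge list (`source`,
#'   `target`, `weight`) covering the pool.
#' @param pool region universe to resample from (strictly larger than the
#'   observed network).
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param two_tailed if `TRUE` report two-tailed p-values instead of the
#'   default upper-tail one-tailed p.
#' @return one-row data.frame with observed scores, bootstrap mean/sd,
#'   z-scores and p-values for hub and authority; when a bootstrap sd is 0
#'   the corresponding z and p are `NA` (significance undefined, reported
#'   explicitly).
#' @export
bootstrap_hits <- function(target, observed_nodes, full_edges, pool,
                           n_iter = 1000L, seed = 1L, two_tailed = FALSE) {
  n_iter <- .check_count(n_iter, "n_iter")
  if (!(target %in% observed_nodes)) {
    stop("`target` must be part of the observed network", call. = FALSE)
  }
  pool <- unique(pool)
  if (length(pool) <= length(observed_nodes)) {
    stop("`pool` must be strictly larger than the observed network", call. = FALSE)
  }
  if (!all(observed_nodes %in% pool)) pool <- union(pool, observed_nodes)
  gfull <- build_network(pool, full_edges)
  Wfull <- .weight_matrix(gfull)

  obs_idx <- match(observed_nodes, rownames(Wfull))
  t_in_obs <- match(target, observed_nodes)
  obs <- .hits_matrix(Wfull[obs_idx, obs_idx, drop = FALSE], tol = 1e-10,
                      zero_ok = TRUE, fallback_eigen = TRUE)
  obs_hub <- obs$hub[t_in_obs]
  obs_auth <- obs$authority[t_in_obs]

  t_idx <- match(target, rownames(Wfull))
  others <- setdiff(seq_len(nrow(Wfull)), t_idx)
  k <- length(observed_nodes) - 1L
  set.seed(seed)
  boot <- matrix(NA_real_, n_iter, 2)
  for (i in seq_len(n_iter)) {
    sel <- c(t_idx, sample(others, k))
    res <- .hits_matrix(Wfull[sel, sel, drop = FALSE], tol = 1e-10,
                        zero_ok = TRUE, fallback_eigen = TRUE)
    boot[i, ] <- c(res$hub[1], res$authority[1])
  }
  stat <- function(observed, draws) {
    mu <- mean(draws)
    s <- sd(draws)
    if (s == 0) {
      return(c(mean = mu, sd = s, z = NA_real_, p = NA_real_))
    }
    z <- (observed - mu) / s
    p <- if (two_tailed) 2 * pnorm(abs(z), lower.tail = FALSE)
         else pnorm(z, lower.tail = FALSE)
    c(mean = mu, sd = s, z = z, p = p)
  }
  sh <- stat(obs_hub, boot[, 1])
  sa <- stat(obs_auth, boot[, 2])
  data.frame(
    region = target, n_iter = n_iter,
    hub = unname(obs_hub), hub_boot_mean = unname(sh["mean"]),
    hub_boot_sd = unname(sh["sd"]), z_hub = unname(sh["z"]),
    p_hub = unname(sh["p"]),
    authority = unname(obs_auth), authority_boot_mean = unname(sa["mean"]),
    authority_boot_sd = unname(sa["sd"]), z_authority = unname(sa["z"]),
    p_authority = unname(sa["p"])
  )
}

#' Keep only the strongest edges (display filter)
#'
#' Returns the `ceiling(fraction * E)` largest-weight edges, ties broken by
#' stable input order. Intended for figure rendering only, never for the
#' statistics.
#'
#' @param g connectome from [build_network()] (>= 1 edge).
#' @param fraction fraction of edges to keep, in (0, 1].
#' @return data.frame edge list (`source`, `target`, `weight`).
#' @export
top_edge_filter <- function(g, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  ne <- igraph::ecount(g)
  if (ne == 0) stop("graph has no edges", call. = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  keep <- ceiling(fraction * ne)
  ord <- order(-el$weight, seq_len(ne))  # stable tie-break by input order
  out <- el[ord[seq_len(keep)], c("source", "target", "weight")]
  rownames(out) <- NULL
  out
}
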