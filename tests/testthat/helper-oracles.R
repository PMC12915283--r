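# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# all permutations of 1..n, built by inserting n into every position of
# each permutation of 1..(n-1)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- perms_of(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# two-sided exact Mann-Whitney p from R's exact distribution (no ties)
mw_pwilcox_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  U <- sum(outer(x, y, ">"))
  center <- n * m / 2
  dev <- abs(U - center)
  ks <- 0:(n * m)
  p <- sum(stats::dwilcox(ks[abs(ks - center) >= dev - 1e-9], n, m))
  list(U = U, p = p)
}

# two-sided exact Mann-Whitney p by direct pair-counting enumeration
# (handles ties; different route: counts x>y pairs per split, no ranks)
mw_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  center <- n * m / 2
  U_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- U_of(x, y)
  splits <- combn(n + m, n)
  u_all <- apply(splits, 2, function(s) U_of(pool[s], pool[-s]))
  list(U = U, p = mean(abs(u_all - center) >= abs(U - center) - 1e-9))
}

# two-sided exact signed-rank p from R's exact distribution (no ties)
signrank_oracle <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  W <- sum(rank(abs(d))[d > 0])
  center <- n * (n + 1) / 4
  ks <- 0:(n * (n + 1) / 2)
  p <- sum(stats::dsignrank(ks[abs(ks - center) >= abs(W - center) - 1e-9], n))
  list(W = W, p = p)
}

# exact two-sided Spearman p by full permutation enumeration, rho via the
# rank-difference formula (valid without ties)
spearman_enum_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) 1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
  rho <- rho_of(rx, ry)
  rhos <- vapply(perms_of(n), function(p) rho_of(rx, ry[p]), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# HITS via eigen decomposition of the symmetric products
hits_eigen_oracle <- function(W) {
  l1 <- function(v) { v <- abs(Re(v)); v / sum(v) }
  list(
    hub = l1(eigen(W %*% t(W), symmetric = TRUE)$vectors[, 1]),
    authority = l1(eigen(t(W) %*% W, symmetric = TRUE)$vectors[, 1])
  )
}

# derangement count by inclusion-exclusion
derangement_count <- function(n) {
  round(sum((-1)^(0:n) * choose(n, 0:n) * factorial(n - (0:n))))
}

# random weighted digraph matrix with >= 1 edge
random_digraph <- function(n, p = 0.4) {
  repeat {
    m <- matrix(runif(n * n) < p, n, n)
    diag(m) <- FALSE
    if (any(m)) break
  }
  W <- matrix(0, n, n)
  W[m] <- runif(sum(m), 0.5, 1.5)
  W
}

# null c-Fos study config: no planted effects, no coupling
null_cfos_config <- function(n_regions, seed) {
  cfos_sim_config(
    n_regions = n_regions,
    activated_regions_dem = integer(0), activated_regions_obs = integer(0),
    effect_log_fold = 0, dyad_coupling_r = 0, coupled_regions = integer(0),
    seed = seed
  )
}

# full-graph edge list for the planted-hub bootstrap scenario: a pool in
# which broadcast competitor hubs are strong everywhere, while the target
# region P001 is a hub only for its 5 dedicated authority regions (P002..
# P006), which accompany it in the observed network
planted_hub_scenario <- function(seed, n_pool = 60) {
  set.seed(seed)
  pool <- sprintf("P%03d", seq_len(n_pool))
  comp <- 7:16
  edges <- do.call(rbind, lapply(comp, function(h) {
    tg <- sample(setdiff(seq_len(n_pool), h), 25)
    data.frame(source = pool[h], target = pool[tg], weight = 2)
  }))
  m <- matrix(runif(n_pool^2) < 0.05, n_pool, n_pool)
  diag(m) <- FALSE
  m[1, ] <- FALSE  # the target's only out-edges are the planted ones
  e <- which(m, arr.ind = TRUE)
  edges <- rbind(edges, data.frame(
    source = pool[e[, 1]], target = pool[e[, 2]],
    weight = runif(nrow(e), 0.5, 1.5)
  ))
  edges <- rbind(edges, data.frame(source = pool[1], target = pool[2:6], weight = 3))
  observed <- c(pool[1:6], sample(pool[setdiff(17:n_pool, comp)], 6))
  list(pool = pool, edges = edges, observed = observed, target = pool[1])
}

# adjusted Rand index (mclust is the reference implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
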