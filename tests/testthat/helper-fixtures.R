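# Shared fixtures, built in code.

# Wrap an explicit stabilized matrix as a system object (mirrors what
# stabilize() stores), for micro-examples where A_s is given directly.
as_system <- function(As, regions = sprintf("R%03d", seq_len(nrow(As)))) {
  ed <- eigen(As, symmetric = TRUE)
  ord <- order(ed$values)
  structure(list(A_s = As, scheme = "spectral", c = 1,
                 rho = max(abs(ed$values)),
                 values = ed$values[ord],
                 vectors = ed$vectors[, ord, drop = FALSE],
                 regions = regions,
                 subject = NA_character_, scan = NA_character_),
            class = "stabilized_system")
}

# 2-node system with coupling a = 0.5: the canonical worked example.
two_node_system <- function(a = 0.5) {
  as_system(matrix(c(0, a, a, 0), 2, 2))
}

# 6-node fixture: two unit-weight triangles joined by one bridge edge 3-4.
two_triangle_connectome <- function() {
  A <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))
  A[edges] <- 1
  A <- A + t(A)
  connectome(A)
}

# Random sparse symmetric nonnegative matrix rescaled to a target spectral
# radius; used for oracle-equivalence ensembles.
random_stable_system <- function(n, rho_target, seed, density = 0.3) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- runif(length(ut)) < density
  A[ut[on]] <- runif(sum(on), 0.1, 1)
  A <- A + t(A)
  lmax <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  if (lmax > 0) A <- A * (rho_target / lmax)
  as_system(A)
}

# Connected synthetic connectome with continuous weights (generic
# controllability regime); regenerates with shifted seed until connected.
connected_continuous_connectome <- function(n = 60, seed = 1) {
  params <- generator_params(n_regions = n, n_communities = 4,
                             weight_law = "lognormal", seed = seed)
  for (try in 0:20) {
    conn <- generate_connectome(params, seed = seed + 1000L * try)
    g <- igraph::graph_from_adjacency_matrix(conn$A, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::is_connected(g)) return(conn)
  }
  stop("could not draw a connected network")
}
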