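# igraph helper on a weighted symmetric matrix (positive weights only)
graph_from_A <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Robust consensus partition of a connectome
#'
#' Community structure is estimated by consensus over many seeded
#' modularity-maximization runs: (1) `n_runs` Louvain runs, each on a
#' seeded random permutation of vertex order (the source of run-to-run
#' variability); (2) the pairwise co-assignment (association) matrix across
#' runs; (3) thresholding against a label-permutation null (the
#' `consensus_threshold` quantile of null co-assignment frequencies);
#' (4) Louvain reclustering of the thresholded association graph. The whole
#' procedure is deterministic given `seed`.
#'
#' @param conn a [connectome].
#' @param n_runs number of base runs (default 100).
#' @param resolution Louvain resolution parameter.
#' @param consensus_threshold null quantile for association thresholding
#'   (default 0.95).
#' @param seed integer seed.
#' @return object of class `partition`: `membership` (named integer vector),
#'   `n_communities`, `consensus` (per-region mean co-assignment frequency
#'   with its final community), `association` (matrix).
#' @export
robust_partition <- function(conn, n_runs = 100, resolution = 1,
                             consensus_threshold = 0.95, seed = 1) {
  stopifnot(inherits(conn, "connectome"))
  n <- length(conn$regions)
  if (n == 0) stop("empty graph")
  g <- graph_from_A(conn$A)
  if (igraph::ecount(g) == 0) {
    # edgeless: every region its own community, trivially consensual
    memb <- stats::setNames(seq_len(n), conn$regions)
    return(structure(list(membership = memb, n_communities = n,
                          consensus = stats::setNames(rep(1, n),
                                                      conn$regions),
                          association = diag(n)),
                     class = "partition"))
  }
  set.seed(seed)
  C <- matrix(0, n, n)
  Cnull <- matrix(0, n, n)
  memberships <- matrix(0L, n, n_runs)
  for (r in seq_len(n_runs)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    m <- igraph::membership(igraph::cluster_louvain(gp,
                                                    resolution = resolution))
    memb <- as.integer(m[perm])   # membership of original vertex i
    memberships[, r] <- memb
    C <- C + outer(memb, memb, "==")
    null_memb <- memb[sample.int(n)]
    Cnull <- Cnull + outer(null_memb, null_memb, "==")
  }
  C <- C / n_runs
  Cnull <- Cnull / n_runs
  thr <- stats::quantile(Cnull[upper.tri(Cnull)], consensus_threshold,
                         names = FALSE)
  Cthr <- C
  Cthr[C <= thr] <- 0
  diag(Cthr) <- 0
  if (all(Cthr == 0)) {
    # no consensus above null: fall back to the best-modularity base run
    mods <- apply(memberships, 2, function(mb)
      igraph::modularity(g, mb, weights = igraph::E(g)$weight))
    memb <- memberships[, which.max(mods)]
  } else {
    gc_ <- graph_from_A(Cthr)
    memb <- as.integer(igraph::membership(igraph::cluster_louvain(gc_)))
  }
  memb <- match(memb, unique(memb))   # canonical labels 1..K
  names(memb) <- conn$regions
  cons <- vapply(seq_len(n), function(i) {
    same <- which(memb == memb[i])
    mean(C[i, same])
  }, numeric(1))
  structure(list(membership = memb, n_communities = max(memb),
                 consensus = stats::setNames(cons, conn$regions),
                 association = C),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d regions in %d communities (sizes: %s)\n",
              length(x$membership), x$n_communities,
              paste(tabulate(x$membership), collapse = ", ")))
  invisible(x)
}

#' Boundary nodes of a partition
#'
#' A region is a boundary node iff it has at least one positive-weight edge
#' to a region assigned to a different community — the minimal reading of
#' "lying at the boundary between communities".
#'
#' @param conn a [connectome].
#' @param partition a [robust_partition] result, or a membership vector in
#'   region order.
#' @return character vector of boundary region ids (possibly empty).
#' @export
boundary_nodes <- function(conn, partition) {
  stopifnot(inherits(conn, "connectome"))
  memb <- if (inherits(partition, "partition")) partition$membership
          else partition
  if (length(memb) != length(conn$regions)) stop("partition length mismatch")
  cross <- vapply(seq_along(memb), function(i)
    any(conn$A[i, memb != memb[i]] > 0), logical(1))
  conn$regions[cross]
}

#' Fiedler bipartition of a (sub)network
#'
#' Splits a weighted adjacency matrix by the sign of the Fiedler
#' eigenvector: the eigenvector of the graph Laplacian `L = D - A`
#' belonging to its second-smallest eigenvalue. Entries `>= 0` go to the
#' first part (zero entries to the positive side). Degenerate spectra
#' (symmetric graphs such as triangles) are broken deterministically by a
#' seeded symmetric perturbation of magnitude 1e-9 on existing edges. If
#' the subnetwork is disconnected, the component split is returned instead
#' (first connected component versus the rest).
#'
#' @param A symmetric nonnegative weight matrix of the subnetwork
#'   (>= 2 nodes).
#' @param seed seed for the degeneracy-breaking perturbation.
#' @return list of two disjoint, non-empty integer index vectors covering
#'   `1..nrow(A)`.
#' @export
fiedler_bipartition <- function(A, seed = 1) {
  n <- nrow(A)
  if (n < 2) stop("subnetwork must have at least 2 nodes")
  comp <- igraph::components(graph_from_A(A))
  if (comp$no > 1) {
    first <- which(comp$membership == 1)
    return(list(first, setdiff(seq_len(n), first)))
  }
  set.seed(seed)
  E <- matrix(0, n, n)
  ut <- upper.tri(A)
  eps <- stats::runif(sum(ut), -1, 1) * 1e-9
  E[ut] <- ifelse(A[ut] > 0, eps, 0)
  Ap <- A + E + t(E)
  L <- diag(rowSums(Ap)) - Ap
  ed <- eigen(L, symmetric = TRUE)
  f <- ed$vectors[, n - 1]           # second-smallest eigenvalue
  pos <- which(f >= 0)
  neg <- setdiff(seq_len(n), pos)
  if (length(neg) == 0 || length(pos) == 0) {
    # numerically flat vector: fall back to median split
    ord <- order(f)
    pos <- ord[seq_len(ceiling(n / 2))]
    neg <- setdiff(seq_len(n), pos)
  }
  list(sort(pos), sort(neg))
}

#' Boundary controllability of every region
#'
#' Implements the iterative boundary-value assignment. First a robust
#' consensus partition is computed and every region with an edge crossing
#' community lines (a first-level boundary node, `N_1` of them) receives
#' the value 1. Then each community is recursively bipartitioned by the
#' Fiedler eigenvector of its induced subnetwork; regions newly exposed as
#' boundary nodes at depth `d` (an edge crossing the new split, not yet
#' assigned) receive the value `(N - n_assigned_before_depth_d) / N`.
#' Subnetworks of at most 2 regions bottom out: their unassigned regions
#' take the current depth's value. Iteration continues until every region
#' is assigned; values lie in `(0, 1]` and are non-increasing in assignment
#' depth. High-boundary regions sit at the interfaces between communities
#' and can couple or decouple the trajectories of different subsystems.
#'
#' By default all remaining subnetworks are processed breadth-first at each
#' depth (values then depend only on depth). `order = "least_avg_ctrl"`
#' instead recurses into one subnetwork per depth — the one with the
#' smallest mean average controllability — for users preferring the
#' least-controllable-first traversal.
#'
#' @param conn a [connectome].
#' @param partition optional precomputed [robust_partition]; computed from
#'   `conn` when NULL.
#' @param n_runs,resolution,consensus_threshold,seed passed to
#'   [robust_partition]; `seed` also drives the Fiedler tie-breaking
#'   perturbations.
#' @param order `"breadth_first"` (default) or `"least_avg_ctrl"`.
#' @return object of class `boundary_values`: `values` (named, in `(0, 1]`),
#'   `depth` (named integer assignment depth), `N_1` (first-level boundary
#'   count), `partition`.
#' @export
boundary_controllability <- function(conn, partition = NULL, n_runs = 100,
                                     resolution = 1,
                                     consensus_threshold = 0.95, seed = 1,
                                     order = c("breadth_first",
                                               "least_avg_ctrl")) {
  stopifnot(inherits(conn, "connectome"))
  order <- match.arg(order)
  n <- length(conn$regions)
  if (n == 0) stop("empty graph")
  if (is.null(partition))
    partition <- robust_partition(conn, n_runs = n_runs,
                                  resolution = resolution,
                                  consensus_threshold = consensus_threshold,
                                  seed = seed)
  memb <- if (inherits(partition, "partition")) partition$membership
          else partition
  A <- conn$A
  values <- rep(NA_real_, n)
  depth_of <- rep(NA_integer_, n)
  bn <- match(boundary_nodes(conn, memb), conn$regions)
  N1 <- length(bn)
  if (N1 > 0) {
    values[bn] <- 1
    depth_of[bn] <- 1L
  }
  subnets <- unname(split(seq_len(n), memb))
  avg_ctrl <- NULL
  if (order == "least_avg_ctrl")
    avg_ctrl <- unname(average_controllability(stabilize(conn)))
  depth <- 1L
  while (anyNA(values) && length(subnets) > 0) {
    depth <- depth + 1L
    val <- (n - sum(!is.na(values))) / n
    if (order == "least_avg_ctrl" && length(subnets) > 1) {
      score <- vapply(subnets, function(S) mean(avg_ctrl[S]), numeric(1))
      pick <- which.min(score)
      todo <- subnets[pick]
      keep <- subnets[-pick]
    } else {
      todo <- subnets
      keep <- list()
    }
    newly <- integer(0)
    children <- list()
    for (S in todo) {
      unassigned <- S[is.na(values[S])]
      if (length(S) <= 2) {
        newly <- c(newly, unassigned)
        next
      }
      halves <- fiedler_bipartition(A[S, S, drop = FALSE],
                                    seed = seed + 1000L * depth + S[1])
      h1 <- S[halves[[1]]]; h2 <- S[halves[[2]]]
      crossing <- S[vapply(S, function(i) {
        other <- if (i %in% h1) h2 else h1
        any(A[i, other] > 0)
      }, logical(1))]
      newly <- c(newly, intersect(crossing, unassigned))
      children <- c(children, list(h1, h2))
    }
    values[newly] <- val
    depth_of[newly] <- depth
    subnets <- c(keep, Filter(function(S) anyNA(values[S]), children))
  }
  if (anyNA(values)) {              # safety net; unreachable by construction
    values[is.na(values)] <- (n - sum(!is.na(values))) / n
    depth_of[is.na(depth_of)] <- depth + 1L
  }
  structure(list(values = stats::setNames(values, conn$regions),
                 depth = stats::setNames(depth_of, conn$regions),
                 N_1 = N1, partition = partition),
            class = "boundary_values")
}

#' @export
print.boundary_values <- function(x, ...) {
  cat(sprintf(
    "<boundary_values> N = %d, N_1 = %d first-level boundary nodes, %d depth levels\n",
    length(x$values), x$N_1, max(x$depth)))
  invisible(x)
}
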