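#' Construct a connectome object
#'
#' A connectome is a weighted, undirected structural brain network: a square,
#' symmetric, nonnegative adjacency matrix whose entry `a_ij` counts the white
#' matter streamlines connecting regions `i` and `j`. The diagonal is zero
#' (self-connections carry no meaning for inter-regional control).
#'
#' @param A square numeric matrix, symmetric to within `tol`, nonnegative.
#'   Row/column names, if present, are used as region identifiers.
#' @param regions character vector of region identifiers; defaults to the
#'   matrix dimnames or `R001..RNNN`.
#' @param subject,scan optional character tags identifying the scan the
#'   matrix was derived from.
#' @param tol symmetry tolerance; asymmetries beyond it are an error,
#'   within it the matrix is symmetrized as `(A + t(A))/2`.
#' @return object of class `connectome` with elements `A` (matrix with
#'   region dimnames), `regions`, `subject`, `scan`.
#' @examples
#' conn <- connectome(matrix(c(0, 6, 6, 0), 2, 2))
#' weighted_degree(conn)
#' @export
connectome <- function(A, regions = NULL, subject = NA_character_,
                       scan = NA_character_, tol = 1e-9) {
  if (!is.matrix(A) || !is.numeric(A)) stop("A must be a numeric matrix")
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (any(!is.finite(A))) stop("A contains non-finite entries")
  if (max(abs(A - t(A))) > tol) stop("A is asymmetric beyond tolerance ", tol)
  A <- (A + t(A)) / 2
  if (any(A < 0)) stop("A contains negative weights")
  if (any(diag(A) != 0)) {
    warning("nonzero diagonal entries set to 0")
    diag(A) <- 0
  }
  if (is.null(regions)) {
    regions <- rownames(A)
    if (is.null(regions)) regions <- sprintf("R%03d", seq_len(n))
  }
  if (length(regions) != n) stop("length(regions) != nrow(A)")
  if (anyDuplicated(regions)) stop("duplicate region identifiers")
  dimnames(A) <- list(regions, regions)
  structure(list(A = A, regions = regions,
                 subject = as.character(subject), scan = as.character(scan)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$regions)
  m <- sum(x$A[upper.tri(x$A)] > 0)
  cat(sprintf("<connectome> %d regions, %d edges, density %.3f\n",
              n, m, if (n > 1) m / (n * (n - 1) / 2) else 0))
  if (!is.na(x$subject)) cat("  subject:", x$subject, " scan:", x$scan, "\n")
  invisible(x)
}

#' Weighted degree (node strength) of every region
#'
#' @param conn a [connectome].
#' @param mode `"sum"` (node strength, the default: `k_i = sum_j a_ij`) or
#'   `"mean"` (strength divided by the number of nonzero edges at the region;
#'   0 for isolated regions). Rank-based analyses are invariant to the
#'   constant-divisor difference between the two on graphs of homogeneous
#'   degree count; both are exposed because hub definitions in the
#'   connectomics literature use either.
#' @return named numeric vector over regions.
#' @export
weighted_degree <- function(conn, mode = c("sum", "mean")) {
  stopifnot(inherits(conn, "connectome"))
  mode <- match.arg(mode)
  k <- rowSums(conn$A)
  if (mode == "mean") {
    cnt <- rowSums(conn$A > 0)
    k <- ifelse(cnt > 0, k / cnt, 0)
  }
  k
}

#' Stabilize a connectome for discrete-time linear dynamics
#'
#' The dynamical model is `x(t+1) = A_s x(t) + B_K u(t)`, with `A_s` a scaled
#' version of the raw streamline-count matrix. The infinite-horizon
#' controllability Gramian exists only when the spectral radius of `A_s` is
#' below 1, so two schemes are provided:
#'
#' * `"spectral"` (default): `A_s = A / (c * (1 + lambda_max(A)))` with
#'   `c = 1`. For nonnegative symmetric `A` this guarantees
#'   `rho = lambda_max / (1 + lambda_max) < 1`.
#' * `"mean_edge_weight"`: `A_s = A / mean(nonzero off-diagonal weights)`,
#'   the normalization conventional in the connectome-control literature.
#'   It does **not** guarantee `rho < 1` (a single-edge graph yields
#'   `rho = 1`); Gramian operations refuse systems with `rho >= 1`.
#'
#' The eigendecomposition of `A_s` is computed once here and reused by all
#' Gramian-based diagnostics.
#'
#' @param conn a [connectome].
#' @param scheme `"spectral"` or `"mean_edge_weight"`.
#' @param c positive scaling constant for the spectral scheme.
#' @return object of class `stabilized_system`: `A_s`, `scheme`, `c`, `rho`
#'   (spectral radius), `values`/`vectors` (eigendecomposition of `A_s`,
#'   ascending eigenvalues), plus the connectome's region ids and tags.
#' @examples
#' sys <- stabilize(connectome(matrix(c(0, 6, 6, 0), 2, 2)))
#' sys$rho  # 6/7
#' @export
stabilize <- function(conn, scheme = c("spectral", "mean_edge_weight"), c = 1) {
  stopifnot(inherits(conn, "connectome"))
  scheme <- match.arg(scheme)
  if (!is.numeric(c) || length(c) != 1 || c <= 0) stop("c must be > 0")
  A <- conn$A
  if (any(!is.finite(A))) stop("non-finite entries")
  off <- A[upper.tri(A)]
  if (scheme == "mean_edge_weight") {
    nz <- off[off > 0]
    if (length(nz) == 0) stop("all-zero matrix: mean edge weight undefined")
    As <- A / mean(nz)
  } else {
    lmax <- if (all(off == 0)) 0 else
      max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    As <- A / (c * (1 + lmax))
  }
  ed <- eigen(As, symmetric = TRUE)
  ord <- order(ed$values)          # ascending
  values <- ed$values[ord]
  vectors <- ed$vectors[, ord, drop = FALSE]
  rho <- max(abs(values))
  structure(list(A_s = As, scheme = scheme, c = c, rho = rho,
                 values = values, vectors = vectors,
                 regions = conn$regions, subject = conn$subject,
                 scan = conn$scan),
            class = "stabilized_system")
}

#' @export
print.stabilized_system <- function(x, ...) {
  cat(sprintf("<stabilized_system> N = %d, scheme = %s, rho = %.6g%s\n",
              length(x$regions), x$scheme, x$rho,
              if (x$rho >= 1) " (UNSTABLE)" else ""))
  invisible(x)
}

# Gramian-based diagnostics require rho < 1; shared guard.
check_stable <- function(sys) {
  stopifnot(inherits(sys, "stabilized_system"))
  if (sys$rho >= 1)
    stop("spectral radius ", format(sys$rho),
         " >= 1: infinite-horizon Gramian diverges (use scheme = 'spectral')")
  invisible(sys)
}

#' Define a control set
#'
#' The input matrix `B_K` has one column per control region, each a canonical
#' basis vector `e_i`: control input enters the named regions directly.
#'
#' @param sys a [stabilize]d system (or a [connectome]); supplies the region
#'   universe.
#' @param nodes control regions, as region ids or integer indices.
#' @return object of class `control_set`: integer indices `K`, region ids,
#'   and the `N x |K|` input matrix `B`.
#' @export
control_set <- function(sys, nodes) {
  regions <- sys$regions
  n <- length(regions)
  if (is.character(nodes)) {
    K <- match(nodes, regions)
    if (anyNA(K)) stop("unknown region id(s): ",
                       paste(nodes[is.na(K)], collapse = ", "))
  } else {
    K <- as.integer(nodes)
    if (any(K < 1 | K > n)) stop("node index out of range")
  }
  if (length(K) < 1) stop("control set must contain at least one region")
  if (anyDuplicated(K)) stop("duplicate control nodes")
  B <- matrix(0, n, length(K))
  B[cbind(K, seq_along(K))] <- 1
  structure(list(K = K, regions = regions[K], B = B), class = "control_set")
}

#' Simulate the discrete-time linear dynamics
#'
#' Iterates `x(t+1) = A_s x(t) + B_K u(t)` for `t = 0, ..., T-1`.
#'
#' @param sys a [stabilize]d system.
#' @param ctrl a [control_set].
#' @param x0 initial state, length-N numeric.
#' @param u input sequence: `T x |K|` matrix (or length-`|K|` vector applied
#'   at `t = 0` with zeros afterwards, or NULL for zero input).
#' @param T horizon, number of steps.
#' @return object of class `trajectory`: `states` ((T+1) x N matrix, row t+1
#'   is `x(t)`), `inputs` (T x |K|), `horizon`.
#' @export
simulate_dynamics <- function(sys, ctrl, x0, u = NULL, T) {
  stopifnot(inherits(sys, "stabilized_system"), inherits(ctrl, "control_set"))
  n <- length(sys$regions)
  if (length(x0) != n) stop("x0 has wrong length")
  T <- as.integer(T)
  if (T < 1) stop("T must be >= 1")
  k <- length(ctrl$K)
  if (is.null(u)) u <- matrix(0, T, k)
  if (is.vector(u) && length(u) == k) {
    u0 <- u
    u <- matrix(0, T, k)
    u[1, ] <- u0
  }
  u <- as.matrix(u)
  if (nrow(u) != T || ncol(u) != k) stop("u must be T x |K|")
  X <- matrix(0, T + 1, n)
  X[1, ] <- x0
  for (t in seq_len(T))
    X[t + 1, ] <- drop(sys$A_s %*% X[t, ]) + drop(ctrl$B %*% u[t, ])
  colnames(X) <- sys$regions
  structure(list(states = X, inputs = u, horizon = T), class = "trajectory")
}
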