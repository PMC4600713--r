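#' Infinite-horizon controllability Gramian
#'
#' Solves the discrete Lyapunov fixed point
#' `W = A_s W A_s' + B_K B_K'`, equivalently the series
#' `W = sum_{tau >= 0} A_s^tau B_K B_K' (A_s')^tau`, for a stable
#' (`rho < 1`) symmetric system. The spectrum of `W` quantifies the input
#' energy needed to steer the network from the control set `K`: an
#' invertible `W` means every target state is reachable, and small
#' eigenvalues mark directions that are reachable only at enormous cost.
#'
#' Two routes are implemented:
#'
#' * `"lyapunov"` (primary): the closed-form spectral solve. With
#'   `A_s = V diag(lambda) V'`, the solution is `W = V M V'` where
#'   `M_jk = (V' B B' V)_jk / (1 - lambda_j lambda_k)`. This is exact for
#'   symmetric `A_s` and numerically robust (no matrix powers accumulate).
#' * `"series"`: truncated series evaluated by horizon doubling
#'   (`W_{2h} = W_h + A^h W_h (A^h)'`), retained as an independent
#'   cross-check; stops when the residual bound
#'   `rho^{2h} * ||W_h|| / (1 - rho^2)` falls below `tol`.
#'
#' The result is symmetrized as `(W + W')/2` to remove round-off asymmetry.
#'
#' @param sys a [stabilize]d system with `rho < 1`.
#' @param nodes control regions (ids or indices), or a [control_set].
#' @param method `"lyapunov"` (default) or `"series"`.
#' @param tol series residual tolerance.
#' @param max_doublings series safety cap.
#' @return object of class `gramian`: `W` (N x N symmetric), `nodes`
#'   (indices), `method`; for the series route, attributes `horizon` and
#'   `residual_bound`.
#' @examples
#' sys <- stabilize(connectome(matrix(c(0, 1, 1, 0), 2, 2)))
#' W <- controllability_gramian(sys, 1)
#' eigen(W$W)$values
#' @export
controllability_gramian <- function(sys, nodes,
                                    method = c("lyapunov", "series"),
                                    tol = 1e-14, max_doublings = 60L) {
  check_stable(sys)
  method <- match.arg(method)
  ctrl <- if (inherits(nodes, "control_set")) nodes else control_set(sys, nodes)
  n <- length(sys$regions)
  if (method == "lyapunov") {
    V <- sys$vectors
    lam <- sys$values
    VK <- V[ctrl$K, , drop = FALSE]          # rows of V at control nodes
    P <- crossprod(VK)                       # V' B B' V
    M <- P / (1 - outer(lam, lam))
    W <- V %*% M %*% t(V)
    W <- (W + t(W)) / 2
    res <- structure(list(W = W, nodes = ctrl$K, method = method),
                     class = "gramian")
  } else {
    BBt <- tcrossprod(ctrl$B)
    W <- BBt
    Ah <- sys$A_s
    h <- 1L
    reps <- 0L
    repeat {
      bound <- sys$rho^(2 * h) * norm(W, "2") / max(1 - sys$rho^2, 1e-300)
      if (bound < tol || reps >= max_doublings) break
      W <- W + Ah %*% W %*% t(Ah)
      Ah <- Ah %*% Ah
      h <- 2L * h
      reps <- reps + 1L
    }
    if (bound >= tol)
      stop("series did not converge within ", max_doublings, " doublings")
    W <- (W + t(W)) / 2
    res <- structure(list(W = W, nodes = ctrl$K, method = method),
                     class = "gramian")
    attr(res, "horizon") <- h
    attr(res, "residual_bound") <- bound
  }
  res
}

#' @export
print.gramian <- function(x, ...) {
  cat(sprintf("<gramian> N = %d, |K| = %d, method = %s\n",
              nrow(x$W), length(x$nodes), x$method))
  invisible(x)
}

#' Global controllability of a single control region
#'
#' The smallest eigenvalue of the single-node controllability Gramian. A
#' strictly positive value means the whole network is theoretically
#' controllable from that one region; in practice the value is minute
#' (orders of magnitude below the largest eigenvalue, which is always at
#' least 1 because `W >= e_i e_i'`), so the network is controllable in
#' principle but extremely hard to steer from one region.
#'
#' For networks beyond a few dozen regions the true smallest eigenvalue
#' falls below double precision, and the computed value is dominated by
#' round-off noise. The returned value is therefore clamped to 0 when it
#' lies within `-1e-12` of zero, and the attribute `below_tol` flags values
#' under `1e-15` as effectively singular at machine precision. For a
#' rigorous strict-positivity statement use [controllability_certificate],
#' which works in log space and does not underflow.
#'
#' @param sys a [stabilize]d system with `rho < 1`.
#' @param node a single control region (id or index).
#' @return the clamped smallest eigenvalue, with attribute `below_tol`
#'   (logical).
#' @export
global_controllability <- function(sys, node) {
  W <- controllability_gramian(sys, node)$W
  lmin <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < -1e-12)
    warning("Gramian eigenvalue ", format(lmin),
            " below PSD tolerance; clamping to 0")
  g <- max(lmin, 0)
  attr(g, "below_tol") <- g < 1e-15
  g
}

#' Certificate of strict positivity for the single-node Gramian
#'
#' For symmetric `A_s` with eigendecomposition `V diag(lambda) V'`, the
#' single-node Gramian factorizes as `W_i = V diag(c) P diag(c) V'` with
#' `c_j = v_ij` and `P_jk = 1 / (1 - lambda_j lambda_k)` a Pick (Cauchy-type)
#' matrix whose determinant has a classical closed form. Hence
#'
#' `log det W_i = sum_j log v_ij^2 + sum_{j<k} 2 log|lambda_j - lambda_k|
#'                - sum_{j,k} log(1 - lambda_j lambda_k)`,
#'
#' computable entirely in log space. `det W_i > 0` (equivalently
#' `lambda_min > 0`, i.e. exact-arithmetic controllability from region `i`)
#' holds iff all eigenvalues of `A_s` are distinct and no component `v_ij`
#' vanishes — the PBH controllability condition for symmetric systems. A
#' certified lower bound `lambda_min >= det(W) / lambda_max^(N-1)` is also
#' reported (in log10), typically astronomically small: the quantitative
#' sense in which single-region control is possible but practically
#' infeasible.
#'
#' @param sys a [stabilize]d system with `rho < 1`.
#' @param node a single control region (id or index).
#' @param gap_tol eigenvalue-distinctness and eigenvector-component
#'   tolerance relative to machine precision.
#' @return list: `controllable` (logical; TRUE when the certificate holds),
#'   `log10_det` (log10 of det W), `log10_lmin_bound` (certified log10 lower
#'   bound on the smallest eigenvalue), `min_gap`, `min_component`.
#' @export
controllability_certificate <- function(sys, node, gap_tol = 1e-12) {
  check_stable(sys)
  ctrl <- if (inherits(node, "control_set")) node else control_set(sys, node)
  if (length(ctrl$K) != 1) stop("certificate is defined for single nodes")
  lam <- sys$values
  ci <- sys$vectors[ctrl$K, ]
  n <- length(lam)
  gaps <- abs(outer(lam, lam, "-"))[lower.tri(diag(n))]
  min_gap <- if (n > 1) min(gaps) else Inf
  min_comp <- min(abs(ci))
  ok <- min_gap > gap_tol && min_comp > gap_tol
  log_det <- sum(log(ci^2)) +
    (if (n > 1) sum(2 * log(gaps)) else 0) -
    sum(log(1 - outer(lam, lam)))
  # lambda_min >= det / lambda_max^(n-1); bound lambda_max by trace
  lmax_ub <- sum(ci^2 / (1 - lam^2))
  log10_lmin <- (log_det - (n - 1) * log(max(lmax_ub, 1))) / log(10)
  list(controllable = ok, log10_det = log_det / log(10),
       log10_lmin_bound = log10_lmin,
       min_gap = min_gap, min_component = min_comp)
}

#' Average controllability of every region
#'
#' `a_i = Trace(W_i)` for the single-node Gramian with `K = {i}`: the energy
#' of the network impulse response from region `i` (the squared H2 norm).
#' Regions with high average controllability can steer the network into many
#' easily reachable states with little input energy; empirically these are
#' the high-strength hubs. The trace is used rather than `Trace(W^{-1})`
#' because the Gramian is typically too ill-conditioned to invert.
#'
#' Computed for all regions at once from the stored eigendecomposition:
#' `a_i = sum_j v_ij^2 / (1 - lambda_j^2)`, the trace of the closed-form
#' Lyapunov solution. For symmetric stable `A_s` this equals
#' `diag((I - A_s^2)^{-1})`, which serves as an independent oracle in the
#' test suite.
#'
#' @param sys a [stabilize]d system with `rho < 1`.
#' @return named numeric vector `a_i >= 1` over regions.
#' @export
average_controllability <- function(sys) {
  check_stable(sys)
  lam <- sys$values
  a <- drop(sys$vectors^2 %*% (1 / (1 - lam^2)))
  stats::setNames(a, sys$regions)
}

#' Modal controllability of every region
#'
#' `phi_i = sum_j (1 - lambda_j^2) v_ij^2`, a scaled aggregate of region
#' `i`'s ability to excite all `N` dynamical modes of `A_s` (per the PBH
#' test, mode `j` is poorly controllable from `i` when `v_ij` is small; the
#' `1 - lambda_j^2` weight emphasizes the fast-decaying, hard-to-reach
#' modes). High-modal regions can push the network into difficult-to-reach
#' states; empirically these are the weakly connected regions. For
#' orthonormal `V` the closed form `phi_i = 1 - (A_s^2)_ii =
#' 1 - sum_j a_ij^2` holds and is used as an independent oracle. Squares
#' make the result invariant to eigenvector sign conventions.
#'
#' @param sys a [stabilize]d system (symmetric; `rho < 1` gives
#'   `phi_i` in `(0, 1]`).
#' @return named numeric vector over regions.
#' @export
modal_controllability <- function(sys) {
  stopifnot(inherits(sys, "stabilized_system"))
  lam <- sys$values
  phi <- drop(sys$vectors^2 %*% (1 - lam^2))
  stats::setNames(phi, sys$regions)
}

# Fast path: smallest/largest eigenvalue of every single-node Gramian,
# reusing the system eigendecomposition (one pair of matmuls + one
# eigenvalue call per region).
single_node_gramian_extremes <- function(sys) {
  check_stable(sys)
  V <- sys$vectors
  lam <- sys$values
  den <- 1 - outer(lam, lam)
  n <- length(lam)
  lmin <- lmax <- numeric(n)
  for (i in seq_len(n)) {
    M <- outer(V[i, ], V[i, ]) / den
    W <- V %*% M %*% t(V)
    ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lmin[i] <- min(ev)
    lmax[i] <- max(ev)
  }
  list(lmin = stats::setNames(lmin, sys$regions),
       lmax = stats::setNames(lmax, sys$regions))
}

#' Full per-region control profile
#'
#' Assembles, for every region of one connectome: average, modal, boundary
#' and global controllability plus weighted degree, as one tidy row per
#' region.
#'
#' @param conn a [connectome].
#' @param sys optional pre-[stabilize]d system (spectral scheme used if
#'   omitted).
#' @param boundary_params list of arguments passed to
#'   [boundary_controllability] (e.g. `n_runs`, `seed`); the boundary
#'   component is deterministic given its seed.
#' @param degree_mode passed to [weighted_degree].
#' @param include character subset of
#'   `c("average", "modal", "boundary", "global")`; dropping `"global"`
#'   (the per-region eigenvalue sweep) or `"boundary"` (the consensus
#'   partition) saves most of the runtime.
#' @return data.frame: `region_id`, `subject`, `scan`, `avg_ctrl`,
#'   `modal_ctrl`, `boundary_ctrl`, `global_ctrl`, `degree` (absent
#'   diagnostics as NA).
#' @export
control_profile <- function(conn, sys = NULL, boundary_params = list(),
                            degree_mode = "sum",
                            include = c("average", "modal", "boundary",
                                        "global")) {
  stopifnot(inherits(conn, "connectome"))
  include <- match.arg(include, several.ok = TRUE)
  if (is.null(sys)) sys <- stabilize(conn)
  n <- length(conn$regions)
  prof <- data.frame(region_id = conn$regions,
                     subject = conn$subject, scan = conn$scan,
                     avg_ctrl = NA_real_, modal_ctrl = NA_real_,
                     boundary_ctrl = NA_real_, global_ctrl = NA_real_,
                     degree = weighted_degree(conn, degree_mode),
                     stringsAsFactors = FALSE, row.names = NULL)
  if ("average" %in% include)
    prof$avg_ctrl <- unname(average_controllability(sys))
  if ("modal" %in% include)
    prof$modal_ctrl <- unname(modal_controllability(sys))
  if ("global" %in% include) {
    ex <- single_node_gramian_extremes(sys)
    prof$global_ctrl <- pmax(unname(ex$lmin), 0)
  }
  if ("boundary" %in% include) {
    bv <- do.call(boundary_controllability, c(list(conn), boundary_params))
    prof$boundary_ctrl <- unname(bv$values[conn$regions])
  }
  prof
}
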