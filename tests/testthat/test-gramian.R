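test_that("edgeless system: Gramian is the input outer product, diagnostics at their limits", {
  sys <- stabilize(connectome(matrix(0, 3, 3)))
  W <- controllability_gramian(sys, 1)$W
  expect_equal(unname(W), diag(c(1, 0, 0)))
  expect_equal(unname(average_controllability(sys)), rep(1, 3))
  expect_equal(unname(modal_controllability(sys)), rep(1, 3))
  g <- global_controllability(sys, 1)
  expect_equal(as.numeric(g), 0)        # rank-1 Gramian: uncontrollable
  expect_true(attr(g, "below_tol"))
})

test_that("2-node worked example: Gramian, trace, modal, and global values are exact", {
  sys <- two_node_system(0.5)
  W <- controllability_gramian(sys, 1)$W
  expect_equal(unname(W), diag(c(16 / 15, 4 / 15)), tolerance = 1e-12)
  Ws <- controllability_gramian(sys, 1, method = "series")$W
  expect_equal(W, Ws, tolerance = 1e-12)
  expect_equal(unname(average_controllability(sys)), c(4 / 3, 4 / 3),
               tolerance = 1e-12)
  expect_equal(unname(modal_controllability(sys)), c(0.75, 0.75),
               tolerance = 1e-12)
  expect_equal(as.numeric(global_controllability(sys, 1)), 4 / 15,
               tolerance = 1e-12)
  # certificate: det W = (16/15)(4/15) = 64/225, computed in log space
  cert <- controllability_certificate(sys, 1)
  expect_true(cert$controllable)
  expect_equal(cert$log10_det, log10(64 / 225), tolerance = 1e-10)
  expect_lte(cert$log10_lmin_bound, log10(4 / 15) + 1e-10)
})

test_that("3-node path: hub node has largest average and smallest modal controllability", {
  As <- matrix(0, 3, 3)
  As[1, 2] <- As[2, 1] <- As[2, 3] <- As[3, 2] <- 0.4
  sys <- as_system(As)
  # oracle: diag((I - A^2)^-1) computed by direct inversion
  oracle <- diag(solve(diag(3) - As %*% As))
  a <- average_controllability(sys)
  expect_equal(unname(a), oracle, tolerance = 1e-12)
  expect_equal(unname(a), c(0.84 / 0.68, 1 / 0.68, 0.84 / 0.68),
               tolerance = 1e-12)
  phi <- modal_controllability(sys)
  expect_equal(unname(phi), c(0.84, 0.68, 0.84), tolerance = 1e-12)
  expect_equal(as.integer(which.max(a)), 2L)
  expect_equal(as.integer(which.min(phi)), 2L)
})

test_that("Lyapunov, series, and closed-form oracles agree on a random stable ensemble", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:50, 1)
    sys <- random_stable_system(n, runif(1, 0.3, 0.95), seed = seed)
    I_A2 <- solve(diag(n) - sys$A_s %*% sys$A_s)
    expect_equal(unname(average_controllability(sys)), diag(I_A2),
                 tolerance = 1e-8)
    expect_equal(unname(modal_controllability(sys)),
                 1 - rowSums(sys$A_s^2), tolerance = 1e-10)
    node <- sample(n, 1)
    Wl <- controllability_gramian(sys, node)$W
    Wser <- controllability_gramian(sys, node, method = "series")$W
    expect_lt(max(abs(Wl - Wser)), 1e-8)
    ev <- eigen(Wl, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(max(ev), 1 - 1e-9)       # W >= e_i e_i'
    expect_gte(min(ev), -1e-10)         # PSD up to round-off
  }
})

test_that("diagnostics approach their weak-coupling limits continuously", {
  base <- random_stable_system(12, 0.9, seed = 3)
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    sys <- as_system(base$A_s * eps / 0.9)
    expect_equal(unname(average_controllability(sys)), rep(1, 12),
                 tolerance = 10 * eps)
    expect_equal(unname(modal_controllability(sys)), rep(1, 12),
                 tolerance = 10 * eps)
  }
})

test_that("multi-node control sets accumulate rank-|K| input structure", {
  sys <- random_stable_system(10, 0.7, seed = 9)
  W12 <- controllability_gramian(sys, c(1, 2))$W
  W1 <- controllability_gramian(sys, 1)$W
  W2 <- controllability_gramian(sys, 2)$W
  # Gramian is additive over disjoint canonical input columns
  expect_equal(W12, W1 + W2, tolerance = 1e-10)
})

test_that("strict positivity certificate holds on connected continuous-weight networks", {
  for (seed in 1:10) {
    conn <- connected_continuous_connectome(60, seed = seed)
    sys <- stabilize(conn)
    node <- ((seed * 7) %% 60) + 1
    cert <- controllability_certificate(sys, node)
    expect_true(cert$controllable)
    expect_true(is.finite(cert$log10_det))
    # lambda_min > 0 in exact arithmetic, yet astronomically small:
    # controllable in principle, practically hard
    expect_lt(cert$log10_lmin_bound, 0)
  }
})

test_that("control profiles assemble all diagnostics consistently", {
  sys <- two_node_system(0.5)
  conn <- connectome(matrix(c(0, 1, 1, 0), 2, 2))  # spectral -> a = 0.5
  prof <- control_profile(conn, boundary_params = list(n_runs = 10, seed = 1))
  expect_equal(nrow(prof), 2)
  expect_equal(prof$avg_ctrl, c(4 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(prof$modal_ctrl, c(0.75, 0.75), tolerance = 1e-12)
  expect_equal(prof$global_ctrl, c(4 / 15, 4 / 15), tolerance = 1e-10)
  expect_equal(unname(prof$degree), c(1, 1))

  edgeless <- control_profile(connectome(matrix(0, 4, 4)),
                              boundary_params = list(n_runs = 5, seed = 1))
  expect_equal(edgeless$avg_ctrl, rep(1, 4))
  expect_equal(edgeless$modal_ctrl, rep(1, 4))
  expect_equal(edgeless$global_ctrl, rep(0, 4))

  # profile covers every region of a realistically sized network
  conn234 <- generate_connectome(generator_params(seed = 2))
  prof234 <- control_profile(conn234, include = c("average", "modal"))
  expect_equal(nrow(prof234), 234)
  expect_true(all(is.na(prof234$boundary_ctrl)))
})
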