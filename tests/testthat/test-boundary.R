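test_that("robust partition recovers planted structure on canonical fixtures", {
  conn <- two_triangle_connectome()
  part <- robust_partition(conn, n_runs = 20, seed = 5)
  expect_equal(part$n_communities, 2)
  expect_equal(unname(part$membership[1:3]), rep(part$membership[[1]], 3))
  expect_equal(unname(part$membership[4:6]), rep(part$membership[[4]], 3))
  expect_false(part$membership[[1]] == part$membership[[4]])

  clique <- connectome(matrix(1, 5, 5) - diag(5))
  expect_equal(robust_partition(clique, n_runs = 10, seed = 1)$n_communities,
               1)

  # determinism under a fixed seed
  p1 <- robust_partition(conn, n_runs = 20, seed = 9)
  p2 <- robust_partition(conn, n_runs = 20, seed = 9)
  expect_identical(p1$membership, p2$membership)

  # edgeless graph: singleton communities
  p0 <- robust_partition(connectome(matrix(0, 4, 4)), n_runs = 5, seed = 1)
  expect_equal(p0$n_communities, 4)
})

test_that("boundary nodes are exactly the regions with community-crossing edges", {
  conn <- two_triangle_connectome()
  part <- robust_partition(conn, n_runs = 20, seed = 5)
  expect_setequal(boundary_nodes(conn, part), c("R003", "R004"))

  clique <- connectome(matrix(1, 4, 4) - diag(4))
  expect_length(boundary_nodes(clique, rep(1, 4)), 0)

  # two fully interconnected communities: every node crosses
  A <- matrix(1, 6, 6) - diag(6)
  conn2 <- connectome(A)
  expect_length(boundary_nodes(conn2, c(1, 1, 1, 2, 2, 2)), 6)
})

test_that("Fiedler bipartition splits paths at the centre and separates components", {
  P4 <- matrix(0, 4, 4)
  P4[cbind(1:3, 2:4)] <- 1
  P4 <- P4 + t(P4)
  halves <- fiedler_bipartition(P4)
  expect_setequal(lapply(halves, sort), list(c(1L, 2L), c(3L, 4L)))

  # 2-node edge
  E2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_setequal(fiedler_bipartition(E2), list(1L, 2L))

  # two disconnected edges: component split
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 1
  expect_setequal(lapply(fiedler_bipartition(D), sort),
                  list(c(1L, 2L), c(3L, 4L)))

  expect_error(fiedler_bipartition(matrix(0, 1, 1)), "at least 2")
})

test_that("boundary values on the two-triangle fixture match the hand-executed recursion", {
  conn <- two_triangle_connectome()
  bv <- boundary_controllability(conn, n_runs = 20, seed = 5)
  expect_equal(bv$N_1, 2)
  # bridge endpoints are first-level boundary nodes with value exactly 1
  expect_equal(unname(bv$values[c("R003", "R004")]), c(1, 1))
  expect_equal(unname(bv$depth[c("R003", "R004")]), c(1L, 1L))
  # remaining four nodes are exposed by the depth-2 triangle splits and
  # receive (6 - 2)/6 = 2/3
  expect_equal(unname(bv$values[c("R001", "R002", "R005", "R006")]),
               rep(2 / 3, 4))
  expect_equal(max(bv$values), 1)
})

test_that("degenerate and edgeless inputs terminate with valid values", {
  bv0 <- boundary_controllability(connectome(matrix(0, 5, 5)), n_runs = 5,
                                  seed = 1)
  expect_equal(bv0$N_1, 0)
  expect_equal(length(unique(bv0$values)), 1)     # all at terminal depth
  expect_true(all(bv0$values > 0 & bv0$values <= 1))

  # single region
  bv1 <- boundary_controllability(connectome(matrix(0, 1, 1)), n_runs = 2,
                                  seed = 1)
  expect_equal(unname(bv1$values), 1)
})

test_that("boundary values lie in (0, 1], weakly decrease with depth, and are seed-deterministic", {
  for (seed in c(2, 11)) {
    conn <- generate_connectome(generator_params(n_regions = 60,
                                                 n_communities = 4,
                                                 seed = seed))
    bv <- boundary_controllability(conn, n_runs = 30, seed = seed)
    expect_true(all(bv$values > 0 & bv$values <= 1))
    ord <- order(bv$depth)
    expect_true(all(diff(bv$values[ord]) <= 1e-12))
    bv2 <- boundary_controllability(conn, n_runs = 30, seed = seed)
    expect_identical(bv$values, bv2$values)
  }
})

test_that("relabelling regions permutes boundary output identically", {
  # equivariance is checked on graphs whose community structure is
  # unambiguous, so the consensus partition is invariant to the run-level
  # randomization
  conn <- two_triangle_connectome()
  set.seed(8)
  perm <- sample(6)
  conn_p <- connectome(conn$A[perm, perm], regions = conn$regions[perm])
  bv <- boundary_controllability(conn, n_runs = 20, seed = 5)
  bv_p <- boundary_controllability(conn_p, n_runs = 20, seed = 5)
  expect_equal(bv_p$values[conn$regions], bv$values[conn$regions])

  conn2 <- generate_connectome(generator_params(n_regions = 30,
                                                n_communities = 3,
                                                p_between = 0.005,
                                                seed = 13))
  set.seed(14)
  perm2 <- sample(30)
  conn2_p <- connectome(conn2$A[perm2, perm2],
                        regions = conn2$regions[perm2])
  part <- robust_partition(conn2, n_runs = 30, seed = 3)
  part_p <- robust_partition(conn2_p, n_runs = 30, seed = 3)
  expect_setequal(boundary_nodes(conn2_p, part_p),
                  boundary_nodes(conn2, part))
})

test_that("least-controllable-first traversal is available and terminates", {
  conn <- generate_connectome(generator_params(n_regions = 40,
                                               n_communities = 3, seed = 4))
  bv <- boundary_controllability(conn, n_runs = 20, seed = 4,
                                 order = "least_avg_ctrl")
  expect_true(all(bv$values > 0 & bv$values <= 1))
  expect_false(anyNA(bv$values))
})
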