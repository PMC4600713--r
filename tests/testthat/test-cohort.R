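test_that("ranking uses ascending order with mid-ranks for ties", {
  expect_equal(rank_regions(c(0.2, 0.5, 0.4)), c(1, 3, 2))
  expect_equal(rank_regions(c(0.3, 0.3)), c(1.5, 1.5))
  set.seed(2)
  for (i in 1:10) {
    v <- sample(runif(20))
    expect_equal(rank_regions(v), order(order(v)))   # sort-based oracle
  }
  expect_error(rank_regions(c(1, NA)), "non-finite")
  expect_error(rank_regions(c(1, Inf)), "non-finite")
})

test_that("rank aggregation is the elementwise mean over scans", {
  expect_equal(aggregate_ranks(list(c(1, 3, 2))), c(1, 3, 2))
  expect_equal(aggregate_ranks(list(c(1, 3, 2), c(2, 3, 1))), c(1.5, 3, 1.5))
  same <- replicate(24, c(4, 1, 2, 3), simplify = FALSE)
  expect_equal(aggregate_ranks(same), c(4, 1, 2, 3))
  expect_error(aggregate_ranks(list()), "no rank")
  expect_error(aggregate_ranks(list(1:3, 1:4)), "unequal")
})

test_that("hub selection takes the k largest with deterministic tie-breaks", {
  v <- c(a = 0.9, b = 0.1, c = 0.8)
  expect_equal(select_control_hubs(v, 2), c("a", "c"))
  expect_equal(select_control_hubs(v, 3), c("a", "c", "b"))
  expect_warning(all3 <- select_control_hubs(v, 5), "all regions")
  expect_length(all3, 3)
  # ties broken lexicographically by region id
  tie <- c(z = 1, m = 1, a = 1, q = 2)
  expect_equal(select_control_hubs(tie, 2), c("q", "a"))
  # top-30 of a 234-region vector
  set.seed(1)
  big <- setNames(runif(234), sprintf("R%03d", 1:234))
  expect_length(select_control_hubs(big, 30), 30)
})

test_that("system enrichment normalizes by system size and sums to 100", {
  labels <- data.frame(region_id = c("a", "b", "x1", "c", "x2", "x3"),
                       system = c("S1", "S1", "S2", "S2", "S2", "S2"))
  enr <- system_enrichment(c("a", "b", "c"), labels)
  expect_equal(enr$norm_pct[enr$system == "S1"], 80)
  expect_equal(enr$norm_pct[enr$system == "S2"], 20)
  expect_equal(sum(enr$norm_pct), 100, tolerance = 1e-9)

  # all hubs in one system
  one <- system_enrichment(c("a", "b"), labels)
  expect_equal(one$norm_pct[one$system == "S1"], 100)

  # hubs spread proportionally to system sizes -> equal normalized shares
  lab2 <- data.frame(region_id = sprintf("r%d", 1:12),
                     system = rep(c("A", "B", "C"), times = c(6, 4, 2)))
  hubs <- c(sprintf("r%d", 1:3), sprintf("r%d", 7:8), "r11")
  enr2 <- system_enrichment(hubs, lab2)
  expect_equal(enr2$norm_pct, rep(100 / 3, 3), tolerance = 1e-9)

  expect_error(system_enrichment(c("a", "zz"), labels), "unlabelled")
})

test_that("system-group hub means match a brute-force group-by", {
  profiles <- expand.grid(region_id = sprintf("r%d", 1:6),
                          subject = c("S1", "S2"), scan = c("1", "2"),
                          stringsAsFactors = FALSE)
  set.seed(4)
  profiles$avg_ctrl <- runif(nrow(profiles), 1, 2)
  labels <- data.frame(region_id = sprintf("r%d", 1:6),
                       system = c("default_mode", "default_mode",
                                  "frontoparietal", "cingulo_opercular",
                                  "dorsal_attention", "visual"))
  hubs <- list(avg_ctrl = c("r1", "r3", "r4", "r5"))
  hm <- system_hub_means(profiles, hubs, labels)
  # brute force for the cognitive_control group (r3, r4)
  rows <- profiles[profiles$region_id %in% c("r3", "r4"), ]
  expect_equal(hm$mean_ctrl[hm$group == "cognitive_control"],
               mean(rows$avg_ctrl))
  per_subj <- tapply(rows$avg_ctrl, rows$subject, mean)
  expect_equal(hm$sd_across_subjects[hm$group == "cognitive_control"],
               sd(per_subj))
  expect_equal(hm$n_hub_members[hm$group == "default_mode"], 1L)
  # single hub in a group: mean equals its own scan-mean
  r1 <- profiles[profiles$region_id == "r1", ]
  expect_equal(hm$mean_ctrl[hm$group == "default_mode"], mean(r1$avg_ctrl))
})

test_that("degree correlations match the closed-form Pearson formula", {
  x <- c(2.1, 3.5, 0.4, 7.7, 5.2, 1.1, 9.9, 4.4, 6.6, 8.8)
  y <- c(1.0, 2.2, 0.2, 6.1, 4.9, 1.4, 9.1, 3.3, 5.8, 7.2)
  res <- degree_correlation(x, y, ranked = FALSE)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 8), tolerance = 1e-12)

  expect_equal(degree_correlation(1:5, 2 * (1:5) + 1, ranked = FALSE)$r, 1)
  expect_equal(degree_correlation(1:5, -(1:5), ranked = FALSE)$r, -1)
  expect_error(degree_correlation(1:5, rep(1, 5)), "zero variance")
  expect_error(degree_correlation(1:2, 1:2), "at least 3")
})

test_that("cohort analysis aggregates per-scan ranks and is deterministic", {
  set.seed(6)
  regions <- sprintf("r%02d", 1:15)
  base <- runif(15, 1, 2)
  make_scan <- function(subject, scan) {
    data.frame(region_id = regions, subject = subject, scan = scan,
               avg_ctrl = base + rnorm(15, 0, 0.05),
               modal_ctrl = 2 - base + rnorm(15, 0, 0.05),
               boundary_ctrl = runif(15),
               global_ctrl = 0, degree = base * 10 + rnorm(15, 0, 0.1),
               stringsAsFactors = FALSE)
  }
  profiles <- rbind(make_scan("S1", "1"), make_scan("S1", "2"),
                    make_scan("S2", "1"), make_scan("S2", "2"))
  labels <- data.frame(region_id = regions,
                       system = rep(cognitive_systems()[4:8], 3))
  res <- cohort_analysis(profiles, labels, k = 5)
  expect_s3_class(res, "cohort_result")
  expect_equal(nrow(res$mean_ranks), 15)
  expect_length(res$hubs$avg_ctrl, 5)
  # avg tracks degree, modal anti-tracks it
  expect_gt(res$correlations$r_ranked[res$correlations$diagnostic ==
                                        "avg_ctrl"], 0.8)
  expect_lt(res$correlations$r_ranked[res$correlations$diagnostic ==
                                        "modal_ctrl"], -0.8)
  # enrichment sums to 100 within each diagnostic
  sums <- tapply(res$enrichment$norm_pct, res$enrichment$diagnostic, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # hand-check one aggregated rank: region r01, avg_ctrl
  scans <- split(profiles, interaction(profiles$subject, profiles$scan,
                                       drop = TRUE))
  hand <- mean(vapply(scans, function(df)
    rank(df$avg_ctrl)[df$region_id == "r01"], numeric(1)))
  expect_equal(res$mean_ranks$avg_ctrl[res$mean_ranks$region_id == "r01"],
               hand)
  res2 <- cohort_analysis(profiles, labels, k = 5)
  expect_identical(res, res2)
})
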