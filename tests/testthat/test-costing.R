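test_that("ambiguity groups match pool-signature sharing", {
  g <- ambiguity_groups(allocate("diagwalks", 15, 3))
  big <- g[g$size > 1, ]
  expect_identical(big$members, I(list(c(1L, 2L), c(14L, 15L))))
  expect_identical(big$main_pool, c(1L, 5L))
  expect_identical(big$control_pool, c(6L, 10L))
  expect_identical(sum(g$size), 15L)

  # transposition decodes uniquely: every group is a singleton
  gt <- ambiguity_groups(allocate("transposition", 64, 6))
  expect_true(all(gt$size == 1L))

  # noreplica groups are the pools themselves
  gn <- ambiguity_groups(allocate("noreplica", 7, 3))
  expect_identical(gn$size, c(3L, 3L, 1L))
  expect_true(all(is.na(gn$control_pool)))
})

test_that("ambiguity groups agree with the brute-force signature partition", {
  for (alg in planner_algorithms()) {
    for (n in c(7, 15, 33)) {
      for (m in c(2, 3, 5)) {
        if (!algorithm_applicable(alg, n, m)) next
        d <- suppressWarnings(allocate(alg, n, m))
        expect_identical(ambiguity_groups(d)$members,
                         I(oracle_signature_partition(d)),
                         label = paste(alg, n, m))
      }
    }
  }
})

test_that("sanger budget follows the squared-group-size formula", {
  expect_identical(sanger_test_count(allocate("noreplica", 2000, 3), 20),
                   119960L)
  expect_identical(sanger_test_count(allocate("noreplica", 128, 4), 7),
                   3584L)
  expect_identical(sanger_test_count(allocate("diagwalks", 15, 3), 1), 8L)
  expect_identical(sanger_test_count(allocate("transposition", 64, 6), 5),
                   0L)
  expect_identical(sanger_test_count(allocate("diagwalks", 64, 6), 0), 0L)
})

test_that("noreplica budget equals the closed form over pool sizes", {
  for (n in c(13, 100, 256, 500)) {
    for (m in c(1, 3, 7, 20)) {
      if (m > n) next
      d <- allocate("noreplica", n, m)
      closed <- as.integer(4 * sum(lengths(d$main_pools)^2))
      expect_identical(sanger_test_count(d, 4), closed)
    }
  }
})

test_that("waiting time is the completion index of the first control pool", {
  expect_identical(waiting_time(allocate("transposition", 64, 6)), 56L)
  expect_identical(waiting_time(allocate("transposition", 128, 8)), 113L)
  expect_identical(waiting_time(allocate("transposition", 2000, 20)), 1901L)
  expect_identical(waiting_time(allocate("diagwalks", 15, 3)), 4L)
  expect_identical(waiting_time(allocate("noreplica", 2000, 17)), 2000L)
  expect_identical(waiting_time(allocate("optreplica", 64, 6)), 64L)

  # closed form (m-1)*p_m + 1 when the cohort divides evenly
  for (n in c(36, 120)) {
    for (m in c(2, 3, 6)) {
      p_m <- n / m
      if (p_m < m) next
      expect_identical(waiting_time(allocate("transposition", n, m)),
                       as.integer((m - 1) * p_m + 1))
    }
  }
  # waiting always within 1..n
  for (alg in planner_algorithms()) {
    w <- waiting_time(suppressWarnings(allocate(alg, 47, 4)))
    expect_gte(w, 1L)
    expect_lte(w, 47L)
  }
})

test_that("cost breakdown conserves pools times price plus tests times price", {
  p3 <- case_study_3()
  cb <- cost_breakdown(allocate("diagwalks", 2000, 20), p3)
  expect_identical(cb$total, 201280)
  expect_identical(cb$num_pools, 200L)
  expect_identical(cb$sanger_tests, 160L)
  expect_identical(cb$waiting, 361L)

  cbt <- cost_breakdown(allocate("transposition", 2000, 20), p3)
  expect_identical(cbt$total, 200000)

  free <- design_parameters(20, 4, 3, 0, 0)
  expect_identical(cost_breakdown(allocate("noreplica", 20, 4), free)$total, 0)

  for (alg in planner_algorithms()) {
    cb <- cost_breakdown(suppressWarnings(allocate(alg, 64, 6)),
                         case_study_1())
    expect_identical(cb$total,
                     cb$num_pools * 1000 + cb$sanger_tests * 8)
    expect_identical(cb$total, cb$ngs_cost + cb$sanger_cost)
  }
})

test_that("configuration sweep finds the printed optima", {
  sw3 <- sweep_configurations(case_study_3(), "noreplica")
  best3 <- sw3[sw3$optimal, ]
  expect_identical(best3$pool_size, 3L)
  expect_identical(best3$num_pools, 667L)
  expect_identical(best3$total_cost, 1626680)

  sw2 <- sweep_configurations(case_study_2(), "noreplica")
  best2 <- sw2[sw2$optimal, ]
  expect_identical(best2$pool_size, 4L)
  expect_identical(best2$num_pools, 32L)
  expect_identical(best2$sanger_tests, 3584L)

  # singleton pools: closed form n*c1 + N_m*n*c2
  p1 <- design_parameters(50, 1, 3, 100, 5)
  sw1 <- sweep_configurations(p1, "noreplica")
  expect_identical(nrow(sw1), 1L)
  expect_identical(sw1$total_cost, 50 * 100 + 3 * 50 * 5)
  expect_true(sw1$optimal)
})

test_that("sweep keeps inapplicable rows and flags exactly one optimum", {
  # transposition at n=10: pool sizes 4..10 have fewer main pools than m
  sw <- sweep_configurations(design_parameters(10, 10, 1, 100, 1),
                             "transposition")
  expect_identical(nrow(sw), 10L)
  expect_identical(sw$applicable, ceiling(10 / sw$pool_size) >= sw$pool_size)
  expect_true(all(is.na(sw$total_cost[!sw$applicable])))
  expect_identical(sum(sw$optimal), 1L)
  expect_false(sw$optimal[!sw$applicable][1])
})

test_that("noreplica NGS cost falls and Sanger cost rises with pool size", {
  p <- design_parameters(173, 15, 4, 900, 7)
  sw <- sweep_configurations(p, "noreplica")
  ngs <- sw$num_pools * p$ngs_cost
  sang <- sw$sanger_tests * p$sanger_cost
  expect_true(all(diff(ngs) <= 0))
  expect_true(all(diff(sang) >= 0))
})

test_that("the flagged optimum equals an independent brute-force minimum", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(10:250, 1)
    mm <- sample(2:12, 1)
    p <- design_parameters(n, mm, sample(0:10, 1),
                           sample(c(0, 50, 1000), 1), sample(c(0, 2, 25), 1))
    alg <- sample(planner_algorithms(), 1)
    sw <- tryCatch(sweep_configurations(p, alg), error = function(e) NULL)
    if (is.null(sw)) next
    costs <- vapply(sw$pool_size[sw$applicable], function(m)
      cost_breakdown(suppressWarnings(allocate(alg, n, m)), p)$total,
      numeric(1))
    expect_identical(sw$total_cost[sw$optimal], min(costs))
    # tie-break: no larger applicable pool size attains the same cost
    larger <- sw$applicable & sw$pool_size > sw$pool_size[sw$optimal]
    expect_true(all(sw$total_cost[larger] > min(costs)))
  }
})

test_that("algorithm comparison reproduces the side-by-side case studies", {
  cmp <- compare_algorithms(case_study_3())
  tot <- as.numeric(cmp$summary[cmp$summary$metric == "total_cost",
                                planner_algorithms()])
  expect_identical(tot, c(1626680, 200000, 200000, 201280))
  # the early-start premium of the diagonal-walk design
  expect_identical(tot[4] - tot[3], 1280)
  wait <- as.numeric(cmp$summary[cmp$summary$metric == "waiting",
                                 planner_algorithms()])
  expect_identical(wait, c(2000, 2000, 1901, 361))

  one <- compare_algorithms(design_parameters(1, 1, 0, 10, 1))
  np <- as.numeric(one$summary[one$summary$metric == "num_pools",
                               planner_algorithms()])
  expect_identical(np, c(1, 2, 2, 2))
})
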