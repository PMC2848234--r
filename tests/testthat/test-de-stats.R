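make_null_ds <- function(g, na, nb, seed) {
  set.seed(seed)
  m <- matrix(rnorm(g * (na + nb)), g, na + nb,
              dimnames = list(sprintf("g%04d", 1:g),
                              c(paste0("a", 1:na), paste0("b", 1:nb))))
  list(ds = expression_dataset(m),
       design = two_group_design(paste0("a", 1:na), paste0("b", 1:nb)))
}

test_that("t-test: textbook case, symmetry, degenerate input", {
  ds <- expression_dataset(matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                                  dimnames = list("g", paste0("e", 1:6))))
  d <- two_group_design(paste0("e", 1:3), paste0("e", 4:6))
  tt <- t_test_probes(ds, d, "pooled")
  expect_equal(abs(tt$statistic), 3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)

  # identical groups -> t = 0, p = 1
  same <- expression_dataset(matrix(c(1, 2, 1, 2), 1, 4,
                                    dimnames = list("g", paste0("e", 1:4))))
  t0 <- t_test_probes(same, two_group_design(c("e1", "e2"), c("e3", "e4")))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)

  # swapping labels negates t, p unchanged
  sw <- t_test_probes(ds, two_group_design(paste0("e", 4:6), paste0("e", 1:3)))
  expect_equal(sw$statistic, -tt$statistic)
  expect_equal(sw$p, tt$p)

  expect_error(t_test_probes(ds, two_group_design("e1", paste0("e", 2:6))),
               ">= 2 experiments")
})

test_that("t-test p-values are uniform under the null", {
  null <- make_null_ds(2000, 4, 4, seed = 123)
  tt <- t_test_probes(null$ds, null$design)
  rate <- mean(tt$p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
  # Kolmogorov-style sanity: roughly uniform deciles
  expect_lt(max(abs(quantile(tt$p, 1:9 / 10) - 1:9 / 10)), 0.05)
})

test_that("WAD matches direct formula evaluation and its ranking property", {
  ds <- expression_dataset(matrix(c(10, 11, 12, 13,
                                    2, 3, 4, 5,
                                    6, 6, 8, 8), 3, 4, byrow = TRUE,
                                  dimnames = list(c("hi", "lo", "mid"),
                                                  paste0("e", 1:4))))
  d <- two_group_design(c("e1", "e2"), c("e3", "e4"))
  w <- wad_statistic(ds, d)
  # independent spreadsheet-style computation
  xbar <- rowMeans(dataset_values(ds))
  weight <- (xbar - min(xbar)) / (max(xbar) - min(xbar))
  diff <- rowMeans(dataset_values(ds)[, 3:4]) - rowMeans(dataset_values(ds)[, 1:2])
  expected <- diff * weight
  expect_equal(setNames(w$wad, w$probe)[names(expected)], expected)
  # max-average probe has weight 1, wad = raw difference
  expect_equal(w$weight[w$probe == "hi"], 1)
  expect_equal(w$wad[w$probe == "hi"], unname(diff["hi"]))

  # equal |difference|: the high-expression gene outranks the low one
  ds2 <- expression_dataset(matrix(c(8, 8, 10, 10,
                                     0, 0, 2, 2,
                                     4, 4, 4, 4), 3, 4, byrow = TRUE,
                                   dimnames = list(c("high", "low", "flat"),
                                                   paste0("e", 1:4))))
  w2 <- wad_statistic(ds2, d)
  expect_lt(w2$rank[w2$probe == "high"], w2$rank[w2$probe == "low"])

  # zero mean difference -> WAD 0
  expect_equal(w2$wad[w2$probe == "flat"], 0)

  # degenerate: all averages equal -> weights 1
  dsc <- expression_dataset(matrix(c(1, 2, 2, 3,
                                     3, 2, 2, 1), 2, 4, byrow = TRUE,
                                   dimnames = list(c("p1", "p2"),
                                                   paste0("e", 1:4))))
  wc <- wad_statistic(dsc, d)
  expect_equal(wc$weight, c(1, 1))
})

test_that("rank product: rank semantics, determinism, null calibration", {
  # probe ranked 1 in every comparison -> RP = 1
  set.seed(9)
  m <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(paste0("g", 1:20), c("a1", "a2", "b1", "b2")))
  m[1, c("b1", "b2")] <- m[1, c("b1", "b2")] + 100  # always top fold change
  ds <- expression_dataset(m)
  d <- two_group_design(c("a1", "a2"), c("b1", "b2"))
  rp <- rank_product(ds, d, n_perm = 10, seed = 1)
  expect_equal(rp$rp[rp$probe == "g1"], 1)
  expect_equal(rp$rank[rp$probe == "g1"], 1)

  # K = 1 comparison: RP equals the fold-change rank itself
  ds1 <- expression_dataset(m[, c("a1", "b1")])
  rp1 <- rank_product(ds1, two_group_design("a1", "b1"), n_perm = 5, seed = 1)
  fc_rank <- rank(-(m[, "b1"] - m[, "a1"]))
  expect_equal(setNames(rp1$rp, rp1$probe)[names(fc_rank)], fc_rank)

  # deterministic given seed; stable across seeds (correlated PFPs)
  rp_a <- rank_product(ds, d, n_perm = 50, seed = 11)
  rp_b <- rank_product(ds, d, n_perm = 50, seed = 11)
  expect_identical(rp_a$pfp, rp_b$pfp)
  rp_c <- rank_product(ds, d, n_perm = 200, seed = 12)
  rp_d <- rank_product(ds, d, n_perm = 200, seed = 13)
  expect_gt(cor(rp_c$pfp[order(rp_c$probe)], rp_d$pfp[order(rp_d$probe)],
                method = "spearman"), 0.9)

  # direction = down mirrors up on negated data
  rp_dn <- rank_product(ds, d, n_perm = 10, seed = 1, direction = "down")
  neg <- expression_dataset(-m)
  rp_neg <- rank_product(neg, d, n_perm = 10, seed = 1, direction = "up")
  expect_equal(rp_dn$rp[order(rp_dn$probe)], rp_neg$rp[order(rp_neg$probe)])

  expect_error(rank_product(ds, d, n_perm = 0, seed = 1), "n_perm")
})

test_that("rank product PFP is calibrated on pure-noise data", {
  null <- make_null_ds(500, 3, 3, seed = 321)
  rp <- rank_product(null$ds, null$design, n_perm = 200, seed = 5)
  expect_lte(mean(rp$pfp < 0.05), 0.08)
})

test_that("multiple-testing adjustment follows the standard formulas", {
  expect_equal(adjust_p(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_p(rep(0.01, 10), "bonferroni"), rep(0.1, 10))
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(adjust_p(rep(1, 5), "holm"), rep(1, 5))
  p <- runif(50)
  for (meth in c("BH", "holm", "bonferroni")) {
    adj <- adjust_p(p, meth)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(adjust_p(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("statistics can feed the filter engine as meta-information", {
  null <- make_null_ds(50, 3, 3, seed = 55)
  tt <- t_test_probes(null$ds, null$design)
  mg <- result_to_meta(tt, "p")
  pl <- evaluate_rule(rule_meta("p", "<", 0.1), null$ds,
                      list(meta = list(p = mg)))
  expect_setequal(pl$members, tt$probe[tt$p < 0.1])
})
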