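test_that("median-based Hedge's g reproduces closed-form worked examples", {
  g1 <- hedges_g(0.58, 0.36, 41, 0.31, 0.30, 34)
  expect_equal(round(g1$g, 1), 0.8)
  g2 <- hedges_g(183, 20, 18, 150, 28, 15)
  expect_equal(round(g2$g, 2), 1.38)
  expect_equal(hedges_g(5, 1, 10, 5, 1, 10)$g, 0)
  # sign follows median1 - median2; magnitude is symmetric under swap
  ga <- hedges_g(1, 1, 10, 3, 1, 10)
  gb <- hedges_g(3, 1, 10, 1, 1, 10)
  expect_lt(ga$g_signed, 0)
  expect_equal(ga$g, gb$g)
  # unit invariance: common rescaling leaves g unchanged
  gc_ <- hedges_g(1000, 1000, 10, 3000, 1000, 10)
  expect_equal(gc_$g, ga$g)
  expect_error(hedges_g(1, 0, 10, 2, 0, 10), "undefined")
  expect_error(hedges_g(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("Wilcoxon rank-sum uses the exact branch for small untied
           samples", {
  w <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3)
  expect_equal(w$method, "exact")
  same <- wilcoxon_ranksum(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)
  expect_match(same$method, "tie")
  # invariance under strictly monotone transforms of the pooled data
  set.seed(41)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  expect_equal(wilcoxon_ranksum(x, y)$p,
               wilcoxon_ranksum(exp(x), exp(y))$p)
  big <- wilcoxon_ranksum(rnorm(20), rnorm(20))
  expect_match(big$method, "approximation")
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "nonempty")
})

test_that("Spearman rho matches hand computation and the base-R estimate", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  s <- spearman_rho(x, y)
  expect_equal(unname(s["rho"]), 0.8)  # 1 - 6*4/(5*24)
  # p from t = rho sqrt((n-2)/(1-rho^2)) on n-2 df
  tt <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(unname(s["p"]), 2 * pt(-tt, 3))
  expect_equal(unname(spearman_rho(1:9, (1:9)^3)["rho"]), 1)
  expect_equal(unname(spearman_rho(1:9, -(1:9))["rho"]), -1)
  # cross-check the estimate against the independent base-R implementation
  set.seed(42)
  a <- rnorm(40); b <- a + rnorm(40)
  expect_equal(unname(spearman_rho(a, b)["rho"]),
               unname(cor(a, b, method = "spearman")))
  # monotone-transform invariance
  expect_equal(spearman_rho(a, b), spearman_rho(exp(a), b^3 + b))
  expect_error(spearman_rho(rep(1, 10), 1:10), "constant")
  expect_error(spearman_rho(1:4, 4:1), "n >= 5")
})

test_that("the KS normality screen accepts normal and rejects exponential
           samples", {
  set.seed(7)
  ok <- vapply(1:100, function(i) ks_normality(rnorm(1000))$p > 0.05,
               logical(1))
  expect_gte(mean(ok), 0.9)
  bad <- vapply(1:100, function(i) ks_normality(rexp(1000))$p < 0.05,
                logical(1))
  expect_gte(mean(bad), 0.95)
  expect_error(ks_normality(rep(3, 10)), "variance")
})

test_that("group tables summarize and contrast metrics the way the field
           reports them", {
  d <- data.frame(
    v = c(10, 12, 14, 30, 31, 29, 50),
    side = c("M", "M", "M", "P", "P", "P", "X"))
  d <- d[d$side != "X", ]
  gt <- group_table(d, "v", "side")
  expect_equal(gt$summary$n, c(3L, 3L))
  expect_equal(gt$summary$median, c(12, 30))
  expect_equal(gt$summary$sd, c(sd(c(10, 12, 14)), sd(c(29, 30, 31))))
  cmp <- gt$comparisons
  expect_equal(cmp$g,
               hedges_g(12, sd(c(10, 12, 14)), 3, 30, sd(c(29, 30, 31)), 3)$g)
  expect_lt(cmp$g_signed, 0)
  # a group with n < 2 is flagged, and its contrast skipped with a reason
  d2 <- data.frame(v = c(1, 2, 3, 9), side = c("M", "M", "M", "P"))
  gt2 <- group_table(d2, "v", "side")
  expect_true(is.na(gt2$summary$sd[gt2$summary$group == "P"]))
  expect_match(gt2$comparisons$note, "skipped")
})

test_that("double-ribbon synapses contribute one analysis row per ribbon", {
  sc <- make_scene(scene_spec("p17-like", seed = 3L), voxelize = FALSE)
  expect_equal(length(unique(sc$truth$synapse_id)), 38L)
  expect_equal(nrow(sc$truth),
               38L + sum(table(sc$truth$synapse_id) == 2L))
})
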