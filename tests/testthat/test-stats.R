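toy_table <- function(means, n = 6, sd = 0, seed = 1) {
  # means: matrix levels_a x levels_b of cell means
  set.seed(seed)
  rows <- expand.grid(a = rownames(means), b = colnames(means),
                      rep = seq_len(n), stringsAsFactors = FALSE)
  rows$value <- means[cbind(rows$a, rows$b)] + rnorm(nrow(rows), 0, sd)
  data.frame(value = rows$value, factor_a = rows$a, factor_b = rows$b,
             replicate_id = rows$rep)
}

test_that("two-way ANOVA matches the hand-computed balanced decomposition", {
  # balanced 2x2, cell means chosen so SS are easy by hand:
  # main effect A = 2, B = 4, no interaction
  m <- matrix(c(10, 12, 14, 16), 2, 2,
              dimnames = list(c("a1", "a2"), c("b1", "b2")))
  tab <- toy_table(m, n = 4, sd = 1, seed = 2)
  res <- two_way_anova(tab)
  expect_equal(res$term, c("factor_a", "factor_b", "factor_a:factor_b",
                           "residuals"))
  # hand sums of squares: SS_A = N/2 * (2/2)^2 * 2 = 4n, SS_B = 16n
  n <- 4
  y <- tab$value
  gm <- mean(y)
  ssa <- sum(tapply(y, tab$factor_a, function(v) length(v) * (mean(v) - gm)^2))
  expect_equal(res$sum_sq[1], ssa, tolerance = 1e-10)
  expect_equal(res$df[1:3], c(1, 1, 1))

  # identical cell distributions ({6,7,8} in every cell): effect sums of
  # squares are exactly 0, so F = 0 and p = 1 for all three terms
  tab0 <- expand.grid(factor_a = c("a1", "a2"), factor_b = c("b1", "b2"),
                      value = c(6, 7, 8), stringsAsFactors = FALSE)
  res0 <- two_way_anova(tab0)
  expect_equal(res0$statistic[1:3], rep(0, 3), tolerance = 1e-10)
  expect_equal(res0$p_value[1:3], rep(1, 3), tolerance = 1e-10)

  expect_error(two_way_anova(data.frame(value = 1:4, factor_a = "x",
                                        factor_b = c("u", "v", "u", "v"))),
               "2 levels")
})

test_that("duplicating every row inflates F without changing directions", {
  m <- matrix(c(10, 11, 13, 15), 2, 2,
              dimnames = list(c("a1", "a2"), c("b1", "b2")))
  tab <- toy_table(m, n = 5, sd = 1.5, seed = 3)
  r1 <- two_way_anova(tab)
  r2 <- two_way_anova(rbind(tab, tab))
  expect_true(all(r2$statistic[1:3] > r1$statistic[1:3]))
  # effect estimates unchanged: cell means identical
  expect_equal(with(tab, tapply(value, list(factor_a, factor_b), mean)),
               with(rbind(tab, tab), tapply(value, list(factor_a, factor_b),
                                            mean)))
})

test_that("Tukey contrasts reduce to the pooled t test for two groups", {
  set.seed(4)
  tab <- data.frame(value = c(rnorm(8, 0), rnorm(8, 1)),
                    factor_a = rep(c("g1", "g2"), each = 8))
  tk <- tukey_hsd(tab)
  tt <- t.test(value ~ factor_a, data = tab, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)

  # three identical groups: all adjusted p ~ 1
  tab3 <- data.frame(value = rep(rnorm(6), 3),
                     factor_a = rep(c("g1", "g2", "g3"), each = 6))
  expect_true(all(tukey_hsd(tab3)$p_adj > 0.999))

  # one separated group owns the two smallest adjusted p values
  tab4 <- data.frame(value = c(rnorm(6, 0, 0.3), rnorm(6, 0.2, 0.3),
                               rnorm(6, 4, 0.3)),
                     factor_a = rep(c("g1", "g2", "g3"), each = 6))
  tk4 <- tukey_hsd(tab4)
  sep <- grepl("g3", tk4$contrast)
  expect_true(max(tk4$p_adj[sep]) < min(tk4$p_adj[!sep]))
  # adjusted p never below the unadjusted pairwise p for k > 2
  p12 <- t.test(tab4$value[tab4$factor_a == "g1"],
                tab4$value[tab4$factor_a == "g2"], var.equal = TRUE)$p.value
  expect_gte(tk4$p_adj[tk4$contrast == "g2-g1"], p12)
})

test_that("Welch df follows the Satterthwaite closed form", {
  # the two-group design of the bacterial co-inoculation comparison
  expect_equal(round(welch_df(6, 0.050, 6, 0.077), 2), 8.58)
  # equal variances, equal n: df is exactly n1 + n2 - 2
  expect_equal(welch_df(8, 1.3, 8, 1.3), 14)
  # never exceeds the pooled df
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    s1 <- runif(1, 0.1, 3); s2 <- runif(1, 0.1, 3)
    expect_lte(welch_df(n1, s1, n2, s2), n1 + n2 - 2 + 1e-12)
  }
})

test_that("welch_t_test agrees with its own summary statistics", {
  set.seed(6)
  a <- rnorm(6, 1.576, 0.05)
  b <- rnorm(6, 1.51, 0.077)
  w <- welch_t_test(a, b)
  expect_equal(w$df, welch_df(6, sd(a), 6, sd(b)), tolerance = 1e-12)
  expect_equal(w$mean_a, mean(a))
  # identical groups: t = 0, p = 1
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})
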