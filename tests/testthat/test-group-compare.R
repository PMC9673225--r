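test_that("the reconstructed IHT-by-outcome table reproduces p = 0.013", {
  tab <- rbind(SB = c(3, 12), MV = c(5, 42), ED = c(5, 5))
  out <- group_compare_categorical(tab, force = "chisq")
  expect_equal(out$statistic, 8.683, tolerance = 1e-3)
  expect_equal(out$df, 2)
  expect_equal(round(out$p_value, 3), 0.013)
})

test_that("homogeneous tables give p = 1 and small tables go to Fisher", {
  expect_equal(group_compare_categorical(rbind(c(10, 10),
                                               c(10, 10)))$p_value, 1)
  small <- rbind(c(2, 9), c(3, 8))   # expected counts < 5
  out <- group_compare_categorical(small)
  expect_equal(out$test_used, "fisher")
  # the IHT table itself has expected counts < 5, so auto picks Fisher
  tab <- rbind(c(3, 12), c(5, 42), c(5, 5))
  expect_equal(group_compare_categorical(tab)$test_used, "fisher")
})

test_that("degenerate tables are rejected", {
  expect_error(group_compare_categorical(rbind(c(0, 0), c(1, 2))),
               "margins")
  expect_error(group_compare_categorical(rbind(c(1.5, 2), c(3, 4))),
               "integers")
})

test_that("identical groups yield p = 1 under pure ties", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 5), y = 7)
  out <- group_compare_continuous(df, y, g)
  expect_equal(out$omnibus$p_value, 1)
  expect_equal(out$family, "kw")
  expect_true(all(out$posthoc$p_adj == 1))
})

test_that("a shifted group is detected and localised by the post hoc", {
  set.seed(15)
  df <- data.frame(
    g = rep(c("g1", "g2", "g3"), each = 50),
    y = c(rnorm(50), rnorm(50), rnorm(50, 2))
  )
  out <- group_compare_continuous(df, y, g)
  expect_lt(out$omnibus$p_value, 0.001)
  ph <- out$posthoc
  involves3 <- ph$group1 == "g3" | ph$group2 == "g3"
  expect_true(all(ph$p_adj[involves3] < 0.01))
  expect_true(all(ph$p_adj[!involves3] > 0.05))
})

test_that("two normal groups reduce to the equal-variance t test", {
  set.seed(33)
  df <- data.frame(g = rep(c("a", "b"), each = 40),
                   y = c(rnorm(40), rnorm(40, 0.5)))
  out <- group_compare_continuous(df, y, g, family = "anova")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(out$omnibus$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(out$omnibus$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("the normality screen routes skewed data to Kruskal-Wallis", {
  set.seed(3)
  df <- data.frame(g = rep(c("a", "b"), each = 60),
                   y = c(rlnorm(60), rlnorm(60, 0.2)))
  expect_equal(group_compare_continuous(df, y, g)$family, "kw")
  dfn <- data.frame(g = rep(c("a", "b"), each = 60),
                    y = rnorm(120))
  expect_equal(group_compare_continuous(dfn, y, g)$family, "anova")
})

test_that("undersized groups are rejected", {
  df <- data.frame(g = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(group_compare_continuous(df, y, g), "at least 2")
  df1 <- data.frame(g = rep("a", 5), y = rnorm(5))
  expect_error(group_compare_continuous(df1, y, g), "2 groups")
})
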