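test_that("Kruskal-Wallis H matches hand-ranked computation", {
  # identical constant groups: every observation tied, no evidence
  expect_equal(kruskalWallis(list(a = c(5, 5, 5), b = c(5, 5)))$H, 0)

  # tie-free toy data: H from the explicit rank formula
  kw <- kruskalWallis(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  handH <- function(groups) {
    x <- unlist(groups); r <- rank(x); n <- length(x)
    sizes <- vapply(groups, length, 1L)
    ends <- cumsum(sizes); starts <- ends - sizes + 1L
    R <- mapply(function(a, b) sum(r[a:b]), starts, ends)
    12 / (n * (n + 1)) * sum(R^2 / sizes) - 3 * (n + 1)
  }
  expect_equal(kw$H, handH(list(c(1, 2, 3), c(4, 5, 6))))
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)

  # two-group H equals the squared rank-sum z on tie-free data
  set.seed(8)
  g1 <- rnorm(12); g2 <- rnorm(15)
  H <- kruskalWallis(list(a = g1, b = g2))$H
  r <- rank(c(g1, g2)); n1 <- 12; n2 <- 15; n <- n1 + n2
  z <- (sum(r[1:n1]) - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-12)

  expect_error(kruskalWallis(list(a = 1:3)), "2 groups")
  expect_error(kruskalWallis(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("chi-square test matches hand computation on printed tables", {
  prop <- matrix(c(20, 10, 40, 20), 2)  # perfectly proportional
  ct <- chiSquareTest(prop)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p, 1)
  diag20 <- chiSquareTest(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag20$statistic, 20)  # sum (O-E)^2/E with E = 5 everywhere
  expect_error(chiSquareTest(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(chiSquareTest(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  # correction flag is honoured
  t2 <- matrix(c(12, 5, 6, 14), 2)
  expect_lt(chiSquareTest(t2, correct = TRUE)$statistic,
            chiSquareTest(t2)$statistic)
})

test_that("Cohen's d uses average-variance pooling and is antisymmetric", {
  expect_equal(round(cohensD(44.22, 7.94, 32.68, 7.30), 2), 1.51)
  expect_equal(round(abs(cohensD(46.83, 9.83, 60.99, 11.11)), 2), 1.35)
  expect_equal(round(cohensD(8.60, 8.36, 6.16, 7.36), 2), 0.31)
  expect_equal(cohensD(5, 1, 5, 2), 0)
  set.seed(2)
  for (i in 1:10) {
    m <- rnorm(2, 0, 5); s <- runif(2, 0.5, 3)
    expect_equal(cohensD(m[1], s[1], m[2], s[2]),
                 -cohensD(m[2], s[2], m[1], s[1]))
  }
  expect_error(cohensD(1, 0, 2, 0), "undefined")
  x <- rnorm(20); y <- rnorm(10)
  expect_equal(cohensDFromSamples(x, y),
               cohensD(mean(x), sd(x), mean(y), sd(y)))
})

test_that("programmed standardized differences are recovered in median", {
  set.seed(77)
  for (delta in c(0.5, 1.0, 1.5)) {
    ds <- replicate(200, {
      g <- drawTwoGroups(145, 9, delta)
      cohensDFromSamples(g$community, g$hospital)
    })
    expect_lt(abs(median(ds) - delta), 0.1)
  }
})

test_that("Spearman matrix is monotone-invariant with NA for constants", {
  set.seed(12)
  df <- data.frame(x = rnorm(50))
  df$ycube <- df$x^3
  df$z <- rnorm(50)
  df$const <- 1
  rho <- spearmanMatrix(df)
  expect_equal(rho["x", "x"], 1)
  expect_equal(rho["x", "ycube"], 1)
  expect_true(is.na(rho["const", "x"]))
  expect_equal(rho, t(rho))
  set.seed(13)
  big <- data.frame(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(spearmanMatrix(big)["a", "b"]), 0.1)
  expect_error(spearmanMatrix(df[1:2, ]), "3 rows")
})

test_that("group comparison table mirrors availability and signs", {
  set.seed(3)
  ft <- data.frame(
    outcome = rep(c("community", "hospital"), c(30, 10)),
    up = c(rnorm(30, 10), rnorm(10, 5)),     # community higher: d > 0
    down = c(rnorm(30, 2), rnorm(10, 6)),    # hospital higher: d < 0
    sparse = c(rnorm(25), rep(NA, 15)))
  cmp <- compareGroups(ft, skip = "outcome")
  expect_equal(cmp$feature, c("up", "down", "sparse"))
  expect_gt(cmp$d[1], 0)
  expect_lt(cmp$d[2], 0)
  expect_equal(cmp$n_C[3], 25)
  expect_equal(cmp$n_H[3], 0)
  expect_true(is.na(cmp$p[3]))
  expect_equal(cmp$n_C[1], 30)

  ranked <- rankFeatures(cmp)
  expect_equal(ranked$p, sort(ranked$p, na.last = TRUE))
})

test_that("feature ranking orders by p then by |d|", {
  cmp <- data.frame(feature = c("a", "b", "c", "d"),
                    p = c(0.001, 0.04, 0.0005, 0.001),
                    d = c(1.2, 0.2, 0.5, 0.4))
  r <- rankFeatures(cmp)
  expect_equal(r$feature, c("c", "a", "d", "b"))
  expect_equal(nrow(rankFeatures(cmp[0, ])), 0L)
})

test_that("cross-validated random forest scores a separable feature", {
  set.seed(1)
  x <- data.frame(f = c(rnorm(48, 0), rnorm(6, 10)))
  y <- rep(c("community", "hospital"), c(48, 6))
  ev <- evaluateRf(x, y, ntree = 200)
  expect_equal(nrow(ev$perFold), 3L)
  expect_false(any(ev$perFold$flagged))  # >= 1 hospital case per fold
  expect_equal(ev$summary$mean[ev$summary$metric == "auc"], 1)
  expect_equal(ev$summary$mean[ev$summary$metric == "sensitivity"], 100)
  ev2 <- evaluateRf(x, y, ntree = 200)
  expect_identical(ev$perFold, ev2$perFold)  # fixed random state

  # stratification keeps >= 1 hospital case per fold at n_H = 3
  y3 <- rep(c("community", "hospital"), c(48, 3))
  ev3 <- evaluateRf(data.frame(f = rnorm(51)), y3, ntree = 100)
  expect_false(any(ev3$perFold$flagged))
  expect_error(evaluateRf(x, rep("community", 54)), "both outcome")
})

test_that("label permutation drives the forest to chance AUC", {
  set.seed(9)
  x <- data.frame(f = rnorm(57))
  y <- rep(c("community", "hospital"), c(48, 9))
  aucs <- replicate(100, {
    ev <- evaluateRf(x[sample(57), , drop = FALSE], y, ntree = 60,
                     seed = sample.int(1e6, 1))
    mean(ev$perFold$auc, na.rm = TRUE)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
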