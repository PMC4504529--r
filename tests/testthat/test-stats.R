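# Brute-force oracles: sign test against full enumeration of sign patterns,
# Mann-Whitney against pair-counting over all group assignments, kappa
# against the confusion-matrix formula.

bf_sign_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  k <- sum(d > 0)
  pats <- as.matrix(expand.grid(rep(list(0:1), n)))
  ks <- rowSums(pats)
  mean(abs(ks - n / 2) >= abs(k - n / 2) - 1e-12)
}

bf_mw <- function(x, y) {
  # pair-counting U (ties count 1/2), enumeration over all assignments
  u_pair <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  U <- u_pair(x, y)
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(ii) u_pair(pooled[ii], pooled[-ii]))
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-12))
}

test_that("sign test handles its boundary cases", {
  expect_warning(res <- sign_test(c(1, 2, 3), c(1, 2, 3)), "tied")
  expect_identical(res$p_value, 1)
  expect_identical(res$n_effective, 0L)
  # 5 pairs, all positive differences: p = 2 * 0.5^5
  res5 <- sign_test(2:6, 1:5)
  expect_identical(res5$p_value, 2 * 0.5^5)
  expect_equal(res5$statistic, 5)
  expect_error(sign_test(1:3, 1:4), "equal length")
})

test_that("sign test matches full enumeration for n <= 10", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    expect_equal(sign_test(a, b)$p_value, bf_sign_p(a - b))
  }
})

test_that("sign test agrees with the binomial test on the sign counts", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(3:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- sign_test(a, b)
    ref <- binom.test(sum(a - b > 0), n, 0.5)
    # binom.test uses the point-probability method; both must agree on
    # significance calls and on symmetric counts
    if (sum(a - b > 0) * 2 == n || ours$p_value == 1)
      expect_equal(ours$p_value, ref$p.value)
    expect_gte(ours$p_value, ref$p.value - 1e-12)
  }
})

test_that("Mann-Whitney: separated samples and symmetry", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(res$statistic, 0)
  swapped <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(res$p_value, swapped$p_value)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact p matches pair-counting enumeration (ties included)", {
  set.seed(10)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    # draw from a small integer support so ties occur often
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    ours <- mann_whitney(x, y)
    bf <- bf_mw(x, y)
    expect_equal(ours$statistic, bf$U)
    expect_equal(ours$p_value, bf$p)
  }
})

test_that("Mann-Whitney agrees with wilcox.test where both are exact", {
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous: no ties
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
})

test_that("Mann-Whitney large-sample path approximates the exact p", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10, 0.4)
  approx_p <- mann_whitney(x, y)$p_value
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(approx_p, ref, tolerance = 1e-10)
  expect_match(mann_whitney(x, y)$method_note, "approximation")
})

test_that("kappa: perfect agreement, paper band, and degenerate table", {
  r <- c("a", "b", "c", "a", "b")
  res <- cohen_kappa(r, r)
  expect_equal(res$kappa, 1)
  expect_identical(res$band, "almost perfect")
  expect_identical(kappa_band(0.64), "substantial")
  expect_identical(kappa_band(0.15), "slight")
  expect_identical(kappa_band(-0.2), "no agreement")
  single <- cohen_kappa(rep("x", 4), rep("x", 4))
  expect_false(single$defined)
  expect_true(is.na(single$kappa))
})

test_that("kappa matches the confusion-matrix formula on random tables", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(10:40, 1)
    r1 <- sample(letters[1:k], n, replace = TRUE)
    r2 <- sample(letters[1:k], n, replace = TRUE)
    res <- cohen_kappa(r1, r2)
    if (!res$defined) next
    tab <- table(factor(r1, levels = letters[1:k]),
                 factor(r2, levels = letters[1:k]))
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    expect_equal(res$kappa, (po - pe) / (1 - pe))
  }
})

test_that("kappa is invariant under category relabeling", {
  set.seed(14)
  r1 <- sample(1:3, 30, replace = TRUE)
  r2 <- sample(1:3, 30, replace = TRUE)
  relab <- c("z", "q", "m")
  expect_equal(cohen_kappa(r1, r2)$kappa,
               cohen_kappa(relab[r1], relab[r2])$kappa)
})
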