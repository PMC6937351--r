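test_that("exact test reproduces the hand-enumerated separation case", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1) # 2 of the 20 labelings are this extreme
  expect_identical(res$method, "exact")
})

test_that("identical multisets give p = 1", {
  x <- c(1, 2, 2, 5)
  res <- mannWhitneyU(x, x)
  expect_equal(res$p, 1)
  expect_equal(res$u, length(x)^2 / 2)
})

test_that("U + U' = n1 n2 and U stays in range", {
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(2:10, 1)
    n2 <- sample(2:10, 1)
    x <- sample(1:6, n1, replace = TRUE) # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    u1 <- mannWhitneyU(x, y, mode = "normal")$u
    u2 <- mannWhitneyU(y, x, mode = "normal")$u
    expect_equal(u1 + u2, n1 * n2)
    expect_gte(u1, 0)
    expect_lte(u1, n1 * n2)
  }
})

test_that("exact p matches independent full enumeration for all n1, n2 <= 6", {
  set.seed(33)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      for (rep in 1:3) {
        ## mix of continuous and tied data
        x <- if (rep == 3) sample(1:4, n1, replace = TRUE) else rnorm(n1)
        y <- if (rep == 3) sample(1:4, n2, replace = TRUE) else rnorm(n2)
        res <- mannWhitneyU(x, y, mode = "exact")
        expect_equal(res$u, pairCountU(x, y), tolerance = 1e-12)
        expect_equal(res$p, enumerationP(x, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("tie-free exact p agrees with the reference implementation", {
  set.seed(44)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    ours <- mannWhitneyU(x, y, mode = "exact")$p
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("normal approximation agrees with the reference implementation", {
  set.seed(55)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- rnorm(45, 0.2)
    ours <- mannWhitneyU(x, y, mode = "normal")$p
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
    ## with heavy ties (tie-corrected variance path)
    xt <- sample(1:5, 25, replace = TRUE)
    yt <- sample(1:5, 30, replace = TRUE)
    ourT <- mannWhitneyU(xt, yt, mode = "normal")$p
    refT <- suppressWarnings(
      wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(ourT, refT, tolerance = 1e-10)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(66)
  x <- rnorm(8)
  y <- rnorm(9, 0.5)
  base <- mannWhitneyU(x, y)
  for (f in list(function(v) exp(v), function(v) v^3,
    function(v) 5 * v - 2
  )) {
    tr <- mannWhitneyU(f(x), f(y))
    expect_equal(tr$u, base$u)
    expect_equal(tr$p, base$p)
  }
})

test_that("exact test size never exceeds the nominal level under the null", {
  set.seed(77)
  rejections <- replicate(400, {
    x <- rnorm(5)
    y <- rnorm(5)
    mannWhitneyU(x, y, mode = "exact")$p < 0.05
  })
  ## guaranteed by construction; simulation bound with slack for MC noise
  expect_lte(mean(rejections), 0.055)
})
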