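test_that("constructor validates shape, range, diagonal and symmetry", {
  ok <- cor_matrix(matrix(c(1, .5, .5, 1), 2), labels = c("a", "b"), n = 100)
  expect_equal(ok$p, 2)
  expect_equal(ok$values["a", "b"], 0.5)

  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(cor_matrix(bad, labels = c("a", "b"), n = 10), "out of range")
  asym <- matrix(c(1, .5, .4, 1), 2)
  expect_error(cor_matrix(asym, labels = c("a", "b"), n = 10), "asymmetric")
  baddiag <- matrix(c(1, .5, .5, .9), 2)
  expect_error(cor_matrix(baddiag, labels = c("a", "b"), n = 10), "diagonal")
  expect_error(cor_matrix(matrix(c(1, .5, .5, 1), 2), labels = c("a", "b"),
                          n = -5), "positive integer")
})

test_that("CSV round trip preserves values, labels, n and kind", {
  d <- random_data_cor(60, 6, seed = 11)
  m <- cor_matrix(d$S, labels = letters[1:6], kind = "full", n = 60)
  path <- tempfile(fileext = ".csv")
  write_corr_csv(m, path)
  m2 <- read_corr_csv(path)
  expect_equal(m2$values, m$values, tolerance = 1e-9)
  expect_identical(m2$labels, m$labels)
  expect_identical(m2$n, m$n)
  expect_identical(m2$kind, "full")

  # identity matrix reads back with zero off-diagonals
  idp <- tempfile(fileext = ".csv")
  write_corr_csv(cor_matrix(diag(15), labels = id15(), n = 100), idp)
  mid <- read_corr_csv(idp)
  expect_true(all(mid$values[upper.tri(mid$values)] == 0))

  # corrupt an entry beyond [-1, 1]
  bad <- m$values
  bad[1, 2] <- bad[2, 1] <- 1.2
  badpath <- tempfile(fileext = ".csv")
  df <- data.frame(label = m$labels, bad)
  colnames(df) <- c("", m$labels)
  utils::write.csv(df, badpath, row.names = FALSE)
  expect_error(read_corr_csv(badpath, n = 60), "out of range")
})

test_that("Fisher-z pooling averages on the z scale and is idempotent and
           order-invariant", {
  mk <- function(r) cor_matrix(matrix(c(1, r, r, 1), 2),
                               labels = c("a", "b"), n = 50)
  # identical tables pool to themselves
  expect_equal(fisher_average(list(mk(.5), mk(.5)))$values[1, 2], 0.5)
  # a single table is returned unchanged
  one <- fisher_average(list(mk(.37)))
  expect_equal(one$values[1, 2], 0.37)
  # direct evaluation of tanh(mean(atanh(r)))
  got <- fisher_average(list(mk(.3), mk(.5)))$values[1, 2]
  expect_equal(got, tanh((atanh(.3) + atanh(.5)) / 2), tolerance = 1e-12)
  expect_equal(got, 0.4048305, tolerance = 1e-6)
  # permutation equivariance in table order
  tabs <- lapply(c(.1, .4, .6), mk)
  expect_equal(fisher_average(tabs)$values,
               fisher_average(rev(tabs))$values)
  # pooled n defaults to the sum of table n
  expect_equal(fisher_average(tabs)$n, 150L)
  # unit correlations cannot be transformed
  expect_error(fisher_average(list(mk(1), mk(.2))), "magnitude 1")
  # mismatched labels refuse to pool
  other <- cor_matrix(matrix(c(1, .2, .2, 1), 2), labels = c("x", "y"),
                      n = 50)
  expect_error(fisher_average(list(mk(.3), other)), "mismatched labels")
})

test_that("partial transform matches closed forms and the regression
           residual oracle", {
  # identity in, identity out: independent variables have zero partials
  idm <- cor_matrix(diag(3), labels = letters[1:3], n = 100)
  expect_equal(to_partial(idm)$values, idm$values, ignore_attr = TRUE)
  # with p = 2 there is nothing to condition on
  m2 <- cor_matrix(matrix(c(1, .5, .5, 1), 2), labels = c("a", "b"), n = 50)
  expect_equal(to_partial(m2)$values[1, 2], 0.5)
  # equicorrelated 3x3: closed form (r - r^2) / (1 - r^2) = 1/3
  m3 <- cor_matrix(matrix(.5, 3, 3) + diag(.5, 3), labels = letters[1:3],
                   n = 50)
  p3 <- to_partial(m3)
  expect_equal(p3$values[lower.tri(p3$values)], rep(1 / 3, 3))
  expect_identical(p3$kind, "partial")

  # brute-force oracle: residual correlations from least-squares fits
  for (seed in 1:5) {
    p <- sample(4:8, 1)
    d <- random_data_cor(80, p, seed = 100 + seed)
    m <- cor_matrix(d$S, labels = paste0("V", 1:p), n = 80)
    pc <- to_partial(m)$values
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      expect_equal(pc[i, j], residual_pcor(d$X, i, j), tolerance = 1e-10)
  }
})

test_that("partial transform stays in range and polices definiteness", {
  # diagonal-perturbed identity stays within [-1, 1]
  set.seed(9)
  for (k in 1:10) {
    v <- diag(6)
    eps <- matrix(rnorm(36, sd = .05), 6)
    v <- v + (eps + t(eps)) / 2
    diag(v) <- 1
    m <- cor_matrix(v, labels = letters[1:6], n = 100)
    pc <- to_partial(m)$values
    expect_true(all(abs(pc) <= 1 + 1e-12))
  }
  # a singular matrix errors with the offending eigenvalue, unless repaired
  sing <- matrix(1, 3, 3)
  sing[1, 2] <- sing[2, 1] <- 1 - 1e-14
  m <- cor_matrix(sing, labels = letters[1:3], n = 10)
  expect_error(to_partial(m), "eigenvalue")
  rep <- to_partial(m, repair_pd = TRUE)
  expect_true(all(is.finite(rep$values)))
  # partial kind is refused as input
  expect_error(to_partial(rep), "full correlation")
})
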