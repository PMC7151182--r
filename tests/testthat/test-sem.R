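one_factor_spec <- function(labels, name = "1f") {
  L <- matrix(NA_real_, length(labels), 1,
              dimnames = list(labels, "F1"))
  model_spec(name, "factor", labels, lambda_pattern = L)
}

test_that("build_sigma assembles the LISREL form and the precision form", {
  # zero loadings + unit residuals = identity
  spec <- model_spec("null", "factor", letters[1:3],
                     lambda_pattern = matrix(0, 3, 1),
                     theta_pattern = diag(NA_real_, 3))
  expect_equal(build_sigma(spec, rep(1, 3)), diag(3), ignore_attr = TRUE)
  # single factor, loadings .8, residuals .36: off-diagonals are .64
  s1 <- one_factor_spec(letters[1:3])
  Sig <- build_sigma(s1, c(.8, .8, .8, .36, .36, .36))
  expect_equal(Sig[upper.tri(Sig)], rep(.64, 3))
  expect_equal(diag(Sig), rep(1, 3), ignore_attr = TRUE)
  # saturated network at precision solve(S) reproduces S
  d <- random_data_cor(50, 4, seed = 41)
  labels <- letters[1:4]
  sat <- build_network_model(t(combn(labels, 2)), labels, name = "sat")
  K <- solve(d$S)
  th <- c(diag(K), K[cbind(match(sat$edges$pairs[, 1], labels),
                           match(sat$edges$pairs[, 2], labels))])
  expect_equal(build_sigma(sat, th), d$S, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("analytic gradients match central differences on every form", {
  d <- random_data_cor(80, 6, seed = 43)
  S <- d$S
  ldS <- determinant(S)$modulus[1]
  fm <- factor_map(list(A = c("V1", "V2", "V3"), B = c("V4", "V5", "V6")))
  specs <- list(
    corr = local({
      L <- matrix(c(NA, NA, NA, 0, 0, 0, 0, 0, 0, NA, NA, NA), 6, 2)
      Psi <- matrix(c(1, NA, NA, 1), 2)
      model_spec("c", "factor", paste0("V", 1:6), lambda_pattern = L,
                 psi_pattern = Psi)
    }),
    hier = suppressWarnings(build_hierarchical(fm)),
    net = build_network_model(cbind(c("V1", "V2"), c("V4", "V5")),
                              paste0("V", 1:6)))
  for (spec in specs) {
    set.seed(7)
    th <- netlvm:::start_values(spec, S, 1)
    g <- netlvm:::ml_objective(spec, th, S, ldS)$grad
    gn <- vapply(seq_along(th), function(k) {
      h <- 1e-6
      tp <- th; tm <- th
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (netlvm:::ml_objective(spec, tp, S, ldS, want_grad = FALSE)$f -
         netlvm:::ml_objective(spec, tm, S, ldS, want_grad = FALSE)$f) /
        (2 * h)
    }, numeric(1))
    expect_equal(g, gn, tolerance = 1e-5)
  }
})

test_that("the discrepancy is zero at equality, positive elsewhere, and the
           chi-square uses (n - 1)", {
  for (seed in 1:5) {
    d <- random_data_cor(60, 5, seed = 50 + seed)
    expect_equal(f_ml_discrepancy(d$S, d$S), 0, tolerance = 1e-12)
    d2 <- random_data_cor(60, 5, seed = 70 + seed)
    expect_gt(f_ml_discrepancy(d$S, d2$S), 0)
  }
  # independence model on p = 2, r = .5, n = 101: chi2 = -100 log(.75)
  m <- cor_matrix(matrix(c(1, .5, .5, 1), 2), labels = c("a", "b"), n = 101)
  f <- fit_ml(build_baseline(c("a", "b")), m, n_starts = 1)
  expect_equal(f$chi2, -100 * log(0.75), tolerance = 1e-6)
  expect_equal(f$df, 1)
})

test_that("saturated models fit perfectly and population matrices are
           recovered exactly", {
  d <- random_data_cor(50, 4, seed = 61)
  labels <- letters[1:4]
  m <- cor_matrix(d$S, labels = labels, n = 50)
  sat <- build_network_model(t(combn(labels, 2)), labels, name = "sat")
  fs <- fit_ml(sat, m, n_starts = 1)
  expect_equal(fs$f_ml, 0, tolerance = 1e-8)
  expect_equal(fs$df, 0)
  expect_equal(fs$sigma_hat, m$values, tolerance = 1e-5, ignore_attr = TRUE)

  # single factor fitted to its own population matrix: chi2 ~ 0 and
  # loadings recovered to 1e-4
  L <- matrix(c(.8, .7, .6), 3, 1, dimnames = list(letters[1:3], "F1"))
  pop <- factor_population_sigma(L)
  sp <- cor_matrix(pop$sigma, labels = letters[1:3], n = 1000)
  ft <- fit_ml(one_factor_spec(letters[1:3]), sp, n_starts = 5)
  expect_equal(ft$chi2, 0, tolerance = 1e-6)
  expect_equal(abs(ft$theta_hat[1:3]), c(.8, .7, .6), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_true(ft$converged)
})

test_that("the optimizer agrees with exhaustive grid search on tiny
           specifications", {
  # one free loading; everything else fixed
  L <- matrix(c(NA, .8), 2, 1)
  spec1 <- model_spec("g1", "factor", c("a", "b"), lambda_pattern = L,
                      theta_pattern = diag(c(.51, .36)))
  m <- cor_matrix(matrix(c(1, .42, .42, 1), 2), labels = c("a", "b"),
                  n = 200)
  got <- fit_ml(spec1, m, n_starts = 3)
  oracle <- grid_fit(spec1, m, lower = 0.1, upper = 0.9)
  expect_equal(got$theta_hat, oracle$par, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(got$f_ml, oracle$value, tolerance = 1e-6)

  # two free parameters: loading and its residual variance
  spec2 <- model_spec("g2", "factor", c("a", "b"), lambda_pattern = L,
                      theta_pattern = diag(c(NA, .36)))
  got2 <- fit_ml(spec2, m, n_starts = 3)
  oracle2 <- grid_fit(spec2, m, lower = c(0.1, 0.2), upper = c(0.9, 1.2))
  expect_equal(got2$theta_hat, oracle2$par, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("frozen-weight generalization has its closed forms and
           symmetries", {
  d <- random_data_cor(100, 5, seed = 81)
  labels <- paste0("V", 1:5)
  m <- cor_matrix(d$S, labels = labels, n = 100)
  fit <- fit_ml(one_factor_spec(labels), m, n_starts = 3)
  # a model fitted to its own population matrix generalizes perfectly to it
  L <- matrix(c(.8, .7, .6, .5, .4), 5, 1, dimnames = list(labels, "F1"))
  pop <- factor_population_sigma(L)
  popm <- cor_matrix(pop$sigma, labels = labels, n = 1000)
  popfit <- fit_ml(one_factor_spec(labels), popm, n_starts = 3)
  selfval <- cor_matrix(pop$sigma, labels = labels, n = 400)
  expect_equal(eval_fixed(popfit, selfval), 0, tolerance = 1e-8)
  # evaluating the training matrix rescales chi2 by (n_val - 1)/(n - 1)
  m400 <- cor_matrix(d$S, labels = labels, n = 400)
  expect_equal(eval_fixed(fit, m400), fit$chi2 * 399 / 99, tolerance = 1e-8)
  # label order of the validation matrix does not matter
  perm <- c(3, 1, 5, 2, 4)
  mperm <- cor_matrix(d$S[perm, perm], labels = labels[perm], n = 400)
  expect_equal(eval_fixed(fit, mperm), eval_fixed(fit, m400),
               tolerance = 1e-10)
  # independence implied matrix: gen chi2 = -(n - 1) log det S
  base <- fit_ml(build_baseline(labels), m, n_starts = 1)
  expect_equal(eval_fixed(base, m400), -399 * determinant(d$S)$modulus[1],
               tolerance = 1e-6)
})

test_that("df accounting and empirical identification checks work", {
  labels <- id15()
  expect_equal(count_df(build_baseline(labels)), 105)
  e73 <- t(combn(labels, 2))[1:73, ]
  expect_equal(count_df(build_network_model(e73, labels)), 32)
  expect_equal(count_df(build_network_model(t(combn(labels, 2)), labels)), 0)
  # over-parameterization is refused at construction
  expect_error(model_spec("bad", "factor", letters[1:2],
                          lambda_pattern = matrix(NA_real_, 2, 2)),
               "over-parameterized")
  # a two-indicator factor inside a larger battery is locally unidentified
  L <- matrix(0, 4, 1)
  L[1:2, 1] <- NA
  unid <- model_spec("unid", "factor", letters[1:4], lambda_pattern = L)
  d <- random_data_cor(200, 4, seed = 91)
  m <- cor_matrix(d$S, labels = letters[1:4], n = 200)
  expect_warning(fu <- fit_ml(unid, m, n_starts = 3), "not identified")
  expect_false(fu$identified)
})

test_that("simulated chi-squares are calibrated against the reference
           distribution", {
  # quick version (acceptance runs the full 200-replicate study): 40
  # replicates of a correctly specified one-factor model, n = 1000
  labels <- letters[1:5]
  L <- matrix(.7, 5, 1, dimnames = list(labels, "F1"))
  pop <- factor_population_sigma(L)
  spec <- one_factor_spec(labels)
  chis <- vapply(1:40, function(i) {
    m <- sample_correlation(pop, 1000, seed = 4000 + i)
    fit_ml(spec, m, n_starts = 2)$chi2
  }, numeric(1))
  expect_equal(mean(chis), spec$df, tolerance = 0.25) # df = 5, se ~ .5
})
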