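test_that("OLS coefficients match an independent normal-equations solve", {
  worst <- 0
  for (seed in 1:100) {
    n <- sample(12:30, 1)
    p <- sample(2:6, 1)
    tbl <- random_instance(seed, n = n, p = p)
    fit <- fit_ols(tbl, descriptors(tbl))
    got <- c(fit$model$intercept,
             vapply(fit$model$terms, function(t) t$coefficient, 0))
    want <- oracle_ols_coef(as.matrix(as.data.frame(tbl)[descriptors(tbl)]),
                            tbl$observed_log)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("interpolating fits and degenerate designs are handled", {
  # two points, one descriptor: exact interpolation
  df <- descriptor_table(data.frame(substrate_id = 1:2, role = "training",
                                    a = c(0, 1), observed_log = c(1, 3)))
  fit <- fit_ols(df, "a")
  expect_equal(fit$stats$SSE, 0, tolerance = 1e-20)
  expect_equal(fit$stats$R2, 1)
  # collinear design errors and names the offending column
  df2 <- descriptor_table(data.frame(
    substrate_id = 1:6, role = "training",
    a = 1:6, b = 2 * (1:6), observed_log = rnorm(6)))
  expect_error(fit_ols(df2, c("a", "b")), "collinear.*b")
  # too few rows
  df3 <- descriptor_table(data.frame(
    substrate_id = 1:2, role = "training", a = 1:2, b = c(2, 1),
    observed_log = c(1, 2)))
  expect_error(fit_ols(df3, c("a", "b")), "at least")
})

test_that("R2, adjusted R2 and F follow their closed forms", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "zero variance")
  set.seed(3)
  tbl <- random_instance(3, n = 15, p = 4)
  fit <- fit_ols(tbl, descriptors(tbl))
  lmfit <- lm(observed_log ~ ., data = as.data.frame(tbl)[c(descriptors(tbl),
                                                            "observed_log")])
  s <- summary(lmfit)
  expect_equal(fit$stats$R2, s$r.squared, tolerance = 1e-10)
  expect_equal(fit$stats$R2_adj, s$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$stats$F, unname(s$fstatistic[1]), tolerance = 1e-8)
  expect_lte(fit$stats$R2_adj, fit$stats$R2)
})

test_that("Friedman LOF matches its formula and penalizes model size", {
  expect_equal(friedman_lof(0, n = 12, c_basis = 5, p_params = 6), 0)
  expect_equal(friedman_lof(0.005291, n = 12, c_basis = 5, p_params = 6),
               (0.005291 / 12) / (1 - 8 / 12)^2, tolerance = 1e-12)
  expect_equal(friedman_lof(0.005291, n = 12, c_basis = 5, p_params = 6),
               0.00397, tolerance = 1e-3)
  # strictly increasing in model size at fixed SSE and n
  lofs <- vapply(1:7, function(p) {
    friedman_lof(0.01, n = 12, c_basis = p, p_params = p + 1)
  }, 0)
  expect_true(all(diff(lofs) > 0))
  expect_error(friedman_lof(0.01, n = 6, c_basis = 4, p_params = 5),
               "too large")
})

test_that("hat-matrix LOO q2 equals the literal n-refit loop", {
  for (seed in c(11, 12, 13)) {
    tbl <- random_instance(seed, n = 14, p = 4)
    got <- loo_q2(tbl, descriptors(tbl))
    want <- oracle_loo_q2(as.data.frame(tbl), descriptors(tbl))
    expect_equal(got, want, tolerance = 1e-10)
  }
  # exactly linear response, zero noise -> q2 = 1
  df <- descriptor_table(data.frame(
    substrate_id = 1:10, role = "training", a = rnorm(10), b = rnorm(10)))
  df$observed_log <- 1 + 2 * df$a - df$b
  tbl <- descriptor_table(as.data.frame(df), descriptors = c("a", "b"))
  expect_equal(loo_q2(tbl, c("a", "b")), 1, tolerance = 1e-10)
})

test_that("q2 never exceeds R2 and pure-noise terms do not help on average", {
  set.seed(99)
  diffs <- numeric(200)
  gaps <- numeric(200)
  for (r in 1:200) {
    n <- 15
    df <- data.frame(substrate_id = 1:n, role = "training",
                     a = rnorm(n), b = rnorm(n), noise = rnorm(n))
    df$observed_log <- 1 + 0.8 * df$a - 0.5 * df$b + rnorm(n, sd = 0.3)
    tbl <- descriptor_table(df, descriptors = c("a", "b", "noise"))
    f2 <- fit_ols(tbl, c("a", "b"))
    f3 <- fit_ols(tbl, c("a", "b", "noise"))
    gaps[r] <- min(f2$stats$R2 - f2$stats$q2_loo,
                   f3$stats$R2 - f3$stats$q2_loo)
    diffs[r] <- f3$stats$q2_loo - f2$stats$q2_loo
  }
  expect_true(all(gaps >= -1e-12)) # q2 <= R2 on every instance
  expect_lte(mean(diffs), 0.005)   # one-sided: no average q2 gain
})

test_that("standardized coefficients rank descriptor importance as reported", {
  # single standardized term: standardized coefficient equals |correlation|
  set.seed(5)
  n <- 40
  df <- data.frame(substrate_id = 1:n, role = "training", x = rnorm(n))
  df$observed_log <- 0.4 * df$x + rnorm(n, sd = 0.5)
  tbl <- descriptor_table(df, descriptors = "x")
  fit <- fit_ols(tbl, "x")
  sc <- standardized_coefficients(fit$model, tbl)
  expect_equal(sc$std_coefficient,
               abs(cor(df$x, df$observed_log)), tolerance = 1e-10)

  # scale invariance: multiplying a column by 10 leaves magnitudes unchanged
  la1 <- training_rows(load_fixture("L-A1"))
  fit1 <- fit_ols(la1, eq3_descriptors)
  sc1 <- standardized_coefficients(fit1$model, la1)
  la1s <- as.data.frame(la1)
  la1s$ALogP_MR <- la1s$ALogP_MR * 10
  la1s <- descriptor_table(la1s, descriptors = eq3_descriptors)
  sc2 <- standardized_coefficients(fit_ols(la1s, eq3_descriptors)$model, la1s)
  expect_equal(sc2$std_coefficient, sc1$std_coefficient, tolerance = 1e-8)

  # reported L-A1 importance order and magnitudes (54.54/39.42/19.85/...)
  expect_equal(sc1$descriptor,
               c("ALogP_MR", "Molecular_Volume", "Jurs_PPSA_3",
                 "Molecular_PolarSASA", "Shadow_XYfrac"))
  expect_equal(sc1$std_coefficient,
               c(54.54, 39.42, 19.85, 6.048, 0.6085), tolerance = 0.02)

  # reported L-A3 order: Shadow_XY > CHI_1 > FPSA_3 > FNSA_3 > Dipole_X
  la3 <- training_rows(load_fixture("L-A3"))
  sc3 <- standardized_coefficients(fit_ols(la3, eq5_descriptors)$model, la3)
  expect_equal(sc3$descriptor,
               c("Shadow_XY", "CHI_1", "Jurs_FPSA_3", "Jurs_FNSA_3",
                 "Dipole_X"))
})

test_that("PLS refinement saturates to OLS and improves monotonically", {
  skip_if_not_installed("mixOmics")
  tbl <- random_instance(21, n = 12, p = 5)
  ols <- fit_ols(tbl, descriptors(tbl))
  pls_full <- fit_gpls(tbl, descriptors(tbl), n_components = 5)
  expect_equal(
    vapply(pls_full$model$terms, function(t) t$coefficient, 0),
    vapply(ols$model$terms, function(t) t$coefficient, 0),
    tolerance = 1e-8)
  expect_equal(pls_full$model$intercept, ols$model$intercept,
               tolerance = 1e-8)
  r2s <- vapply(1:5, function(k) {
    fit_gpls(tbl, descriptors(tbl), n_components = k)$stats$R2
  }, 0)
  expect_true(all(diff(r2s) >= -1e-10))
  expect_error(fit_gpls(tbl, descriptors(tbl), n_components = 9),
               "n_components")
})

test_that("validation reports recompute residuals as observed - predicted", {
  tbl <- load_fixture("L-A2")
  fit <- fit_ols(training_rows(tbl), published_model("L-A2")$model$terms)
  rep <- validation_report(fit$model, tbl)
  expect_equal(rep$residual, rep$observed_log - rep$predicted_log)
  expect_equal(nrow(rep), 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(fit, training_rows(tbl), path, seed = 7)
  lines <- readLines(path)
  expect_match(lines[1], "seed 7")
  expect_match(lines[2], "R2=")
})
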