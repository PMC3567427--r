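# Independent oracles used across the suite. These deliberately avoid the
# package's fitting code paths: normal equations instead of QR, literal
# refit loops instead of hat-matrix identities, exhaustive enumeration
# instead of genetic search.

# OLS coefficients via explicit normal equations
oracle_ols_coef <- function(X, y) {
  Xf <- cbind(1, X)
  as.numeric(solve(t(Xf) %*% Xf, t(Xf) %*% y))
}

# leave-one-out q2 via n literal refits with lm()
oracle_loo_q2 <- function(df, predictors, response = "observed_log") {
  form <- stats::as.formula(paste(response, "~",
                                  paste(predictors, collapse = "+")))
  press <- 0
  for (i in seq_len(nrow(df))) {
    fit_i <- stats::lm(form, data = df[-i, , drop = FALSE])
    press <- press + as.numeric(df[[response]][i] -
                                  stats::predict(fit_i, df[i, , drop = FALSE]))^2
  }
  y <- df[[response]]
  1 - press / sum((y - mean(y))^2)
}

# best Friedman-LOF subset of a fixed size by exhaustive enumeration
oracle_best_subset_lof <- function(df, pool, size, response = "observed_log",
                                   d_smooth = 0.5) {
  n <- nrow(df)
  best <- list(lof = Inf, subset = NULL)
  for (idx in utils::combn(length(pool), size, simplify = FALSE)) {
    vars <- pool[idx]
    X <- cbind(1, as.matrix(df[vars]))
    fit <- stats::lm.fit(X, df[[response]])
    if (fit$rank < ncol(X)) next
    sse <- sum(fit$residuals^2)
    lof <- (sse / n) / (1 - (size + d_smooth * (size + 1)) / n)^2
    if (lof < best$lof) best <- list(lof = lof, subset = sort(vars))
  }
  best
}

# random full-rank regression instance
random_instance <- function(seed, n = 12, p = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("V%02d", seq_len(p))))
  beta <- rnorm(p + 1)
  y <- beta[1] + X %*% beta[-1] + rnorm(n, sd = 0.3)
  df <- data.frame(substrate_id = seq_len(n), role = "training", X,
                   observed_log = as.numeric(y))
  descriptor_table(df, descriptors = colnames(X))
}

eq3_descriptors <- c("ALogP_MR", "Molecular_Volume", "Molecular_PolarSASA",
                     "Shadow_XYfrac", "Jurs_PPSA_3")
eq5_descriptors <- c("CHI_1", "Dipole_X", "Jurs_FNSA_3", "Jurs_FPSA_3",
                     "Shadow_XY")
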