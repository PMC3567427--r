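test_that("mole fractions follow y/M normalization", {
  two <- oil_composition("toy", c("oleic", "linoleic"), c(30, 30),
                         molar_mass = c(800, 800))
  expect_equal(unname(mole_fractions(two)), c(0.5, 0.5))
  ratio <- oil_composition("toy", c("a", "b"), c(30, 30),
                           molar_mass = c(1000, 500))
  expect_equal(unname(mole_fractions(ratio)), c(1 / 3, 2 / 3))

  olive <- oil_composition(
    "Olive oil", c("palmitic", "stearic", "oleic", "linolenic", "linoleic"),
    c(14.5, 2.5, 70.0, 1.5, 12.0))
  w <- mole_fractions(olive)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(names(which.max(w)), "oleic")
  # hand computation with the default homotriglyceride masses
  y <- c(14.5, 2.5, 70.0, 1.5, 12.0)
  M <- c(807.3, 891.5, 885.4, 873.3, 879.4)
  expect_equal(unname(w), (y / M) / sum(y / M), tolerance = 1e-12)
})

test_that("composition constructor applies the >1% inclusion rule and guards", {
  expect_message(
    comp <- oil_composition("toy", c("a", "b"), c(98, 0.5),
                            molar_mass = c(800, 900)),
    "dropping")
  expect_equal(comp$fatty_acid, "a")
  expect_error(oil_composition("toy", "a", 150, molar_mass = 800),
               "more than 100")
  expect_error(oil_composition("toy", "a", 50, molar_mass = -1), "> 0")
  expect_error(oil_composition("toy", "mystery", 50),
               "no default triglyceride molar mass")
})

test_that("mixture prediction is a convex combination with invariances", {
  expect_equal(predict_mixture(1, 12.3)$X_mix, 12.3)
  expect_equal(predict_mixture(c(0.5, 0.5), c(10, 30))$X_mix, 20)
  expect_error(predict_mixture(c(0.5, 0.5), c(10, -1)), ">= 0")
  expect_error(predict_mixture(c(0.7, 0.5), c(10, 20)), "sum to 1")
  expect_error(predict_mixture(c(0.5, 0.5), 10), "same length")

  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    y <- runif(k, 10, 40)
    y <- y / sum(y) * 95 # mass fractions of a near-complete composition
    M <- runif(k, 700, 950)
    X <- runif(k, 5, 35)
    comp <- oil_composition("toy", paste0("fa", 1:k), y, molar_mass = M)
    w <- mole_fractions(comp)
    xm <- predict_mixture(unname(w), X)$X_mix
    # brute-force one-liner of the mixture rule
    expect_equal(xm, sum((y / M) / sum(y / M) * X), tolerance = 1e-12)
    expect_gte(xm, min(X) - 1e-12)
    expect_lte(xm, max(X) + 1e-12)
    # reordering invariance
    o <- sample(k)
    compo <- oil_composition("toy", paste0("fa", 1:k)[o], y[o],
                             molar_mass = M[o])
    expect_equal(predict_mixture(unname(mole_fractions(compo)), X[o])$X_mix,
                 xm, tolerance = 1e-12)
    # proportional rescaling of all mass fractions
    comps <- oil_composition("toy", paste0("fa", 1:k), y / 2,
                             molar_mass = M)
    expect_equal(predict_mixture(unname(mole_fractions(comps)), X)$X_mix,
                 xm, tolerance = 1e-12)
  }
})

test_that("oil prediction chains model evaluation, back-transform and weighting", {
  # single component present in a bundled table: X_mix equals that row's
  # back-transformed model prediction
  la1 <- load_fixture("L-A1")
  fit <- attr(reproduce_prediction_columns("L-A1"), "fit")
  row1 <- as.data.frame(la1[la1$substrate_id == 1, ])
  comp_tbl <- cbind(fatty_acid = "oleic", row1)
  comp <- oil_composition("mono", "oleic", 99)
  pred <- predict_oil("L-A1", comp, comp_tbl, model = fit$model)
  expect_equal(pred$X_mix,
               from_log_activity(predict(fit$model, row1)),
               tolerance = 1e-12)

  # duplicating a component with split mass fractions leaves X_mix unchanged
  comp_tbl2 <- rbind(comp_tbl,
                     transform(comp_tbl, fatty_acid = "oleic_b"))
  comp_split <- oil_composition("mono", c("oleic", "oleic_b"), c(60, 39),
                                molar_mass = c(885.4, 885.4))
  pred2 <- predict_oil("L-A1", comp_split, comp_tbl2, model = fit$model)
  expect_equal(pred2$X_mix, pred$X_mix, tolerance = 1e-12)

  # missing components are reported by name
  expect_error(predict_oil("L-A1", comp_split, comp_tbl, model = fit$model),
               "oleic_b")
})

test_that("bundled oil tables expose compositions and measured activities", {
  comps <- load_oil_compositions()
  expect_setequal(names(comps), c("Soybean oil", "Olive oil"))
  olive <- comps[["Olive oil"]]
  expect_equal(olive$mass_fraction_pct,
               c(14.5, 2.5, 70.0, 1.5, 12.0))
  expect_equal(olive$mass_fraction_sd_pct, c(1.3, 1.2, 1.0, 0.5, 1.0))
  acts <- load_oil_activity_table()
  expect_equal(nrow(acts), 6)
  # measured value passthrough, as reported for olive oil with L-A1
  expect_equal(acts$measured_Uml[acts$oil == "Olive oil" &
                                   acts$lipase_id == "L-A1"], 27.53)
})

test_that("simple-mean mode implements the unweighted average variant", {
  p <- predict_mixture(c(0.9, 0.1), c(10, 30), mode = "simple_mean")
  expect_equal(p$X_mix, 20)
  expect_equal(p$weights, c(0.5, 0.5))
})
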