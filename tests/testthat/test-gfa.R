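desk <- function(seed, ...) gfa_desk_config(rng_seed = seed, ...)

test_that("config validation lists all problems at once", {
  expect_error(gfa_config(rng_seed = NA), "rng_seed")
  err <- tryCatch(
    gfa_config(population_size = 1, crossover_rate = 2, min_terms = 4,
               max_terms = 2, rng_seed = 1),
    error = conditionMessage)
  expect_match(err, "population_size")
  expect_match(err, "crossover_rate")
  expect_match(err, "min_terms > max_terms")
})

test_that("population initialization respects size bounds and determinism", {
  cfg <- desk(4, min_terms = 5, max_terms = 5)
  pool <- letters[1:5]
  set.seed(cfg$rng_seed)
  pop <- initialize_population(pool, cfg)
  expect_length(pop, 200)
  # forced subset: every individual is the full pool
  expect_true(all(vapply(pop, function(x) identical(x, sort(pool)), TRUE)))

  cfg2 <- desk(4, min_terms = 1, max_terms = 3)
  set.seed(99); popA <- initialize_population(letters[1:10], cfg2)
  set.seed(99); popB <- initialize_population(letters[1:10], cfg2)
  expect_identical(popA, popB)
  expect_true(all(lengths(popA) >= 1 & lengths(popA) <= 3))
  expect_error(initialize_population(character(), cfg2), "pool")
})

test_that("crossover splices parents, collapses duplicates, keeps bounds", {
  cfg <- desk(1, min_terms = 1, max_terms = 4)
  pool <- letters[1:10]
  set.seed(7)
  # identical parents -> child equals parents
  p <- c("a", "b", "c")
  for (i in 1:20) expect_identical(crossover_terms(p, p, pool, cfg), p)
  # disjoint 2-term parents -> size within [1, 4]
  for (i in 1:200) {
    ch <- crossover_terms(c("a", "b"), c("c", "d"), pool, cfg)
    expect_true(length(ch) >= 1 && length(ch) <= 4)
    expect_true(all(ch %in% pool))
    expect_false(anyDuplicated(ch) > 0)
  }
})

test_that("mutation respects bounds, never duplicates, is identity at rate 0", {
  pool <- letters[1:8]
  cfg0 <- desk(1, mutation_rate = 0)
  set.seed(11)
  expect_identical(mutate_terms(c("a", "c"), pool, cfg0), c("a", "c"))
  cfg1 <- desk(1, mutation_rate = 1, min_terms = 1, max_terms = 4)
  set.seed(12)
  for (i in 1:2000) {
    m <- mutate_terms(c("a", "b", "c"), pool, cfg1)
    expect_true(length(m) >= 1 && length(m) <= 4)
    descs <- sub("[<>].*$", "", m)
    expect_false(anyDuplicated(descs) > 0)
  }
})

test_that("lof fitness delegates to the OLS + LOF chain and culls unfittable models", {
  tbl <- training_rows(load_fixture("L-A1"))
  fit <- fit_ols(tbl, eq3_descriptors)
  expect_equal(lof_fitness(eq3_descriptors, tbl), fit$stats$LOF)
  # collinear duplicate-information model -> infinite fitness
  df <- as.data.frame(tbl)
  df$copy <- df$ALogP_MR * 2
  tbl2 <- descriptor_table(df, descriptors = c(eq3_descriptors, "copy"))
  expect_equal(lof_fitness(c("ALogP_MR", "copy"), tbl2), Inf)
})

test_that("GFA runs are reproducible and elitist (best LOF non-increasing)", {
  tbl <- load_fixture("L-A1")
  cfg <- desk(42, population_size = 60, generations = 30)
  r1 <- run_gfa(tbl, cfg)
  r2 <- run_gfa(tbl, cfg)
  expect_identical(r1$best_terms, r2$best_terms)
  expect_identical(r1$ranked, r2$ranked)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(diff(r1$trajectory$best_lof) <= 1e-15))
  expect_true(all(r1$ranked$lof == sort(r1$ranked$lof)))
  expect_equal(nrow(r1$ranked), cfg$population_size)
  expect_true(all(is.finite(r1$ranked$lof[seq_len(cfg$elite)])))
})

test_that("forced to five terms on the study pool, GFA refits the published model", {
  tbl <- load_fixture("L-A1")
  res <- run_gfa(tbl, desk(3, min_terms = 5, max_terms = 5),
                 pool = eq3_descriptors)
  expect_setequal(res$best_terms, eq3_descriptors)
  expect_equal(res$best_model$stats$R2, 0.9833, tolerance = 0.002)
})

test_that("on small pools GFA matches the exhaustive LOF optimum", {
  tbl <- random_instance(202, n = 20, p = 10)
  df <- as.data.frame(tbl)
  df$observed_log <- 1 + 0.9 * df$V01 - 0.7 * df$V05 + 0.5 * df$V08 +
    rnorm(20, sd = 0.15)
  tbl <- descriptor_table(df, descriptors = descriptors(tbl))
  oracle <- oracle_best_subset_lof(df, descriptors(tbl), size = 3)
  hits <- 0
  for (seed in 1:10) {
    res <- run_gfa(tbl, desk(seed, min_terms = 3, max_terms = 3))
    # GFA can never beat the enumerated optimum
    expect_gte(res$ranked$lof[1], oracle$lof - 1e-12)
    if (setequal(res$best_terms, oracle$subset)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("spline-enabled search stays within term bounds and is reproducible", {
  tbl <- load_fixture("L-A2")
  cfg <- desk(5, population_size = 80, generations = 25,
              allow_splines = TRUE, max_terms = 4)
  r1 <- run_gfa(tbl, cfg)
  r2 <- run_gfa(tbl, cfg)
  expect_identical(r1$best_terms, r2$best_terms)
  expect_true(all(r1$ranked$n_terms <= 4))
  expect_true(is.finite(r1$ranked$lof[1]))
})

test_that("GFA results export to JSON with ranked population and metadata", {
  tbl <- load_fixture("L-A1")
  res <- run_gfa(tbl, desk(8, population_size = 40, generations = 10))
  path <- withr::local_tempfile(fileext = ".json")
  gfa_result_to_json(res, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$seed, 8)
  expect_equal(nrow(doc$ranked), 40)
  expect_equal(doc$best_model$intercept, res$best_model$model$intercept)
})
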