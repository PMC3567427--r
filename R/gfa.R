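#' Genetic function approximation configuration
#'
#' Hyperparameters of the GFA descriptor-subset search. The study fixes
#' the population size (1500) and the Friedman LOF smoothing factor
#' (d = 0.5); the remaining operators follow common GFA practice and are
#' all exposed here. `gfa_desk_config()` is a reduced profile (population
#' 200, 100 generations) suitable for interactive work and test suites;
#' on the small descriptor pools involved it reaches the same optima as
#' the full-size profile.
#'
#' @param population_size Number of models in the population (>= 2).
#' @param generations Generation cap.
#' @param crossover_rate,mutation_rate Probabilities in \[0, 1\].
#' @param min_terms,max_terms Bounds on the model size (number of terms).
#' @param d_smooth Friedman LOF smoothing factor (default 0.5).
#' @param allow_splines Offer truncated-spline terms during the search.
#' @param spline_knot_quantiles Quantiles of each descriptor's training
#'   values used as candidate spline knots (knots must lie inside the data
#'   range to be identifiable).
#' @param elite Number of best models copied unchanged each generation.
#' @param tournament_size Tournament size for parent selection.
#' @param convergence_window Stop when the best model's term set has been
#'   unchanged for this many generations.
#' @param rng_seed Integer seed; mandatory, so that every run is exactly
#'   reproducible.
#' @return An object of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 1500, generations = 500,
                       crossover_rate = 0.9, mutation_rate = 0.1,
                       min_terms = 1, max_terms = 5, d_smooth = 0.5,
                       allow_splines = FALSE,
                       spline_knot_quantiles = c(0.2, 0.4, 0.6, 0.8),
                       elite = 2, tournament_size = 3,
                       convergence_window = 50, rng_seed) {
  if (missing(rng_seed) || !is.finite(rng_seed)) {
    stop("gfa_config requires an explicit integer rng_seed", call. = FALSE)
  }
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              min_terms = as.integer(min_terms),
              max_terms = as.integer(max_terms),
              d_smooth = d_smooth, allow_splines = isTRUE(allow_splines),
              spline_knot_quantiles = spline_knot_quantiles,
              elite = as.integer(elite),
              tournament_size = as.integer(tournament_size),
              convergence_window = as.integer(convergence_window),
              rng_seed = as.integer(rng_seed))
  problems <- character()
  if (cfg$population_size < 2) problems <- c(problems, "population_size < 2")
  if (cfg$generations < 1) problems <- c(problems, "generations < 1")
  for (r in c("crossover_rate", "mutation_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      problems <- c(problems, paste(r, "outside [0, 1]"))
    }
  }
  if (cfg$min_terms < 1) problems <- c(problems, "min_terms < 1")
  if (cfg$min_terms > cfg$max_terms) {
    problems <- c(problems, "min_terms > max_terms")
  }
  if (cfg$d_smooth < 0) problems <- c(problems, "d_smooth < 0")
  if (cfg$elite < 0 || cfg$elite > cfg$population_size) {
    problems <- c(problems, "elite outside [0, population_size]")
  }
  if (cfg$tournament_size < 1) problems <- c(problems, "tournament_size < 1")
  if (cfg$convergence_window < 1) {
    problems <- c(problems, "convergence_window < 1")
  }
  if (any(cfg$spline_knot_quantiles <= 0 | cfg$spline_knot_quantiles >= 1)) {
    problems <- c(problems, "spline_knot_quantiles outside (0, 1)")
  }
  if (length(problems)) {
    stop("invalid gfa_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "gfa_config")
}

#' @rdname gfa_config
#' @param ... Overrides passed on to [gfa_config()].
#' @export
gfa_desk_config <- function(rng_seed, ...) {
  defaults <- list(population_size = 200, generations = 100,
                   convergence_window = 20, rng_seed = rng_seed)
  overrides <- list(...)
  do.call(gfa_config, utils::modifyList(defaults, overrides))
}

## Individuals are canonical sorted character vectors of term keys:
## "desc" (identity), "desc>knot" (spline_above), "desc<knot" (spline_below).
key_to_term <- function(key) {
  if (grepl(">", key, fixed = TRUE)) {
    parts <- strsplit(key, ">", fixed = TRUE)[[1]]
    model_term(parts[1], transform = "spline_above",
               knot = as.numeric(parts[2]))
  } else if (grepl("<", key, fixed = TRUE)) {
    parts <- strsplit(key, "<", fixed = TRUE)[[1]]
    model_term(parts[1], transform = "spline_below",
               knot = as.numeric(parts[2]))
  } else {
    model_term(key)
  }
}

keys_to_terms <- function(keys) lapply(keys, key_to_term)

key_descriptor <- function(keys) sub("[<>].*$", "", keys)

canonical <- function(keys) sort(unique(keys))

## collapse duplicate (descriptor, transform) pairs, keeping the first
dedupe_keys <- function(keys) {
  sig <- paste(key_descriptor(keys),
               ifelse(grepl(">", keys), "a", ifelse(grepl("<", keys), "b", "i")))
  keys[!duplicated(sig)]
}

## sample() treats a length-1 numeric as 1:n; always index explicitly
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

clamp_size <- function(keys, pool_keys, min_terms, max_terms) {
  if (length(keys) > max_terms) {
    keys <- resample(keys, max_terms)
  }
  if (length(keys) < min_terms) {
    avail <- setdiff(pool_keys, keys)
    avail <- avail[!key_descriptor(avail) %in% key_descriptor(keys)]
    need <- min(min_terms - length(keys), length(avail))
    if (need > 0) keys <- c(keys, resample(avail, need))
  }
  canonical(keys)
}

#' GFA genetic operators
#'
#' `initialize_population` draws uniform random term subsets with sizes in
#' `[min_terms, max_terms]`; `crossover_terms` recombines two parents by
#' cutting both term lists at one shared random point and splicing the head
#' of one onto the tail of the other (so identical parents reproduce
#' themselves; duplicate (descriptor, transform) pairs collapse, size is
#' clamped back into bounds); `mutate_terms` applies, with probability
#' `mutation_rate`, one randomly chosen edit: swap a term's descriptor for
#' an unused one, add a term, drop a term, or (when splines are enabled)
#' toggle a term between identity and a spline basis at a candidate knot.
#'
#' These operators act on "term key" character vectors (`"desc"`,
#' `"desc>knot"`, `"desc<knot"`); randomness comes from the R RNG, so runs
#' are reproducible under `set.seed`.
#'
#' @param pool_keys Candidate term keys (for plain searches, the
#'   descriptor names).
#' @param config A [gfa_config()].
#' @param a,b,keys Individuals (character vectors of term keys).
#' @param knot_table Named list of candidate knots per descriptor (used
#'   when `config$allow_splines` is TRUE).
#' @return A population (list of individuals) for
#'   `initialize_population`; an individual for the other operators.
#' @export
initialize_population <- function(pool_keys, config) {
  if (length(pool_keys) < config$min_terms) {
    stop("descriptor pool smaller than min_terms", call. = FALSE)
  }
  max_sz <- min(config$max_terms, length(pool_keys))
  lapply(seq_len(config$population_size), function(i) {
    sz <- resample(seq(config$min_terms, max_sz))
    canonical(resample(pool_keys, sz))
  })
}

#' @rdname initialize_population
#' @export
crossover_terms <- function(a, b, pool_keys, config) {
  # one shared cut point, so identical parents reproduce themselves
  cut <- resample(0:min(length(a), length(b)))
  child <- dedupe_keys(c(head(a, cut), tail(b, length(b) - cut)))
  if (length(child) == 0L) return(canonical(a))
  clamp_size(child, pool_keys, config$min_terms, config$max_terms)
}

#' @rdname initialize_population
#' @export
mutate_terms <- function(keys, pool_keys, config, knot_table = NULL) {
  if (runif(1) >= config$mutation_rate) return(keys)
  descs <- key_descriptor(keys)
  pool_descs <- unique(key_descriptor(pool_keys))
  unused <- setdiff(pool_descs, descs)
  ops <- c(
    if (length(unused)) "swap",
    if (length(keys) < config$max_terms && length(unused)) "add",
    if (length(keys) > config$min_terms) "drop",
    if (config$allow_splines && length(knot_table)) "toggle"
  )
  if (!length(ops)) return(keys)
  op <- resample(ops)
  if (op == "swap") {
    i <- sample.int(length(keys), 1)
    keys[i] <- resample(unused)
  } else if (op == "add") {
    keys <- c(keys, resample(unused))
  } else if (op == "drop") {
    keys <- keys[-sample.int(length(keys), 1)]
  } else { # toggle spline form
    i <- sample.int(length(keys), 1)
    d <- descs[i]
    if (grepl("[<>]", keys[i])) {
      keys[i] <- d
    } else if (!is.null(knot_table[[d]])) {
      knot <- resample(knot_table[[d]])
      keys[i] <- paste0(d, resample(c(">", "<")), format(knot, digits = 12))
    }
    keys <- dedupe_keys(keys)
  }
  canonical(keys)
}

#' Friedman-LOF fitness of a term set
#'
#' Fits the term set by least squares on the table and returns the
#' Friedman lack-of-fit score (lower is fitter). Unfittable models
#' (rank-deficient, or too large for the sample) score `Inf` and are
#' culled by selection.
#'
#' @param terms Term keys (character) or a list of [model_term()]s.
#' @param table Training descriptor table.
#' @param response Response column name.
#' @param d_smooth LOF smoothing factor.
#' @return The LOF score, or `Inf` when the model cannot be fitted.
#' @export
lof_fitness <- function(terms, table, response = "observed_log",
                        d_smooth = 0.5) {
  if (is.character(terms)) terms <- keys_to_terms(terms)
  tryCatch(
    fit_ols(table, terms, response = response, d_smooth = d_smooth)$stats$LOF,
    error = function(e) Inf
  )
}

## fast internal fitness on a precomputed descriptor matrix, with caching
make_scorer <- function(M, y, d_smooth) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n <- length(y)
  function(keys) {
    id <- paste(keys, collapse = ";")
    hit <- cache[[id]]
    if (!is.null(hit)) return(hit)
    p <- length(keys)
    val <- if (p + 1 > n || (p + d_smooth * (p + 1)) >= n) {
      Inf
    } else {
      X <- matrix(1, n, p + 1L)
      for (j in seq_len(p)) {
        k <- keys[j]
        if (grepl(">", k, fixed = TRUE)) {
          parts <- strsplit(k, ">", fixed = TRUE)[[1]]
          X[, j + 1L] <- pmax(M[, parts[1]] - as.numeric(parts[2]), 0)
        } else if (grepl("<", k, fixed = TRUE)) {
          parts <- strsplit(k, "<", fixed = TRUE)[[1]]
          X[, j + 1L] <- pmax(as.numeric(parts[2]) - M[, parts[1]], 0)
        } else {
          X[, j + 1L] <- M[, k]
        }
      }
      fit <- lm.fit(X, y)
      if (fit$rank < ncol(X)) {
        Inf
      } else {
        sse <- sum(fit$residuals^2)
        (sse / n) / (1 - (p + d_smooth * (p + 1)) / n)^2
      }
    }
    cache[[id]] <- val
    val
  }
}

rank_population <- function(pop, fitness) {
  keystr <- vapply(pop, paste, "", collapse = ";")
  order(fitness, lengths(pop), keystr)
}

#' Run the genetic function approximation search
#'
#' Evolves a population of descriptor-subset linear models under Friedman
#' lack-of-fit fitness: score, rank, copy the elite unchanged, then fill
#' the next generation with tournament-selected parents recombined by
#' [crossover_terms()] and perturbed by [mutate_terms()]. The search stops
#' at the generation cap or as soon as the best model's term set has been
#' stable for `convergence_window` generations (the "descriptors became
#' constant" stopping rule). Ties in the ranking break deterministically:
#' lower LOF first, then fewer terms, then lexicographic term keys.
#'
#' Only training rows of `table` are used. The best term set is refitted
#' with [fit_ols()] to produce the returned model and statistics.
#'
#' @param table A [descriptor_table()]; rows with `role == "training"` are
#'   used (all rows if the table has no test rows).
#' @param config A [gfa_config()].
#' @param pool Descriptor names to search over; defaults to all
#'   descriptors of the table.
#' @param response Response column name.
#' @return An object of class `gfa_result`: `best_model` (a `qsar_fit`),
#'   `best_terms` (term keys), `ranked` (data.frame of the final
#'   population, ascending LOF), `population` (list of term-key vectors in
#'   ranked order), `trajectory` (per-generation best LOF and term set),
#'   `generations_run`, `converged`, `seed`.
#' @examples
#' tbl <- load_fixture("L-A1")
#' res <- run_gfa(tbl, gfa_desk_config(rng_seed = 1, max_terms = 3))
#' res$best_model$stats$LOF
#' @export
run_gfa <- function(table, config, pool = NULL,
                    response = "observed_log") {
  stopifnot(inherits(config, "gfa_config"))
  train <- if ("role" %in% names(table) && any(table$role == "training")) {
    table[table$role == "training", , drop = FALSE]
  } else {
    table
  }
  pool <- pool %||% attr(table, "descriptors")
  if (is.null(pool) || !length(pool)) {
    stop("empty descriptor pool", call. = FALSE)
  }
  M <- as.matrix(as.data.frame(train)[pool])
  y <- train[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)

  knot_table <- NULL
  if (config$allow_splines) {
    knot_table <- lapply(setNames(pool, pool), function(d) {
      unique(as.numeric(quantile(M[, d], config$spline_knot_quantiles)))
    })
  }
  pool_keys <- pool

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$rng_seed)

  scorer <- make_scorer(M, y, config$d_smooth)
  pop <- initialize_population(pool_keys, config)
  fitness <- vapply(pop, scorer, 0)

  trajectory <- data.frame(generation = integer(), best_lof = numeric(),
                           best_terms = character(),
                           stringsAsFactors = FALSE)
  best_key_str <- ""
  stable_for <- 0L
  converged <- FALSE
  gen <- 0L

  for (gen in seq_len(config$generations)) {
    ord <- rank_population(pop, fitness)
    pop <- pop[ord]
    fitness <- fitness[ord]
    cur_best <- paste(pop[[1]], collapse = ";")
    trajectory <- rbind(trajectory, data.frame(
      generation = gen, best_lof = fitness[1], best_terms = cur_best,
      stringsAsFactors = FALSE))
    if (identical(cur_best, best_key_str)) {
      stable_for <- stable_for + 1L
      if (stable_for >= config$convergence_window) {
        converged <- TRUE
        break
      }
    } else {
      best_key_str <- cur_best
      stable_for <- 0L
    }

    tournament <- function() {
      idx <- sample.int(config$population_size,
                        min(config$tournament_size, config$population_size))
      idx[which.min(fitness[idx])]
    }
    next_pop <- pop[seq_len(config$elite)]
    while (length(next_pop) < config$population_size) {
      pa <- tournament()
      pb <- tournament()
      child <- if (runif(1) < config$crossover_rate) {
        crossover_terms(pop[[pa]], pop[[pb]], pool_keys, config)
      } else {
        pop[[if (fitness[pa] <= fitness[pb]) pa else pb]]
      }
      child <- mutate_terms(child, pool_keys, config, knot_table)
      next_pop[[length(next_pop) + 1L]] <- child
    }
    pop <- next_pop
    fitness <- vapply(pop, scorer, 0)
  }

  ord <- rank_population(pop, fitness)
  pop <- pop[ord]
  fitness <- fitness[ord]

  train_dt <- subset_rows(descriptor_table(
    as.data.frame(train), descriptors = pool,
    lipase_id = attr(table, "lipase_id"), aliases = attr(table, "aliases")),
    rep(TRUE, nrow(train)))
  best_fit <- fit_ols(train_dt, keys_to_terms(pop[[1]]), response = response,
                      d_smooth = config$d_smooth, provenance = "gfa")
  ranked <- data.frame(
    rank = seq_along(pop),
    lof = fitness,
    n_terms = lengths(pop),
    terms = vapply(pop, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  structure(list(best_model = best_fit, best_terms = pop[[1]],
                 ranked = ranked, population = pop,
                 trajectory = trajectory, generations_run = gen,
                 converged = converged, seed = config$rng_seed,
                 config = config),
            class = "gfa_result")
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf(
    "GFA search: %d generations (%s), seed %d\nbest LOF = %.5g, terms: %s\n",
    x$generations_run,
    if (x$converged) "converged" else "generation cap reached",
    x$seed, x$ranked$lof[1], paste(x$best_terms, collapse = " + ")))
  print(x$best_model$stats)
  invisible(x)
}

#' Export a GFA result to JSON
#'
#' Writes the ranked population (term sets and LOF scores), the best
#' model in the standard model-JSON form, and the run metadata.
#'
#' @param result A `gfa_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
gfa_result_to_json <- function(result, path) {
  stopifnot(inherits(result, "gfa_result"))
  doc <- list(
    seed = result$seed,
    generations_run = result$generations_run,
    converged = result$converged,
    best_model = jsonlite::fromJSON(model_to_json(result$best_model$model),
                                    simplifyVector = FALSE),
    best_stats = unclass(result$best_model$stats),
    ranked = result$ranked
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
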