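# Real-coded genetic algorithm for conductance-scaling fits.

#' Score a model's AP features against experimental targets
#'
#' Sum over scored features of ((model - experiment)/SE)^2; 0 iff the model
#' reproduces every target exactly, lower is better. A non-beating model (any
#' scored feature missing or non-finite) receives the configured penalty.
#'
#' @param features a \code{cardiomag_ap_features} object or named numeric.
#' @param targets list with named numeric \code{mean} and \code{se}
#'   (see \code{\link{ap_targets}}); scored features are \code{names(mean)}.
#' @param penalty score assigned when any scored feature is unavailable.
#' @return Non-negative scalar score.
#' @export
ap_score <- function(features, targets, penalty = 1e6) {
  stopifnot(all(targets$se > 0), identical(names(targets$mean), names(targets$se)))
  want <- names(targets$mean)
  vals <- if (is.list(features)) unlist(features[want]) else features[want]
  if (length(vals) != length(want) || any(!is.finite(vals))) return(penalty)
  sum(((vals - targets$mean) / targets$se)^2)
}

#' GA configuration
#'
#' Standard real-coded GA defaults: tournament selection (size 3), BLX-alpha
#' blend crossover (alpha = 0.5) at rate 0.9, per-gene Gaussian mutation
#' (sigma = 10\% of the gene range) at rate 0.1, elitism 1.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param bounds 2 x n matrix (rows lower/upper) of per-gene bounds.
#' @param crossover_rate,mutation_rate,mutation_sigma_frac,tournament_size,elitism
#'   GA operator settings.
#' @param penalty score for failed evaluations.
#' @param seed integer RNG seed for this run.
#' @return list of class \code{cardiomag_ga_config}.
#' @export
ga_config <- function(pop_size = 100, generations = 200, bounds,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      mutation_sigma_frac = 0.1, tournament_size = 3,
                      elitism = 1, penalty = 1e6, seed = 1) {
  stopifnot(pop_size >= 1, generations >= 1,
            is.matrix(bounds), nrow(bounds) == 2,
            all(bounds[1, ] <= bounds[2, ]))
  structure(list(pop_size = pop_size, generations = generations,
                 bounds = bounds, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma_frac = mutation_sigma_frac,
                 tournament_size = tournament_size, elitism = elitism,
                 penalty = penalty, seed = seed),
            class = "cardiomag_ga_config")
}

#' Run a real-coded GA
#'
#' Minimizes \code{evaluator(genes)} over the configured bounds. The initial
#' population is per-gene uniform over the bounds; genes are clamped to
#' bounds after every variation step; elitism preserves the incumbent best,
#' so the per-generation best score is monotone non-increasing. Deterministic
#' given \code{config$seed}.
#'
#' @param evaluator function(named numeric genes) -> scalar score (lower
#'   better). See \code{\link{ap_evaluator}} for the AP-fitting evaluator.
#' @param config a \code{\link{ga_config}}.
#' @return list of class \code{cardiomag_ga_result}: \code{best} (named
#'   genes), \code{best_score}, \code{history} (per-generation best),
#'   \code{seed}.
#' @export
run_ga <- function(evaluator, config) {
  stopifnot(inherits(config, "cardiomag_ga_config"))
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  n_gene <- length(lo)
  gene_names <- colnames(config$bounds)
  rng_state <- .save_rng()
  on.exit(.restore_rng(rng_state))
  set.seed(config$seed)

  clamp <- function(x) pmin(pmax(x, lo), hi)
  pop <- t(replicate(config$pop_size, runif(n_gene, lo, hi)))
  if (n_gene == 1) pop <- matrix(pop, ncol = 1)
  evaluate <- function(g) {
    names(g) <- gene_names
    val <- tryCatch(evaluator(g), error = function(e) config$penalty)
    if (!is.finite(val)) config$penalty else val
  }
  scores <- apply(pop, 1, evaluate)
  history <- numeric(config$generations)
  sigma <- config$mutation_sigma_frac * (hi - lo)

  for (gen in seq_len(config$generations)) {
    ord <- order(scores)
    elite_idx <- ord[seq_len(config$elitism)]
    newpop <- matrix(NA_real_, config$pop_size, n_gene)
    newscores <- rep(NA_real_, config$pop_size)
    newpop[seq_len(config$elitism), ] <- pop[elite_idx, , drop = FALSE]
    newscores[seq_len(config$elitism)] <- scores[elite_idx]

    tournament <- function() {
      cand <- sample.int(config$pop_size, config$tournament_size, replace = TRUE)
      cand[which.min(scores[cand])]
    }
    i <- config$elitism + 1L
    while (i <= config$pop_size) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      if (runif(1) < config$crossover_rate) {
        # BLX-alpha, alpha = 0.5
        cmin <- pmin(p1, p2); cmax <- pmax(p1, p2); d <- cmax - cmin
        child <- runif(n_gene, cmin - 0.5 * d, cmax + 0.5 * d)
      } else {
        child <- p1
      }
      mut <- runif(n_gene) < config$mutation_rate
      child[mut] <- child[mut] + rnorm(sum(mut), 0, sigma[mut])
      child <- clamp(child)
      newpop[i, ] <- child
      newscores[i] <- evaluate(child)
      i <- i + 1L
    }
    pop <- newpop; scores <- newscores
    history[gen] <- min(scores)
  }
  best_i <- which.min(scores)
  best <- pop[best_i, ]
  names(best) <- gene_names
  structure(list(best = best, best_score = scores[best_i],
                 history = cummin(history), seed = config$seed),
            class = "cardiomag_ga_result")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(state) {
  if (is.null(state)) return(invisible())
  assign(".Random.seed", state, envir = globalenv())
}

#' Select the best of several independent GA runs
#'
#' @param results list of \code{cardiomag_ga_result}.
#' @return The run with the minimum best score; ties broken by lowest seed.
#' @export
select_best_of_runs <- function(results) {
  if (!length(results)) stop("empty result list")
  scores <- vapply(results, function(r) r$best_score, numeric(1))
  seeds <- vapply(results, function(r) r$seed, numeric(1))
  results[[order(scores, seeds)[1]]]
}

#' Evaluator mapping conductance scalings to an AP-fit score
#'
#' Builds the simulate -> extract features -> score chain used to fit a cell
#' model to experimental AP targets. Intracellular potassium and SR calcium
#' are clamped during evaluation by default to accelerate convergence
#' (disable via \code{fixed = character(0)}).
#'
#' @param model_template a \code{cardiomag_cell_model}; its \code{genes} name
#'   the scaling factors being optimized.
#' @param targets see \code{\link{ap_score}}.
#' @param duration_s,dt_ms,analysis_window_s simulation settings.
#' @param fixed state variables clamped during GA evaluation (NULL = registry
#'   default for the model).
#' @param penalty score for non-beating models.
#' @return function(genes) -> score, for \code{\link{run_ga}}.
#' @export
ap_evaluator <- function(model_template, targets, duration_s = 60,
                         dt_ms = 0.01, analysis_window_s = 20,
                         fixed = NULL, penalty = 1e6) {
  if (is.null(fixed))
    fixed <- model_registry()[[model_template$id]]$fixed_default
  force(targets)
  function(genes) {
    m <- cell_model(model_template$id, scalings = genes,
                    overrides = model_template$params[
                      c("T_degC", "Tref_degC")], fixed = fixed)
    tr <- tryCatch(
      simulate_ap(m, duration_s = duration_s, dt_ms = dt_ms),
      error = function(e) NULL)
    if (is.null(tr)) return(penalty)
    feats <- extract_ap_features(tr, m$id, analysis_window_s = analysis_window_s)
    ap_score(feats, targets, penalty = penalty)
  }
}

#' Fit conductance scalings with independent GA restarts
#'
#' Runs \code{restarts} independently seeded GAs and adopts the best run.
#'
#' @inheritParams ap_evaluator
#' @param config base \code{\link{ga_config}} (its seed seeds restart 1;
#'   restart k uses \code{seed + k - 1}).
#' @param restarts number of independent runs.
#' @return list: \code{best_run}, \code{runs}.
#' @export
optimize_model <- function(model_template, targets, config, restarts = 10,
                           duration_s = 60, dt_ms = 0.01, fixed = NULL) {
  stopifnot(restarts >= 1)
  ev <- ap_evaluator(model_template, targets, duration_s = duration_s,
                     dt_ms = dt_ms, fixed = fixed, penalty = config$penalty)
  runs <- lapply(seq_len(restarts), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    run_ga(ev, cfg)
  })
  list(best_run = select_best_of_runs(runs), runs = runs)
}
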