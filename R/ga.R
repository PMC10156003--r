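#' Genetic-algorithm configuration
#'
#' Operator settings for the real-coded GA used to minimize the embedding
#' distance: tournament selection, blend-alpha (BLX) crossover, Gaussian
#' mutation clipped to the bounds, and elitism (which makes the best-so-far
#' trace non-increasing). The full-scale protocol uses populations of 300
#' (four-parameter model) or 400 (five-parameter model); scaled-down fits use
#' much smaller populations.
#'
#' @param pop_size individuals per generation (>= 2).
#' @param generations number of generations.
#' @param tournament_k tournament size for parent selection.
#' @param cx_prob probability a child is produced by crossover (otherwise it
#'   clones the first parent).
#' @param cx_alpha BLX-alpha blend range extension.
#' @param mut_prob per-gene mutation probability.
#' @param mut_sigma_frac mutation standard deviation as a fraction of each
#'   parameter's bound width.
#' @param elitism number of best individuals copied unchanged (>= 1).
#' @param seed RNG seed for the run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 300, generations = 20, tournament_k = 3,
                      cx_prob = 0.9, cx_alpha = 0.5, mut_prob = 0.3,
                      mut_sigma_frac = 0.1, elitism = 1, seed = 1) {
  if (pop_size < 2) stop("'pop_size' must be at least 2")
  if (elitism < 1) stop("'elitism' must be at least 1")
  if (elitism >= pop_size) stop("'elitism' must be smaller than 'pop_size'")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament_k = as.integer(tournament_k), cx_prob = cx_prob,
                 cx_alpha = cx_alpha, mut_prob = mut_prob,
                 mut_sigma_frac = mut_sigma_frac,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Minimize an objective with a genetic algorithm
#'
#' Real-coded GA over box bounds. The objective is called as
#' `fn(x, seed)` with a fresh evaluation seed per candidate, matching the
#' single-replicate policy for stochastic simulators: the population, not
#' repeated evaluation, averages over simulator noise. Elite individuals
#' carry their recorded objective value forward, so the best trace never
#' increases.
#'
#' @param fn objective function `function(x, seed) -> scalar` to minimize.
#' @param bounds data frame with columns `name`, `lower`, `upper`.
#' @param cfg a [ga_config()].
#' @return A list of class `ga_result`: `best_par`, `best_obj`, `trace`
#'   (per-generation data frame with `gen`, `best`, `mean`), `population`,
#'   `history` (all evaluated candidates with objectives), `seed`.
#' @examples
#' sphere <- function(x, seed) sum((x - c(0.3, -0.2))^2)
#' b <- data.frame(name = c("x1", "x2"), lower = -1, upper = 1)
#' res <- ga_optimize(sphere, b, ga_config(pop_size = 30, generations = 40))
#' res$best_par
#' @export
ga_optimize <- function(fn, bounds, cfg = ga_config()) {
  stopifnot(all(c("name", "lower", "upper") %in% names(bounds)))
  if (any(bounds$lower >= bounds$upper))
    stop("each bound must have lower < upper")
  p <- nrow(bounds)
  lo <- bounds$lower
  hi <- bounds$upper
  width <- hi - lo
  with_local_seed(cfg$seed, {
    eval_seeds <- function(k) sample.int(.Machine$integer.max - 1, k)
    evaluate <- function(pop) {
      sds <- eval_seeds(nrow(pop))
      obj <- vapply(seq_len(nrow(pop)),
                    function(i) fn(pop[i, ], sds[i]), numeric(1))
      if (all(!is.finite(obj)))
        stop("objective returned no finite value for an entire generation")
      obj
    }
    pop <- matrix(runif(cfg$pop_size * p, rep(lo, each = cfg$pop_size),
                        rep(hi, each = cfg$pop_size)),
                  cfg$pop_size, p)
    colnames(pop) <- bounds$name
    obj <- evaluate(pop)
    hist_par <- pop
    hist_obj <- obj
    trace <- data.frame(gen = 0, best = min(obj), mean = mean(obj))
    tournament <- function() {
      cand <- sample.int(cfg$pop_size, cfg$tournament_k, replace = TRUE)
      cand[which.min(obj[cand])]
    }
    for (gen in seq_len(cfg$generations)) {
      ord <- order(obj)
      n_off <- cfg$pop_size - cfg$elitism
      off <- matrix(0, n_off, p, dimnames = list(NULL, bounds$name))
      for (i in seq_len(n_off)) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        child <- if (runif(1) < cfg$cx_prob) {
          cmin <- pmin(p1, p2)
          cmax <- pmax(p1, p2)
          d <- cmax - cmin
          runif(p, cmin - cfg$cx_alpha * d, cmax + cfg$cx_alpha * d)
        } else p1
        mut <- runif(p) < cfg$mut_prob
        child[mut] <- child[mut] +
          rnorm(sum(mut), 0, cfg$mut_sigma_frac * width[mut])
        off[i, ] <- pmin(pmax(child, lo), hi)
      }
      off_obj <- evaluate(off)
      elite_idx <- ord[seq_len(cfg$elitism)]
      pop <- rbind(pop[elite_idx, , drop = FALSE], off)
      obj <- c(obj[elite_idx], off_obj)
      colnames(pop) <- bounds$name
      hist_par <- rbind(hist_par, off)
      hist_obj <- c(hist_obj, off_obj)
      trace <- rbind(trace,
                     data.frame(gen = gen, best = min(obj),
                                mean = mean(obj[is.finite(obj)])))
    }
    best <- which.min(obj)
    structure(list(best_par = setNames(pop[best, ], bounds$name),
                   best_obj = obj[best], trace = trace, population = pop,
                   objectives = obj,
                   history = data.frame(hist_par, objective = hist_obj),
                   seed = cfg$seed),
              class = "ga_result")
  })
}
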