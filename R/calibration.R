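#' Parameter ranges for fitting
#'
#' A table of the free parameters with the widest range of potential values
#' from which the Monte Carlo training simulations are sampled.
#' `ranges_ex1()` / `ranges_ex2()` give the stock ranges of the two example
#' models; `ranges_ex1()` can be restricted to a subset of parameters (the
#' remaining ones stay fixed at values supplied via `base_params` in the
#' fitting functions).
#'
#' @param name,lower,upper vectors defining the ranges (`lower < upper`).
#' @return A data frame of class `parameter_ranges`.
#' @export
parameter_ranges <- function(name, lower, upper) {
  if (any(lower >= upper))
    stop("each parameter must have lower < upper")
  structure(data.frame(name = name, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("parameter_ranges", "data.frame"))
}

#' @rdname parameter_ranges
#' @param params subset of parameter names to keep.
#' @export
ranges_ex1 <- function(params = NULL) {
  r <- parameter_ranges(
    name = c("kill_prob", "infiltration", "pdl1_max", "pdl1_rate"),
    lower = c(0.001, 0.05, 0.001, 1e-6),
    upper = c(0.1, 1.0, 0.05, 2e-4))
  if (!is.null(params)) {
    if (!all(params %in% r$name)) stop("unknown ex1 parameter name")
    r <- r[match(params, r$name), , drop = FALSE]
    class(r) <- c("parameter_ranges", "data.frame")
  }
  r
}

#' @rdname parameter_ranges
#' @export
ranges_ex2 <- function(params = NULL) {
  r <- parameter_ranges(
    name = c("kill_prob", "infiltration", "basal_death_prob",
             "hypoxic_radius", "hypoxic_death_prob"),
    lower = c(1e-4, 0.05, 1e-5, 0, 1e-4),
    upper = c(0.02, 1.0, 5e-3, 1500, 0.02))
  if (!is.null(params)) {
    if (!all(params %in% r$name)) stop("unknown ex2 parameter name")
    r <- r[match(params, r$name), , drop = FALSE]
    class(r) <- c("parameter_ranges", "data.frame")
  }
  r
}

#' Sample parameter sets over their ranges
#'
#' Independent uniform draws per dimension, reproducible by seed. These are
#' the Monte Carlo parameter sets the training simulations are run at (the
#' full-scale protocol uses 10,000).
#'
#' @param ranges a [parameter_ranges()].
#' @param n number of parameter sets (>= 1).
#' @param seed RNG seed.
#' @return Numeric matrix (n x n_params) with parameter names as columns.
#' @export
sample_parameters <- function(ranges, n, seed = 1) {
  if (!inherits(ranges, "parameter_ranges")) stop("'ranges' must be parameter_ranges")
  if (n < 1) stop("'n' must be at least 1")
  with_local_seed(seed, {
    m <- vapply(seq_len(nrow(ranges)),
                function(j) runif(n, ranges$lower[j], ranges$upper[j]),
                numeric(n))
    m <- matrix(m, nrow = n)
    colnames(m) <- ranges$name
    m
  })
}

# merge a sampled row into a full parameter set, preserving variant and
# re-validating (e.g. pdl1_rate <= pdl1_max clipped into validity)
override_params <- function(base_params, x) {
  pl <- unclass(base_params)
  for (nm in names(x)) {
    if (!nm %in% names(pl)) stop(sprintf("unknown parameter '%s'", nm))
    pl[[nm]] <- unname(x[[nm]])
  }
  if (identical(attr(base_params, "variant"), "ex1")) {
    pl$pdl1_rate <- min(pl$pdl1_rate, pl$pdl1_max)
    abm_params_ex1(pl$kill_prob, pl$infiltration, pl$pdl1_max, pl$pdl1_rate)
  } else {
    pl$hypoxic_death_prob <- max(pl$hypoxic_death_prob, pl$basal_death_prob)
    abm_params_ex2(pl$kill_prob, pl$infiltration, pl$basal_death_prob,
                   pl$hypoxic_radius, pl$hypoxic_death_prob)
  }
}

# deterministic per-task child seed, independent of evaluation order
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483647) + 1L
}

#' Build a Monte Carlo training set
#'
#' Runs `replicates` simulations per sampled parameter set and processes each
#' final state into a simplified image. Child seeds are a deterministic
#' function of the master seed and the task index, so results are identical
#' whether tasks run serially or in parallel, and the same master seed always
#' reproduces the same training set. Simulation failures are recorded per
#' task rather than aborting the build.
#'
#' @param params_mat matrix from [sample_parameters()].
#' @param base_params an `abm_params` providing values for parameters not in
#'   `params_mat`.
#' @param sim_cfg a [sim_config()].
#' @param pspec a [process_spec()].
#' @param replicates simulation replicates per parameter set (stochastic
#'   simulators are replicated to capture run-to-run variation).
#' @param seed master seed.
#' @return A `training_set`: list with `params` (the matrix), `images`
#'   (list, one per task), `row` (training-set row of each image), `seeds`,
#'   and `failed` (logical per task).
#' @export
build_training_set <- function(params_mat, base_params, sim_cfg, pspec,
                               replicates = 2, seed = 1) {
  n <- nrow(params_mat)
  tasks <- expand.grid(row = seq_len(n), rep = seq_len(replicates))
  tasks <- tasks[order(tasks$row, tasks$rep), ]
  seeds <- vapply(seq_len(nrow(tasks)),
                  function(i) child_seed(seed, tasks$row[i] * 1000 + tasks$rep[i]),
                  integer(1))
  images <- vector("list", nrow(tasks))
  failed <- logical(nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    pars <- override_params(base_params, params_mat[tasks$row[i], ])
    img <- tryCatch({
      ct <- simulate_abm(pars, sim_cfg, seeds[i])
      process_cells(ct, pspec)
    }, error = function(e) NULL)
    if (is.null(img)) failed[i] <- TRUE else images[[i]] <- img
  }
  structure(list(params = params_mat, images = images, row = tasks$row,
                 replicate = tasks$rep, seeds = seeds, failed = failed,
                 base_params = base_params, sim_cfg = sim_cfg,
                 pspec = pspec, seed = seed),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(
    "<training_set> %d parameter sets x %d replicate(s), %d image(s), %d failed\n",
    nrow(x$params), max(x$replicate), sum(!x$failed), sum(x$failed)))
  invisible(x)
}

#' Narrow parameter bounds from the nearest training simulations
#'
#' Projects the target and every training image into the embedding space,
#' takes the `n_closest` training images nearest to the target (ensemble-
#' averaged distance, ties broken by training-set index), and returns the
#' per-parameter minimum and maximum over the selected simulations as the
#' narrowed lower and upper bounds for parameter estimation.
#'
#' @param ens an `encoder_ensemble`.
#' @param target a `simplified_image`.
#' @param ts a `training_set`.
#' @param n_closest how many nearest simulations to use (the stock
#'   four-parameter protocol uses 100; adjust to the model being fit).
#' @return A data frame of class `narrowed_bounds` with columns `name`,
#'   `lower`, `upper`; attributes `distances` (per usable training image),
#'   `selected` (indices into the image list) and `rows` (training-set rows).
#' @export
estimate_bounds <- function(ens, target, ts, n_closest = 100) {
  ok <- which(!ts$failed)
  if (n_closest < 1 || n_closest > length(ok))
    stop(sprintf("'n_closest' must be in [1, %d]", length(ok)))
  d <- ensemble_distances(ens, target, ts$images[ok])
  sel <- ok[order(d, ok)[seq_len(n_closest)]]
  rows <- ts$row[sel]
  sub <- ts$params[rows, , drop = FALSE]
  nb <- data.frame(name = colnames(ts$params),
                   lower = apply(sub, 2, min),
                   upper = apply(sub, 2, max),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(nb, distances = d, selected = sel, rows = rows,
            class = c("narrowed_bounds", "data.frame"))
}

#' Calibration objective
#'
#' Builds the objective function minimized by the GA: simulate the ABM at the
#' candidate parameters (a single replicate per evaluation), process the
#' final state into a simplified image, and return the ensemble-averaged
#' embedding distance to the target image. Degenerate simulations (e.g. all
#' tumor channels empty after extinction) return `penalty` instead of
#' erroring, and a count of such evaluations is kept on the returned
#' function's environment (`attr(fn, "n_degenerate")()`).
#'
#' @param target a `simplified_image`.
#' @param ens an `encoder_ensemble`.
#' @param base_params full `abm_params` supplying non-fitted values.
#' @param sim_cfg a [sim_config()].
#' @param pspec a [process_spec()].
#' @param penalty objective value for degenerate simulations.
#' @param fixed_seed if non-`NULL`, every evaluation simulates with this seed
#'   regardless of the seed the optimizer passes, making the objective a
#'   deterministic function of the parameters. With small populations the
#'   best-of-many-noisy-draws selection otherwise rewards lucky simulations
#'   far from the optimum; a fixed evaluation seed removes that at the cost
#'   of conditioning on one noise realization.
#' @return `function(x, seed)` returning a non-negative scalar.
#' @export
make_objective <- function(target, ens, base_params, sim_cfg, pspec,
                           penalty = 100, fixed_seed = NULL) {
  n_degenerate <- 0L
  fn <- function(x, seed) {
    if (!is.null(fixed_seed)) seed <- fixed_seed
    if (is.null(names(x)))
      stop("objective requires a named parameter vector")
    pars <- override_params(base_params, x)
    img <- tryCatch({
      ct <- simulate_abm(pars, sim_cfg, seed)
      process_cells(ct, pspec)
    }, error = function(e) NULL)
    if (is.null(img)) {
      n_degenerate <<- n_degenerate + 1L
      return(penalty)
    }
    as.numeric(ensemble_distance(ens, target, img))
  }
  attr(fn, "n_degenerate") <- function() n_degenerate
  fn
}

#' End-to-end ABM calibration to a target image
#'
#' The full pipeline: process the target (if given as a cell table), sample
#' training parameters over the widest ranges, run the Monte Carlo training
#' simulations, train the encoder ensemble on their simplified images, narrow
#' the parameter bounds to the min-max of the `n_closest` nearest training
#' simulations, and minimize the ensemble embedding distance with a genetic
#' algorithm. A prebuilt `training_set` and/or `encoder_ensemble` can be
#' supplied to skip those stages.
#'
#' @param target a `cell_table` or `simplified_image` to fit to.
#' @param ranges a [parameter_ranges()] over the fitted parameters.
#' @param base_params full `abm_params` supplying non-fitted values (and the
#'   variant).
#' @param sim_cfg a [sim_config()].
#' @param pspec a [process_spec()].
#' @param encoder_cfg an [encoder_config()] (input shape is derived from the
#'   processed target when `NULL`).
#' @param ga_cfg a [ga_config()].
#' @param n_train training simulations (parameter sets) to generate.
#' @param replicates simulation replicates per training parameter set.
#' @param n_members ensemble size.
#' @param n_closest nearest simulations used for bound narrowing.
#' @param seed master seed; all stage seeds derive from it and are recorded.
#' @param training_set optional prebuilt `training_set`.
#' @param ensemble optional prebuilt `encoder_ensemble`.
#' @param bounds_override optional named list `name -> c(lower, upper)`
#'   replacing narrowed bounds for selected parameters; every use is recorded
#'   in the result's `audit_log`.
#' @param objective_seed `"fresh"` (a new simulation seed per candidate
#'   evaluation; the GA population averages over simulator noise) or
#'   `"fixed"` (one seed for all evaluations, making the objective
#'   deterministic -- preferable for small populations, where the arg-min of
#'   many noisy draws is biased toward lucky simulations).
#' @return A `fit_result`: narrowed bounds, GA trace, best parameters (as a
#'   full `abm_params`), best objective, a top-10 summary table
#'   (best/max/min/mean/CV per parameter), all seeds, and the audit log.
#' @export
fit_abm <- function(target, ranges, base_params, sim_cfg, pspec,
                    encoder_cfg = NULL, ga_cfg = ga_config(),
                    n_train = 300, replicates = 2, n_members = 5,
                    n_closest = 100, seed = 1, training_set = NULL,
                    ensemble = NULL, bounds_override = NULL,
                    objective_seed = c("fresh", "fixed")) {
  objective_seed <- match.arg(objective_seed)
  audit <- character(0)
  target_img <- if (inherits(target, "simplified_image")) target
                else process_cells(target, pspec)
  ts <- training_set
  if (is.null(ts)) {
    pm <- sample_parameters(ranges, n_train, seed = child_seed(seed, 1))
    ts <- build_training_set(pm, base_params, sim_cfg, pspec,
                             replicates = replicates,
                             seed = child_seed(seed, 2))
  }
  ens <- ensemble
  if (is.null(ens)) {
    if (is.null(encoder_cfg)) {
      d <- dim(target_img)
      encoder_cfg <- encoder_config(input_shape = d)
    }
    # failed simulations leave gaps: cap the contrastive batch at half the
    # usable images so training always has at least two batches' worth
    n_ok <- sum(!ts$failed)
    encoder_cfg$batch_size <- max(2L, min(encoder_cfg$batch_size,
                                          n_ok %/% 2L))
    ens <- train_ensemble(ts$images[!ts$failed], encoder_cfg,
                          n_members = n_members,
                          seed = child_seed(seed, 3))
  }
  nb <- estimate_bounds(ens, target_img, ts, n_closest = n_closest)
  if (!is.null(bounds_override)) {
    for (nm in names(bounds_override)) {
      i <- match(nm, nb$name)
      if (is.na(i)) stop(sprintf("bounds_override names unknown parameter '%s'", nm))
      audit <- c(audit, sprintf(
        "manual bound override for '%s': [%g, %g] -> [%g, %g]",
        nm, nb$lower[i], nb$upper[i],
        bounds_override[[nm]][1], bounds_override[[nm]][2]))
      nb$lower[i] <- bounds_override[[nm]][1]
      nb$upper[i] <- bounds_override[[nm]][2]
    }
  }
  fn <- make_objective(target_img, ens, base_params, sim_cfg, pspec,
                       fixed_seed = if (objective_seed == "fixed")
                         child_seed(seed, 5) else NULL)
  ga_cfg$seed <- child_seed(seed, 4)
  ga <- ga_optimize(fn, nb, ga_cfg)
  top10 <- top_fits_summary(ga, k = 10)
  structure(list(bounds = nb, ga = ga, trace = ga$trace,
                 best_par = ga$best_par,
                 best_params = override_params(base_params, ga$best_par),
                 best_obj = ga$best_obj, top10 = top10,
                 n_degenerate = attr(fn, "n_degenerate")(),
                 training_set = ts, ensemble = ens,
                 seeds = list(master = seed, sample = child_seed(seed, 1),
                              training = child_seed(seed, 2),
                              ensemble = child_seed(seed, 3),
                              ga = child_seed(seed, 4),
                              objective = if (objective_seed == "fixed")
                                child_seed(seed, 5) else "fresh"),
                 audit_log = audit),
            class = "fit_result")
}

# spread of the k best evaluated parameter sets: best/max/min/mean/CV per
# parameter (a tight spread indicates the GA converged to similar sets)
top_fits_summary <- function(ga, k = 10) {
  h <- ga$history
  h <- h[order(h$objective), , drop = FALSE]
  h <- h[!duplicated(h[, setdiff(names(h), "objective"), drop = FALSE]), ,
         drop = FALSE]
  h <- head(h, k)
  pars <- h[, setdiff(names(h), "objective"), drop = FALSE]
  data.frame(
    parameter = names(pars),
    best = as.numeric(pars[1, ]),
    maximum = vapply(pars, max, numeric(1)),
    minimum = vapply(pars, min, numeric(1)),
    mean = vapply(pars, mean, numeric(1)),
    cv = vapply(pars, function(v) sd(v) / mean(v), numeric(1)),
    row.names = NULL)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  best objective:", format(x$best_obj, digits = 4), "\n")
  cat("  best parameters:\n")
  print(x$best_par)
  cat("  top-10 spread:\n")
  print(x$top10, digits = 4)
  if (length(x$audit_log)) cat("  audit:", x$audit_log, sep = "\n    ")
  invisible(x)
}
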