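#' Desk-scale self-fit experiment for the PD-L1 model
#'
#' Fits the PD-L1 example ABM to one of its own simulations: a base
#' simulation is generated at the nominal parameter set
#' ([nominal_params_ex1()]), the full calibration pipeline (Monte Carlo
#' training set over the widest parameter ranges, contrastive encoder
#' ensemble, nearest-neighbor bound narrowing, genetic algorithm) is run
#' against it, and the recovered parameters are compared to the nominal ones.
#' Since the generating parameters are known, the relative recovery error
#' measures how well the learned embedding distance identifies parameters.
#'
#' Defaults are a desk-scale protocol (about 100 training simulations, a
#' 3-member ensemble, a GA population of 20): the same pipeline the
#' full-scale experiments run with 10,000 simulations, 50 networks and
#' populations of 300-400, shrunk to a single-CPU budget.
#'
#' @param master_seed seed for the whole experiment (base simulation,
#'   sampling, training, GA all derive from it).
#' @param fit_params names of the parameters to fit; the rest stay fixed at
#'   their nominal values. Default fits the T-cell killing probability only.
#' @param n_train training parameter sets.
#' @param replicates simulation replicates per training parameter set.
#' @param n_members ensemble size.
#' @param n_closest nearest training simulations for bound narrowing.
#' @param ga_pop,ga_gens GA population size and generation count.
#' @param target simplified-image size.
#' @param sim_cfg a variant-`"ex1"` [sim_config()].
#' @param encoder_cfg an [encoder_config()]; `NULL` builds the protocol
#'   default (16-32 filter conv stack, hidden 32, temperature 0.2, large
#'   contrastive batches, 60 epochs).
#' @return A list: `fit` (the [fit_abm()] result), `nominal` (named vector of
#'   the fitted parameters' nominal values), `recovered` (best-fit values),
#'   `rel_error` (absolute relative recovery error per parameter), and
#'   `target_seed`.
#' @export
self_fit_ex1 <- function(master_seed = 1, fit_params = "kill_prob",
                         n_train = 100, replicates = 1, n_members = 3,
                         n_closest = 20, ga_pop = 20, ga_gens = 8,
                         target = c(16, 16), sim_cfg = sim_config("ex1"),
                         encoder_cfg = NULL) {
  nominal <- nominal_params_ex1()
  pspec <- process_spec_ex1(target = target)
  target_seed <- child_seed(master_seed, 99)
  base <- make_base_simulation(nominal, sim_cfg, pspec, seed = target_seed)
  ranges <- ranges_ex1(fit_params)
  n_img <- n_train * replicates
  enc_cfg <- encoder_cfg
  if (is.null(enc_cfg))
    enc_cfg <- encoder_config(
      input_shape = c(target, length(pspec$schema$channels)),
      conv_filters = c(16, 32), hidden = 32, temperature = 0.2,
      batch_size = n_img %/% 2L, epochs = 60, lr = 1e-3)
  ga_cfg <- ga_config(pop_size = ga_pop, generations = ga_gens)
  fit <- fit_abm(base$image, ranges, base_params = nominal,
                 sim_cfg = sim_cfg, pspec = pspec, encoder_cfg = enc_cfg,
                 ga_cfg = ga_cfg, n_train = n_train,
                 replicates = replicates, n_members = n_members,
                 n_closest = n_closest, seed = master_seed)
  nom <- unlist(unclass(nominal))[fit_params]
  rec <- fit$best_par[fit_params]
  list(fit = fit, nominal = nom, recovered = rec,
       rel_error = abs(rec - nom) / abs(nom), target_seed = target_seed)
}

#' First generation at which the GA best objective plateaus
#'
#' The generation index (0 = initial population) at which the best objective
#' first comes within `tol` (relative) of the final best value. Used to check
#' that only a small number of fitting steps are needed before the best fit
#' levels off.
#'
#' @param trace a GA trace data frame (`gen`, `best`, `mean`) from
#'   [ga_optimize()] or a `fit_result`.
#' @param tol relative tolerance (default 0.05).
#' @return Integer generation index.
#' @export
plateau_generation <- function(trace, tol = 0.05) {
  if (inherits(trace, "fit_result")) trace <- trace$trace
  final <- trace$best[nrow(trace)]
  thresh <- final + tol * abs(final)
  trace$gen[which(trace$best <= thresh)[1]]
}
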