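#' @title ABM parameter sets
#'
#' @description Constructors for the free parameters of the two example ABM
#' variants. `abm_params_ex1()` parameterizes the PD-L1 suppression model:
#' tumor cells gain the checkpoint ligand PD-L1 in the presence of T cells and
#' suppress adjacent active T cells with probability equal to their current
#' PD-L1 level; suppressed T cells no longer migrate or kill, and killed tumor
#' cells are removed. `abm_params_ex2()` parameterizes the hypoxic-core model:
#' no PD-L1/suppression, but tumor cells die spontaneously (with an elevated
#' probability inside a static central hypoxic disk) and dead tumor cells
#' persist in place.
#'
#' @param kill_prob probability that an active T cell kills an adjacent live
#'   tumor cell, per encounter per timestep.
#' @param infiltration dimensionless fraction in (0, 1] of the current tumor
#'   radius that T cells infiltrate: migrating T cells halt at radial
#'   coordinate `(1 - infiltration) * tumor_radius`.
#' @param pdl1_max maximum PD-L1 level (a probability) a tumor cell can reach.
#' @param pdl1_rate PD-L1 increment per timestep while at least one T cell is
#'   within interaction range; must not exceed `pdl1_max`.
#' @param basal_death_prob per-step probability of spontaneous death for live
#'   tumor cells outside the hypoxic region.
#' @param hypoxic_radius radius (micrometers) of the central hypoxic disk.
#' @param hypoxic_death_prob per-step death probability inside the hypoxic
#'   disk; must be at least `basal_death_prob`.
#' @return An object of class `abm_params` (a named list with a `variant`
#'   attribute, `"ex1"` or `"ex2"`).
#' @examples
#' abm_params_ex1(0.02, 0.8, 0.01, 5e-5)
#' abm_params_ex2(4e-3, 0.39, 1e-3, 641, 5e-3)
#' @export
abm_params_ex1 <- function(kill_prob, infiltration, pdl1_max, pdl1_rate) {
  check_prob(kill_prob, "kill_prob")
  check_prob(pdl1_max, "pdl1_max")
  check_prob(pdl1_rate, "pdl1_rate")
  if (!is.numeric(infiltration) || infiltration <= 0 || infiltration > 1)
    stop("'infiltration' must be in (0, 1]")
  if (pdl1_rate > pdl1_max)
    stop("'pdl1_rate' must not exceed 'pdl1_max'")
  structure(
    list(kill_prob = kill_prob, infiltration = infiltration,
         pdl1_max = pdl1_max, pdl1_rate = pdl1_rate),
    class = "abm_params", variant = "ex1")
}

#' @rdname abm_params_ex1
#' @export
abm_params_ex2 <- function(kill_prob, infiltration, basal_death_prob,
                           hypoxic_radius, hypoxic_death_prob) {
  check_prob(kill_prob, "kill_prob")
  check_prob(basal_death_prob, "basal_death_prob")
  check_prob(hypoxic_death_prob, "hypoxic_death_prob")
  if (!is.numeric(infiltration) || infiltration <= 0 || infiltration > 1)
    stop("'infiltration' must be in (0, 1]")
  if (hypoxic_radius < 0) stop("'hypoxic_radius' must be non-negative")
  if (hypoxic_death_prob < basal_death_prob)
    stop("'hypoxic_death_prob' must be at least 'basal_death_prob'")
  structure(
    list(kill_prob = kill_prob, infiltration = infiltration,
         basal_death_prob = basal_death_prob, hypoxic_radius = hypoxic_radius,
         hypoxic_death_prob = hypoxic_death_prob),
    class = "abm_params", variant = "ex2")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

#' Simulation configuration
#'
#' Fixed (non-fitted) constants of the ABM: the biophysical scaffolding the
#' fit is conditioned on. Cell diameter defaults to 20 micrometers (a tumor
#' of 150 cell diameters spans roughly 3,000 micrometers). The hypoxic disk of
#' the `ex2` variant is static and centered on the initial tumor centroid,
#' which the initializer places at the origin.
#'
#' @param variant `"ex1"` (PD-L1 suppression) or `"ex2"` (hypoxic core).
#' @param domain_size side length of the square domain, micrometers; cells are
#'   clamped to `[-domain_size/2, domain_size/2]`.
#' @param cell_diameter cell diameter, micrometers.
#' @param n_steps number of timesteps to simulate.
#' @param proliferation_prob per-step division probability of live tumor cells.
#' @param recruitment_rate mean number of T cells recruited at the tumor rim
#'   per step (fractional part realized as a Bernoulli draw).
#' @param migration_step distance an active T cell migrates inward per step,
#'   micrometers.
#' @param interaction_radius_factor two cells interact ("nearby") when their
#'   center distance is at most this factor times the sum of their radii.
#' @param init_tumor_radius radius of the initial hexagonally packed tumor
#'   disk, micrometers.
#' @param relax_tol_frac mechanics relaxation stops when the worst pairwise
#'   overlap is below this fraction of a cell radius.
#' @param relax_max_iter maximum relaxation sweeps per call.
#' @param hypoxic_center center of the hypoxic disk (ex2), micrometers.
#' @return An object of class `sim_config` (named list).
#' @export
sim_config <- function(variant = c("ex1", "ex2"),
                       domain_size = 4000,
                       cell_diameter = 20,
                       n_steps = if (variant == "ex1") 100 else 60,
                       proliferation_prob = 0.02,
                       recruitment_rate = 2,
                       migration_step = 10,
                       interaction_radius_factor = 1.1,
                       init_tumor_radius = if (variant == "ex1") 150 else 300,
                       relax_tol_frac = 0.05,
                       relax_max_iter = 50,
                       hypoxic_center = c(0, 0)) {
  variant <- match.arg(variant)
  force(n_steps); force(init_tumor_radius)
  if (n_steps <= 0) stop("'n_steps' must be positive")
  if (cell_diameter <= 0) stop("'cell_diameter' must be positive")
  structure(
    list(variant = variant, domain_size = domain_size,
         cell_diameter = cell_diameter, n_steps = as.integer(n_steps),
         proliferation_prob = proliferation_prob,
         recruitment_rate = recruitment_rate, migration_step = migration_step,
         interaction_radius_factor = interaction_radius_factor,
         init_tumor_radius = init_tumor_radius,
         relax_tol_frac = relax_tol_frac,
         relax_max_iter = as.integer(relax_max_iter),
         hypoxic_center = hypoxic_center),
    class = "sim_config")
}

kind_levels <- function() {
  c("tumor_live", "tumor_dead", "tcell_active", "tcell_suppressed")
}

state_to_table <- function(m) {
  df <- data.frame(
    id = as.integer(m[, "id"]),
    kind = kind_levels()[as.integer(m[, "kind"])],
    x = m[, "x"], y = m[, "y"], radius = m[, "radius"], pdl1 = m[, "pdl1"],
    stringsAsFactors = FALSE)
  class(df) <- c("cell_table", "data.frame")
  df
}

table_to_state <- function(ct) {
  kind <- match(ct$kind, kind_levels())
  if (anyNA(kind))
    stop("unknown cell kind in state: ",
         paste(unique(ct$kind[is.na(kind)]), collapse = ", "))
  pdl1 <- if ("pdl1" %in% names(ct)) ct$pdl1 else rep(0, nrow(ct))
  radius <- if ("radius" %in% names(ct)) ct$radius else rep(10, nrow(ct))
  id <- if ("id" %in% names(ct)) ct$id else seq_len(nrow(ct))
  cbind(id = id, kind = kind, x = ct$x, y = ct$y, radius = radius,
        pdl1 = pdl1)
}

check_variant <- function(params, cfg) {
  if (!inherits(params, "abm_params")) stop("'params' must be an abm_params")
  if (!inherits(cfg, "sim_config")) stop("'cfg' must be a sim_config")
  if (!identical(attr(params, "variant"), cfg$variant))
    stop(sprintf("parameter variant '%s' does not match config variant '%s'",
                 attr(params, "variant"), cfg$variant))
  invisible(TRUE)
}

#' Initial ABM state
#'
#' Hexagonally packed disk of live tumor cells of radius
#' `cfg$init_tumor_radius`, centered on the origin. No T cells.
#'
#' @param cfg a [sim_config()].
#' @return A `cell_table` of the initial cells.
#' @export
init_state <- function(cfg) {
  state_to_table(cpp_init_state(unclass(cfg)))
}

#' Advance an ABM state by one timestep
#'
#' Applies, in fixed order: tumor proliferation (with mechanics relaxation),
#' PD-L1 gain (ex1), T-cell recruitment at the tumor rim and inward migration,
#' T-cell killing, suppression (ex1), death/removal (ex2 deaths persist as
#' immobile dead cells), and a final overlap relaxation. Cells within each
#' phase are processed in an order randomized from the step's own RNG stream,
#' which is derived from `(seed, t)` only, so a step is reproducible
#' independently of earlier steps.
#'
#' @param state a `cell_table` (e.g. from [init_state()]).
#' @param params an [abm_params_ex1()] or [abm_params_ex2()] matching the
#'   config variant.
#' @param cfg a [sim_config()].
#' @param seed integer simulation seed.
#' @param t current timestep (0-based).
#' @param log_events if `TRUE`, kill and suppression events are returned.
#' @return A list with elements `state` (the updated `cell_table`), `t`
#'   (incremented step), and `events` (data frame with columns `step`, `type`
#'   in `c("kill", "suppress")`, `actor_id`, `actor_kind`, `target_id`).
#' @export
abm_step <- function(state, params, cfg, seed, t = 0, log_events = FALSE) {
  check_variant(params, cfg)
  res <- cpp_step(table_to_state(state), unclass(params), unclass(cfg),
                  as.double(seed), as.integer(t), isTRUE(log_events))
  list(state = state_to_table(res$state), t = res$t,
       events = label_events(res$events))
}

label_events <- function(ev) {
  ev$type <- c("kill", "suppress")[ev$type]
  ev$actor_kind <- kind_levels()[ev$actor_kind]
  ev
}

#' Run an ABM simulation
#'
#' Initializes a tumor disk and advances it `cfg$n_steps` steps. All
#' randomness comes from a private stream seeded by `seed`, so identical
#' `(params, cfg, seed)` reproduce the output bit-for-bit regardless of the
#' state of R's global RNG. Extinction of all live tumor cells is not an
#' error; the returned table simply carries `attr(, "extinct") == TRUE`.
#'
#' @inheritParams abm_step
#' @return A `cell_table` of the final state with columns `id`, `kind`, `x`,
#'   `y`, `radius`, `pdl1`, and attributes `extinct`, `params`, `config`,
#'   `seed` (and `events` when `log_events = TRUE`).
#' @examples
#' cfg <- sim_config("ex1", init_tumor_radius = 60, n_steps = 10)
#' ct <- simulate_abm(abm_params_ex1(0.02, 0.8, 0.01, 5e-5), cfg, seed = 1)
#' table(ct$kind)
#' @export
simulate_abm <- function(params, cfg, seed, log_events = FALSE) {
  check_variant(params, cfg)
  res <- cpp_simulate(unclass(params), unclass(cfg), as.double(seed),
                      isTRUE(log_events))
  ct <- state_to_table(res$state)
  attr(ct, "extinct") <- res$extinct
  attr(ct, "params") <- params
  attr(ct, "config") <- cfg
  attr(ct, "seed") <- seed
  if (isTRUE(log_events)) attr(ct, "events") <- label_events(res$events)
  ct
}

#' Cells within a radius of a focal cell
#'
#' Returns the cells (excluding the focal cell itself) whose center distance
#' to the focal cell is at most `radius`, ordered by cell id. Uses the same
#' bucket-grid search as the simulator's interaction phases.
#'
#' @param state a `cell_table`.
#' @param id id of the focal cell; must be present in `state`.
#' @param radius search radius, micrometers (non-negative).
#' @return The matching rows of `state`, ordered by `id`.
#' @export
neighbors_within <- function(state, id, radius) {
  row <- match(id, state$id)
  if (is.na(row)) stop(sprintf("cell id %s is not in the state", id))
  if (!is.numeric(radius) || radius < 0)
    stop("'radius' must be non-negative")
  idx <- cpp_neighbors_within(table_to_state(state), row, radius)
  state[idx, , drop = FALSE]
}

#' Tumor radius of a state
#'
#' Maximum distance from the tumor centroid (over live and dead tumor cells)
#' to any tumor cell center. Errors when the state holds no tumor cells.
#'
#' @param state a `cell_table` containing at least one tumor cell.
#' @return Radius in micrometers.
#' @export
tumor_radius <- function(state) {
  if (!any(state$kind %in% c("tumor_live", "tumor_dead")))
    stop("state contains no tumor cells; tumor radius undefined")
  cpp_tumor_radius(table_to_state(state))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(x$kind)
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sep = "")
  }
  if (isTRUE(attr(x, "extinct"))) cat(" [extinct]")
  cat("\n")
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
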