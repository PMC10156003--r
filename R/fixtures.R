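#' Nominal parameters of the PD-L1 example model
#'
#' The manually chosen parameter set used to generate the base simulation for
#' the self-fit experiment: killing probability 0.02, infiltration 0.8,
#' maximum PD-L1 0.01, PD-L1 rate 5e-5.
#'
#' @return An [abm_params_ex1()] object.
#' @export
nominal_params_ex1 <- function() {
  abm_params_ex1(kill_prob = 0.02, infiltration = 0.8, pdl1_max = 0.01,
                 pdl1_rate = 5e-5)
}

#' Generate a base simulation for self-fitting
#'
#' Runs the PD-L1 model at a known ("nominal") parameter set and processes
#' the final state, producing the target that the self-fit experiment then
#' tries to recover the parameters of. A manifest records the generator,
#' spec, seed and cheap content checksums so the fixture can be regenerated
#' and verified byte-identically.
#'
#' @param nominal an [abm_params_ex1()] (default [nominal_params_ex1()]).
#' @param sim_cfg a [sim_config()] for variant `"ex1"`.
#' @param pspec a [process_spec()] (default [process_spec_ex1()]).
#' @param seed simulation seed.
#' @return List with `cells` (`cell_table`), `image` (`simplified_image`)
#'   and `manifest`.
#' @export
make_base_simulation <- function(nominal = nominal_params_ex1(),
                                 sim_cfg = sim_config("ex1"),
                                 pspec = process_spec_ex1(),
                                 seed = 1) {
  cells <- simulate_abm(nominal, sim_cfg, seed)
  image <- process_cells(cells, pspec)
  manifest <- list(generator = "make_base_simulation",
                   params = unclass(nominal), seed = seed,
                   n_cells = nrow(cells),
                   checksum = fixture_checksum(cells))
  list(cells = cells, image = image, manifest = manifest)
}

fixture_checksum <- function(ct) {
  sprintf("%d:%.6f:%.6f", nrow(ct), sum(ct$x) %% 1e6, sum(ct$y) %% 1e6)
}

#' Ring-tumor fixture specification
#'
#' Parametric stand-in for a live/dead-stained tumor image at image scale: a
#' disk of cells roughly 5,500 micrometers across whose central "hypoxic"
#' core is dead and whose rim is alive. Defaults place cells on a jittered
#' hexagonal lattice at one cell-diameter spacing. The true density and core
#' extent of any particular imaged tumor are unknown; these defaults are
#' plausible placeholders, and the generator is explicitly synthetic.
#'
#' @param outer_radius tumor radius, micrometers (default 2750, i.e. a
#'   5,500-micron diameter).
#' @param dead_core_radius radius of the dead core, micrometers; must be
#'   smaller than `outer_radius`.
#' @param cell_spacing lattice spacing, micrometers.
#' @param live_density,dead_density retention probability of lattice sites
#'   outside/inside the core, in (0, 1].
#' @param jitter_sd Gaussian positional jitter, micrometers.
#' @param mix_frac fraction of core cells labeled live instead of dead
#'   (emulates live/dead stain overlap; default 0).
#' @param seed RNG seed.
#' @return An object of class `ring_tumor_spec`.
#' @export
ring_tumor_spec <- function(outer_radius = 2750, dead_core_radius = 1100,
                            cell_spacing = 20, live_density = 0.9,
                            dead_density = 0.9, jitter_sd = 4,
                            mix_frac = 0, seed = 1) {
  if (dead_core_radius >= outer_radius)
    stop("'dead_core_radius' must be smaller than 'outer_radius'")
  if (live_density <= 0 || live_density > 1 ||
      dead_density <= 0 || dead_density > 1)
    stop("densities must be in (0, 1]")
  structure(list(outer_radius = outer_radius,
                 dead_core_radius = dead_core_radius,
                 cell_spacing = cell_spacing, live_density = live_density,
                 dead_density = dead_density, jitter_sd = jitter_sd,
                 mix_frac = mix_frac, seed = seed),
            class = "ring_tumor_spec")
}

#' Generate a ring-tumor cell table
#'
#' Jittered hexagonal placement at `cell_spacing`, thinned by the live/dead
#' densities; cells inside `dead_core_radius` are labeled `tumor_dead`,
#' outside `tumor_live`. Reproducible by the spec's seed.
#'
#' @param spec a [ring_tumor_spec()].
#' @return A `cell_table` with a `manifest` attribute.
#' @export
make_ring_tumor <- function(spec) {
  if (!inherits(spec, "ring_tumor_spec")) stop("'spec' must be a ring_tumor_spec")
  with_local_seed(spec$seed, {
    dx <- spec$cell_spacing
    dy <- spec$cell_spacing * sqrt(3) / 2
    ny <- floor(spec$outer_radius / dy) + 1
    rows <- -ny:ny
    pts <- do.call(rbind, lapply(rows, function(iy) {
      py <- iy * dy
      off <- if (iy %% 2 == 0) 0 else dx / 2
      half <- sqrt(max(0, spec$outer_radius^2 - py^2))
      nx <- floor((half + dx) / dx)
      px <- (-nx:nx) * dx + off
      cbind(px, py)
    }))
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    keep_r <- r <= spec$outer_radius
    pts <- pts[keep_r, , drop = FALSE]
    r <- r[keep_r]
    inside <- r < spec$dead_core_radius  # half-open: core radius 0 = no core
    dens <- ifelse(inside, spec$dead_density, spec$live_density)
    keep <- runif(length(r)) < dens
    if (!any(keep))
      stop("spacing/density too sparse: no cells placed")
    pts <- pts[keep, , drop = FALSE]
    inside <- inside[keep]
    kind <- ifelse(inside, "tumor_dead", "tumor_live")
    if (spec$mix_frac > 0) {
      flip <- inside & runif(length(kind)) < spec$mix_frac
      kind[flip] <- "tumor_live"
    }
    x <- pts[, 1] + rnorm(nrow(pts), 0, spec$jitter_sd)
    y <- pts[, 2] + rnorm(nrow(pts), 0, spec$jitter_sd)
    ct <- cell_table(x, y, kind)
    attr(ct, "manifest") <- list(generator = "make_ring_tumor",
                                 spec = unclass(spec),
                                 checksum = fixture_checksum(ct))
    ct
  })
}

#' Generate two families of simplified images
#'
#' Test harness for encoder separation checks: `n` processed images per
#' family, each family drawn from a ring-tumor spec with per-member seed
#' variation (so members differ stochastically while families differ
#' structurally).
#'
#' @param specA,specB [ring_tumor_spec()]s for the two families.
#' @param n images per family (>= 2).
#' @param seed master seed.
#' @param pspec a [process_spec()] applied to each generated table (default:
#'   live+dead presence channels at the spec's spacing).
#' @return List with elements `A` and `B`, each a list of `n`
#'   `simplified_image`s.
#' @export
make_family_pair <- function(specA, specB, n = 16, seed = 1,
                             pspec = NULL) {
  if (n < 2) stop("'n' must be at least 2")
  if (is.null(pspec))
    pspec <- process_spec(schema_ex2(),
                          cell_diameter = specA$cell_spacing,
                          tumor_channels = c("tumor_live", "tumor_dead"))
  gen <- function(spec, offset) {
    lapply(seq_len(n), function(i) {
      s <- spec
      s$seed <- child_seed(seed, offset + i)
      process_cells(make_ring_tumor(s), pspec)
    })
  }
  list(A = gen(specA, 0), B = gen(specB, 10000))
}
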