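# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# quick configurations for unit tests (smaller tumor, fewer steps); any
# field can be overridden by name
cfg_with <- function(defaults, overrides) {
  do.call(sim_config, utils::modifyList(defaults, overrides))
}

quick_cfg_ex1 <- function(...) {
  cfg_with(list(variant = "ex1", init_tumor_radius = 60, n_steps = 30),
           list(...))
}

quick_cfg_ex2 <- function(...) {
  cfg_with(list(variant = "ex2", init_tumor_radius = 150, n_steps = 20),
           list(...))
}

# hand-built two-cell state: one tumor cell and one active T cell 15 um apart
two_cell_state <- function(gap = 15) {
  ct <- cell_table(x = c(0, gap), y = c(0, 0),
                   kind = c("tumor_live", "tcell_active"),
                   pdl1 = c(0, 0))
  ct$radius <- c(10, 10)
  ct
}

# a config under which nothing stochastic happens except what the test enables
inert_cfg <- function(variant = "ex1", ...) {
  cfg_with(list(variant = variant, proliferation_prob = 0,
                recruitment_rate = 0, migration_step = 0, n_steps = 1,
                init_tumor_radius = 30),
           list(...))
}

# ring/disk image families for encoder tests (16x16, two channels)
family_pspec <- function() {
  process_spec(schema_ex2(), cell_diameter = 20,
               tumor_channels = c("tumor_live", "tumor_dead"),
               target = c(16, 16))
}

ring_disk_families <- function() {
  cached("ring_disk_families", {
    sA <- ring_tumor_spec(outer_radius = 600, dead_core_radius = 300,
                          cell_spacing = 20, jitter_sd = 4)
    sB <- ring_tumor_spec(outer_radius = 600, dead_core_radius = 1,
                          cell_spacing = 20, jitter_sd = 4)
    suppressMessages(make_family_pair(sA, sB, n = 24, seed = 11,
                                      pspec = family_pspec()))
  })
}

# small trained ensemble over the two families (used by metric/bounds tests)
family_ensemble <- function() {
  cached("family_ensemble", {
    fam <- ring_disk_families()
    cfg <- encoder_config(input_shape = c(16, 16, 2),
                          conv_filters = c(8, 16), hidden = 16,
                          batch_size = 16, epochs = 10, lr = 2e-3)
    train_ensemble(c(fam$A, fam$B), cfg, n_members = 3, seed = 5)
  })
}

# desk-scale single-parameter self-fits (shared by the acceptance tests)
selffit_results <- function() {
  cached("selffit_results", {
    lapply(1:3, function(s)
      suppressMessages(self_fit_ex1(master_seed = s)))
  })
}
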