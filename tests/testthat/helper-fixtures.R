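# Shared fixtures: a realistic three-agent panel, a unit-box panel for
# optimizer stress tests, and truth-surface builders.

pmr_panel <- function() {
  agent_panel(
    agent_spec("propolis", "fold-dilution", 0, 1e-4, stock_mass_conc = 200),
    agent_spec("metformin", "mM", 0, 10),
    agent_spec("regorafenib", "uM", 0, 6.5)
  )
}

unit_panel <- function() {
  agent_panel(agent_spec("a", "u", 0, 1),
              agent_spec("b", "u", 0, 2),
              agent_spec("c", "u", 0, 3))
}

term_names_for <- function(panel) rsmopt:::.term_names(names(panel))

# A plausible viability truth on the PMR panel: high control viability,
# all three agents suppressive, mild curvature and one synergy term.
pmr_truth_coef <- function() {
  c("(Intercept)" = 100, propolis = -3e5, metformin = -4,
    regorafenib = -6, "propolis^2" = 1.2e9, "metformin^2" = 0.18,
    "regorafenib^2" = 0.35, "propolis:metformin" = 1.5e4,
    "propolis:regorafenib" = 2e4, "metformin:regorafenib" = 0.12)
}

# Random full-rank quadratic model on the unit panel, fitted exactly from
# noise-free data on the default grid.
random_unit_model <- function(seed, panel = unit_panel(),
                              spec = design_spec(panel)) {
  set.seed(seed)
  co <- stats::rnorm(10, 0, c(50, 20, 10, 7, 15, 4, 2, 5, 3, 2))
  names(co) <- term_names_for(panel)
  tr <- surface_truth(co, panel, grid = default_dose_grid(panel),
                      noise_sd = 0, bio_rep_sd = 0, n_tech = 1, n_bio = 1,
                      seed = seed)
  fit_quadratic_surface(
    aggregate_replicates(generate_viability_table(tr), panel), spec)
}

# Long-schema record table built by hand (no generator) for io tests.
tiny_records <- function(panel = pmr_panel()) {
  data.frame(
    propolis = c(0, 1e-4, 1e-4), metformin = c(0, 3, 3),
    regorafenib = c(0, 6.5, 6.5),
    endpoint = "viability_pct", value = c(100, 40, 42),
    context = "FA-free", subject = "PLC",
    bio_rep = c(1L, 1L, 2L), tech_rep = 1L
  )
}
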