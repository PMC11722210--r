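# Shared fixtures, built in code at test time.

# Two-species irreversible decay A -> B at a fixed rate; linear, so the
# solution is available in closed form.
decay_network <- function(k = 0.3) {
  reaction_network(c("A", "B"),
                   list(parse_reaction(sprintf("A -> B @ fixed:%g", k))))
}

# A purely unimolecular 3-species chain with a loop; linear dynamics
# x' = M x, solvable by the matrix exponential.
linear_network <- function() {
  reaction_network(c("A", "B", "C"), lapply(c(
    "A -> B @ fixed:0.7",
    "B -> C @ fixed:0.4",
    "C -> A @ fixed:0.2",
    "B -> A @ fixed:0.1"
  ), parse_reaction))
}

# Rate matrix M of a unimolecular network so that x' = M x.
unimolecular_rate_matrix <- function(net) {
  k <- vapply(net$reactions, function(r) r$rate$value, numeric(1))
  ns <- length(net$species)
  M <- matrix(0, ns, ns)
  for (j in seq_along(net$reactions)) {
    from <- which(net$reactant_stoich[j, ] > 0)
    M[, from] <- M[, from] + k[j] * net$net_stoich[j, ]
  }
  M
}

# Small but complete scenario bundles, cached across test files.
.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function(scenario = "LARGE", n_cells = 1200, seed = 101) {
  key <- paste0("bundle_", scenario, "_", n_cells, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- simulator_config(n_cells = n_cells, scenario = scenario,
                            seed = seed)
    .fixture_env[[key]] <- generate_scenario(cfg)
  }
  .fixture_env[[key]]
}

# Selection report on a small LARGE bundle, reused by selection and CLI
# tests (estimation dominates the cost, so share it).
small_report <- function() {
  if (is.null(.fixture_env$small_report)) {
    .fixture_env$small_report <- run_model_selection(
      small_bundle(), n_starts = 4, search_size = 400)
  }
  .fixture_env$small_report
}

# Full-size study runs (8000 cells, defaults, B = 200), one per
# scenario, shared across the acceptance checks.
study_run <- function(scenario, seed = 1) {
  key <- paste0("study_", scenario, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    bundle <- generate_scenario(
      simulator_config(n_cells = 8000, scenario = scenario, seed = seed))
    report <- run_model_selection(bundle)
    boot <- bootstrap_model_selection(bundle, B = 200, seed = seed,
                                      report = report)
    .fixture_env[[key]] <- list(bundle = bundle, report = report,
                                boot = boot)
  }
  .fixture_env[[key]]
}
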