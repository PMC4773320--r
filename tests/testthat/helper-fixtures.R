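# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

test_spec <- function() {
  if (is.null(.fixtures$spec)) .fixtures$spec <- population_spec()
  .fixtures$spec
}

test_drug <- function() {
  if (is.null(.fixtures$drug)) .fixtures$drug <- drug_params()
  .fixtures$drug
}

test_ref <- function() {
  if (is.null(.fixtures$ref)) {
    .fixtures$ref <- reference_individual(test_spec(), test_drug())
  }
  .fixtures$ref
}

# A small accepted population shared across tests (seeded, deterministic).
test_pop <- function() {
  if (is.null(.fixtures$pop)) {
    .fixtures$pop <- generate_population(50, test_spec(), test_drug(),
                                         seed = 424242)
  }
  .fixtures$pop
}

# The trial's nominal sampling schedule, reused as a cheap simulation grid.
trial_times <- function() trial_design()$sampling_times

# Names of all mass columns that must sum to body weight.
mass_columns <- function() {
  c("blood_kg", "lymph_kg", paste0("mass_", lymphpbpk:::ORGANS))
}
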