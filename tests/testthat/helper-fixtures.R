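## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

## A small simulated dataset: 40 regions, strong signal.
tiny_sim <- function() {
  cached("tiny_sim", function() {
    simulate_dataset(sim_config(n_regions = 40, concordance_target = 0.8,
                                seed = 11))
  })
}

tiny_dataset <- function() {
  cached("tiny_dataset", function() {
    ds <- split_by_chromosome(tiny_sim()$dataset)
    ds <- zscore_normalize(ds)
    augment_with_revcomp(ds)
  })
}

## A model trained for 2 epochs on the tiny simulation: enough to give the
## network non-trivial, structured weights for attribution tests.
tiny_model <- function() {
  cached("tiny_model", function() {
    mpra_cnn(tiny_dataset(),
             mpra_model_spec(filters_per_layer = 24),
             mpra_train_control(epochs = 2, learning_rate = 3e-3, seed = 3))
  })
}

## A constant-output model (all-zero linear weights).
constant_model <- function(L = 145L, n_tasks = 4L) {
  mpracnn:::linear_mpra_model(matrix(0, n_tasks, 4L * L), numeric(n_tasks), L)
}
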