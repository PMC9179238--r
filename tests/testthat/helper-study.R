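# Shared fixtures, built once per test run and cached.
# tiny_*: fast objects for unit tests.
# default_study_results(): the full default study used by the acceptance
# tests (expensive; built lazily on first use).

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tiny_config <- function() {
  cached("tiny_config",
         study_config(n_animals = 2, n_events = 8000, max_visits = 10))
}

tiny_study <- function() {
  cached("tiny_study", simulate_study(tiny_config(), seed = 42))
}

tiny_results <- function() {
  cached("tiny_results", run_study_hrdcc(tiny_study(), "reference"))
}

# one mid-size single sample with truth labels for gating checks
tiny_sample <- function() {
  cached("tiny_sample", {
    st <- tiny_study()
    asinh_transform(events_for_sample(st, st$samples$sample_id[1],
                                      n_events = 20000))
  })
}

default_study <- function() {
  cached("default_study", simulate_study(study_config(), seed = 1))
}

default_study_results <- function() {
  cached("default_results", run_study_hrdcc(default_study(), "both"))
}

default_reference_results <- function() {
  dplyr::filter(default_study_results(), mode == "reference")
}

# small standalone series generator for longitudinal/episode tests
sim_series <- function(n = 55, f = function(d) 20 + 0.02 * d, sd = 1,
                       seed = 1) {
  set.seed(seed)
  d <- sort(sample(1:300, n))
  tibble::tibble(dim = d, value = f(d) + rnorm(n, 0, sd))
}
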