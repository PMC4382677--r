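# Small network parameters for fast structural tests of the simulator.
# The ring couplings scale with unit count only through the 1/N
# normalization, so a 24-unit ring preserves the dynamical regime.
small_params <- function(...) {
  network_params(n_sensory = 24L, n_assoc = 24L, ...)
}

# preferred category of association ring units (boundary at 0)
pref_category <- function(n = 128, boundary = 0) {
  pd <- ring_directions(n)
  assign_category(ifelse(pd %% 180 == 0, pd + 1e-6, pd), boundary)
}

# Shared heavy simulation products, built once per test run and reused
# across test files (training at full scale dominates suite time).
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# 20,000-trial feedback training with the landmark snapshots; first 6,000
# trials double as the associative-learning phase check.
feedback_run_20k <- function() {
  cached("fb20k", train("feedback", 20000, network_params(), task_spec(),
                        seed = 101L,
                        snapshots = c(0L, 500L, 6000L, 12000L)))
}

no_feedback_run_20k <- function() {
  cached("nfb20k", train("no_feedback", 20000, network_params(), task_spec(),
                         seed = 101L, snapshots = c(0L, 500L, 6000L)))
}

fixed_tuning_run_20k <- function() {
  cached("fix20k", train("fixed_tuning", 20000, network_params(), task_spec(),
                         seed = 101L))
}

eval_of <- function(run, snap, n_trials = 1200, seed_off = 0L) {
  key <- sprintf("ev_%s_%s_%d", run$variant, snap, n_trials)
  cached(key, {
    w <- if (snap == "final") run$weights else run$snapshots[[snap]]
    frozen_evaluation(w, n_trials, run$params, run$task,
                      seed = 7000L + seed_off)
  })
}
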