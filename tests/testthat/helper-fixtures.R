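# Shared fixtures: everything is generated in code at test time.

quick_sampler <- function(seed = NULL, chains = 2, iters = 200) {
  sampler_config(n_chains = chains, n_warmup = iters, n_samples = iters,
                 seed = seed)
}

# small simulated cohort + dataset; returns list(agents, schedule, data, cfg)
make_cohort <- function(n_subjects = 6, n_per_recipient = 25, seed = 1, ...) {
  set.seed(seed)
  cfg <- population_config(n_subjects = n_subjects, ...)
  schedule <- generate_schedule(n_per_recipient)
  agents <- sample_population(cfg)
  data <- simulate_dataset(agents, schedule, cfg)
  list(agents = agents, schedule = schedule, data = data, cfg = cfg)
}

# minimal ep_fit-shaped object for unit tests of operations that only
# consume fit components (no MCMC involved)
fake_fit <- function(model_name, pointwise_ll, trials, subject_ids,
                     subject_rhat = NULL) {
  structure(
    list(model = model_spec(model_name), pointwise_ll = pointwise_ll,
         trials = trials, subject_ids = subject_ids,
         subject_rhat = subject_rhat,
         max_rhat = if (is.null(subject_rhat)) 1 else max(subject_rhat),
         converged = TRUE),
    class = "ep_fit")
}
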