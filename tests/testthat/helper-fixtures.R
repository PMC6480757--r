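# Shared fixtures built in code.

identity_corr <- function() {
  m <- diag(4)
  dimnames(m) <- list(c("S", "L", "W", "B"), c("S", "L", "W", "B"))
  m
}

# One-task-type config with independent traits, handy for isolating a single
# generative pathway.
tiny_config <- function(n_persons = 20, seed = 1,
                        task_types = default_task_types()[1, ], ...) {
  sim_config(
    n_persons = n_persons,
    task_types = task_types,
    materials = "numbers",
    latent_corr = identity_corr(),
    seed = seed,
    ...
  )
}

# Hand-buildable trial table.
make_trials <- function(rt, acc, person = "p1", task = "t1", block = 1,
                        warmup = rep(FALSE, length(rt))) {
  tibble::tibble(
    person = person, task = task, block = block,
    trial = seq_along(rt), rt_ms = rt, accuracy = acc, is_warmup = warmup
  )
}
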