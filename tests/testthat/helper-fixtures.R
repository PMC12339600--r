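# Shared fixtures, built in code.

toy_problems <- function() {
  data.frame(x_ss = c(10, 25, 54), t_ss = c(0, 0, 0),
             x_ll = c(20, 60, 55), t_ll = c(30, 14, 117))
}

# random natural-scale parameters inside each model's support
random_params <- function(model, n = 1L) {
  switch(model,
    hyperbolic = data.frame(k = exp(runif(n, -7, 1)),
                            m = exp(runif(n, -2, 3))),
    hyperboloid = data.frame(k = exp(runif(n, -7, 1)),
                             m = exp(runif(n, -2, 3)),
                             s = runif(n, 0.2, 1.8)),
    direct_difference = data.frame(u = runif(n, 0.2, 1.6),
                                   v = runif(n, 0.2, 1.6),
                                   w = runif(n, 0.02, 0.98)))
}

# small cached dataset so several tests can share one simulation
.fixture_env <- new.env(parent = emptyenv())

small_mcq_dataset <- function() {
  if (is.null(.fixture_env$small_mcq))
    .fixture_env$small_mcq <- generate_dataset(
      n_per_model = 300, design = "mcq", seed = 7101)
  .fixture_env$small_mcq
}
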