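# Shared parameter sets: the two printed simulation benchmarks (growth-only
# and growth-with-deletion) plus the pure preferential-attachment limit.
params_growth <- function() {
  evo_params(c = 3, m = 2, r = 0, q = 0, a = 0.5, b = 1, s = 0.5, t = 1)
}
params_deletion <- function() {
  evo_params(c = 3, m = 2, r = 0.2, q = 0.1, a = 0.5, b = 1, s = 0.5, t = 1)
}
params_pure_pa <- function(c = 3) {
  evo_params(c = c, m = 0, r = 0, q = 0, a = 0, b = 1, s = 0, t = 0)
}

# Star K_{1,n}: node 0 is the hub.
star_graph <- function(n_leaves = 3) {
  params <- evo_params(c = 1)
  edges <- cbind(0L, seq_len(n_leaves))
  netevolve:::new_evo_graph(edges = edges, node_ids = 0:n_leaves,
                            params = params, next_id = n_leaves + 1,
                            init_n = n_leaves + 1, style = "complete")
}

# Distribution of a tail family on a finite grid (normalized there).
family_dist <- function(family, theta, k_min, k_max) {
  kk <- k_min:k_max
  lp <- switch(family,
    shifted_powerlaw = -theta[1] * log(kk + theta[2]),
    powerlaw_expcorr = -theta[1] * log(kk) + kk * log(theta[2]),
    exponential = kk * log(theta[1]))
  degree_distribution(kk, exp(lp - max(lp)), source = "closed_form")
}
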