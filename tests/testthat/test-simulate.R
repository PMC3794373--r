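test_that("seed graphs provide c distinct attachment targets", {
  g <- seed_graph(evo_params(c = 3), "complete")
  expect_equal(c(g$n, g$e), c(4, 6))  # K4
  g1 <- seed_graph(evo_params(c = 1), "complete")
  expect_equal(c(g1$n, g1$e), c(3, 3))  # K3
  gr <- seed_graph(evo_params(c = 4), "ring")
  expect_equal(c(gr$n, gr$e), c(5, 5))
  expect_true(all(gr$degrees == 2))
  for (g in list(g, g1, gr)) expect_true(validate_graph(g))
})

test_that("degree-biased sampling follows the mixture weights on a star", {
  g <- star_graph(3)  # hub degree 3, three leaves of degree 1
  draw_hub_freq <- function(rand, pref, n = 40000) {
    set.seed(99)
    mean(replicate(n, sample_weighted_nodes(g, rand, pref, 1)) == 0)
  }
  expect_equal(draw_hub_freq(1, 1), 4 / 10, tolerance = 0.03)
  expect_equal(draw_hub_freq(0, 1), 3 / 6, tolerance = 0.03)
  expect_equal(draw_hub_freq(1, 0), 1 / 4, tolerance = 0.03)
  # exclusion and distinctness
  set.seed(1)
  expect_setequal(sample_weighted_nodes(g, 1, 1, 3, exclude = 0L), 1:3)
  expect_error(sample_weighted_nodes(g, 1, 1, 4, exclude = 0L), "eligible")
})

test_that("pure growth bookkeeping: one node and c edges per step", {
  p <- params_pure_pa()
  g <- evolve(p, n_target = 504, seed = 5, check_each_step = TRUE)
  tau <- g$summary$steps
  expect_equal(g$n, 4 + tau)          # K4 seed plus one node per step
  expect_equal(g$e, 6 + 3 * tau)      # c = 3 edges per step, none lost
  expect_equal(g$summary$nodes_deleted, 0)
  expect_equal(g$summary$edges_deleted, 0)
})

test_that("runs are reproducible from the seed and graphs stay simple", {
  p <- params_deletion()
  g1 <- evolve(p, 2000, seed = 42, check_each_step = TRUE)
  g2 <- evolve(p, 2000, seed = 42)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$node_ids, g2$node_ids)
  g3 <- evolve(p, 2000, seed = 43)
  expect_false(identical(g1$edges, g3$edges))
  expect_true(validate_graph(g1))
  # heavy deletion stays simple too
  gh <- evolve(evo_params(c = 2, m = 3, r = 0.6, q = 0.8, a = 1, b = 1,
                          s = 1, t = 1), 800, seed = 7,
               check_each_step = TRUE)
  expect_true(validate_graph(gh))
})

test_that("empirical degree distribution is a normalized histogram with mean 2e/n", {
  g <- evolve(params_deletion(), 5000, seed = 3)
  d <- empirical_degree_distribution(g)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(d$mean, 2 * g$e / g$n, tolerance = 1e-12)
  expect_equal(d$n_samples, g$n)
  # burn-in exclusion drops early nodes but keeps the graph intact
  db <- empirical_degree_distribution(g, exclude_burn_in = TRUE)
  expect_lt(db$n_samples, d$n_samples)
  expect_equal(g$n, 5000)
})

test_that("realized mean degree converges to 2(c + m(1-q))/(1+r)", {
  sets <- list(params_pure_pa(),            # growth only, external
               params_growth(),             # + internal links
               evo_params(c = 3, r = 0.3, a = 0.5, b = 1),         # + node del
               evo_params(c = 3, m = 2, q = 0.5, a = 0.5, b = 1,
                          s = 0.5, t = 1),                         # + edge del
               params_deletion())           # all four processes
  for (p in sets) {
    kb <- vapply(1:10, function(sd)
      evolve(p, 20000, seed = sd)$summary$mean_degree, numeric(1))
    se <- stats::sd(kb) / sqrt(length(kb))
    expect_lt(abs(mean(kb) - mean_degree(p)), 3 * max(se, 1e-3))
  }
})

test_that("pure-PA simulations reproduce the exact stationary p_3", {
  p3 <- vapply(1:10, function(sd) {
    d <- empirical_degree_distribution(evolve(params_pure_pa(), 30000, sd))
    d$prob[d$k == 3]
  }, numeric(1))
  expect_equal(mean(p3), 0.4, tolerance = 0.01 / 0.4)
})

test_that("stationary distribution is independent of the seed-graph style", {
  dc <- pooled_degree_distribution(params_growth(), 30000, 1:3,
                                   init_style = "complete")
  dr <- pooled_degree_distribution(params_growth(), 30000, 1:3,
                                   init_style = "ring")
  expect_lt(compare_distributions(dc, dr)$ks_stat, 0.02)
})

test_that("simulated distributions agree with the rate-equation solution", {
  for (p in list(params_growth(), params_deletion())) {
    sim <- pooled_degree_distribution(p, 50000, 1:4)
    sol <- stationary_distribution(p, k_max = 20000)
    expect_lt(compare_distributions(sim, sol)$ks_stat, 0.02)
  }
})

test_that("graph files round-trip and edge lists are canonical", {
  g <- evolve(params_growth(), 300, seed = 1)
  tf <- tempfile(fileext = ".tsv")
  write_edge_list(g, tf)
  ed <- as.matrix(utils::read.table(tf, sep = "\t"))
  expect_equal(unname(ed), unname(g$edges))
  expect_true(all(ed[, 1] < ed[, 2]))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  expect_true(any(grepl("edgedefault=\"undirected\"", readLines(gml))))
})
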