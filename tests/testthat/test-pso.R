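# Swarm fitness, pruning scores and the discrete PSO run.

test_that("pruning score is mismatched over matched covered weight", {
  # one attribute, rule S2 with consequent A: covers x < 1
  X <- matrix(c(0.1, 0.2, 0.3, 1.0), ncol = 1)
  d <- weighted_dataset(X, c("A", "A", "B", "B"))
  r <- fuzzy_rule("1", "A", 1)
  # covered: first three instances; matched weight 2, mismatched 1
  expect_equal(g_score(r, d), 0.5)
  # perfect rule scores 0
  expect_equal(g_score(fuzzy_rule("1", "A", 1),
                       weighted_dataset(X[1:2, , drop = FALSE], c("A", "A"))), 0)
  # no correctly labeled covered weight -> Inf
  expect_equal(g_score(fuzzy_rule("1", "B", 1),
                       weighted_dataset(X[1:2, , drop = FALSE], c("A", "A"))), Inf)
  # weights matter
  d2 <- weighted_dataset(X, c("A", "A", "B", "B"), weights = c(1, 1, 4, 1))
  expect_equal(g_score(r, d2), 2)
  expect_error(g_score(fuzzy_rule("1", NA), d), "consequent")
})

test_that("particle fitness is the weighted winner-rule accuracy of acceptable rules", {
  X <- matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1)
  d <- weighted_dataset(X, c("low", "low", "high", "high"))
  good <- list(fuzzy_rule("1", "low", 1), fuzzy_rule("2", "high", 1))
  expect_equal(particle_fitness(good, d), 1)
  # no acceptable rule (cf = 0 filtered) -> fitness 0
  expect_equal(particle_fitness(list(fuzzy_rule("1", "low", 0)), d), 0)
  expect_equal(particle_fitness(list(), d), 0)
  # a rule with g above the threshold is pruned from the set
  bad <- fuzzy_rule("0", "low", 0.9)   # covers all; g = 1 mismatch per match
  expect_equal(particle_fitness(list(bad), d, g_threshold = 0.5), 0)
  # weighted: misclassifying the heavy instance costs its share of weight
  # (g_threshold relaxed so the lopsided rule is not pruned first)
  dw <- weighted_dataset(X, c("low", "low", "high", "high"),
                         weights = c(5, 1, 1, 1))
  only_high <- list(fuzzy_rule("2", "high", 1))
  expect_equal(particle_fitness(only_high, dw, g_threshold = 10), 2 / 8)
})

test_that("the stacked rule-matrix evaluation matches the reference functions", {
  set.seed(61)
  d <- rand_dataset(40, 4)
  d$weights <- runif(40, 0.1, 2)
  MEM <- build_membership_cache(d$X)
  Rmat <- matrix(sample(0:14, 6 * 4, replace = TRUE), 6, 4)
  classes <- sort(unique(d$labels))
  counts <- vapply(classes, function(cl) sum(d$labels == cl), numeric(1))
  ev <- eval_rule_matrix(Rmat, MEM, d$labels, classes, counts, d$weights, 1)
  for (j in 1:6) {
    r <- fuzzy_rule(Rmat[j, ], NA)
    expect_equal(ev$mu[, j], rule_compatibility(r, d$X))
    cc <- class_compatibility(r, d)
    if (sum(cc$beta) > 0) {
      cf <- certainty_factor(cc$beta)
      if (!cf$tied) {
        expect_equal(ev$consequent[j], cf$consequent)
        expect_equal(ev$cf[j], cf$cf)
        expect_equal(ev$g[j], g_score(fuzzy_rule(Rmat[j, ], cf$consequent), d))
      } else {
        expect_true(is.na(ev$cf[j]))
      }
    } else {
      expect_true(is.na(ev$cf[j]))
    }
  }
})

test_that("a swarm run is deterministic given the seed", {
  d <- generate_synthetic(planted_demo_spec(80), seed = 71)$data
  cfg <- swarm_config(swarm_size = 5, B = 6, max_iter = 15, seed = 72)
  a <- pso_run(d, cfg)
  b <- pso_run(d, cfg)
  expect_equal(a, b)
})

test_that("a frozen swarm stalls out after exactly stall_limit extra iterations", {
  d <- generate_synthetic(planted_demo_spec(60), seed = 81)$data
  cfg <- swarm_config(swarm_size = 4, B = 5, max_iter = 100,
                      omega = 0, c1 = 0, c2 = 0, stall_limit = 5, seed = 82)
  out <- pso_run(d, cfg)
  tr <- attr(out, "trace")
  # positions never move, so the best is set at iteration 1 and the run
  # stops after stall_limit further unchanged iterations
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$best_fitness, rep(tr$best_fitness[1], 6))
})

test_that("the global-best trace is non-decreasing and rules are valid", {
  d <- generate_synthetic(planted_demo_spec(120), seed = 91)$data
  cfg <- swarm_config(swarm_size = 8, B = 10, max_iter = 40, seed = 92)
  rules <- pso_run(d, cfg)
  tr <- attr(rules, "trace")
  expect_true(all(diff(tr$best_fitness) >= 0))
  expect_equal(attr(rules, "fitness"), tr$best_fitness[nrow(tr)])
  expect_lte(length(rules), cfg$B)
  keys <- vapply(rules, function(r) paste(encode_rule(r), r$consequent),
                 character(1))
  expect_false(any(duplicated(keys)))
  for (r in rules) {
    expect_true(r$cf > 0)
    expect_lte(g_score(r, d), cfg$g_threshold)
  }
  # the returned rules reproduce the reported fitness
  expect_equal(particle_fitness(rules, d), attr(rules, "fitness"))
})

test_that("degenerate inputs are rejected", {
  one_class <- weighted_dataset(matrix(runif(10), 5, 2), rep("A", 5))
  expect_error(pso_run(one_class, swarm_config(swarm_size = 3, B = 2)),
               "two classes")
  zero_w <- weighted_dataset(matrix(runif(4), 2, 2), c("A", "B"),
                             weights = c(0, 0))
  expect_error(pso_run(zero_w, swarm_config(swarm_size = 3, B = 2)), "weight")
  expect_error(particle_fitness(list(), zero_w), "weight")
})

test_that("single swarm runs recover planted structure on most seeds", {
  hits <- 0L
  for (s in 1:10) {
    sim <- generate_synthetic(planted_demo_spec(200, noise = 0.05),
                              seed = 7000 + s)
    set.seed(8000 + s)
    rules <- pso_run(sim$data, swarm_config())
    pred <- classify(rules, sim$data$X)
    acc <- mean(!is.na(pred) & pred == sim$data$labels)
    if (acc >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
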