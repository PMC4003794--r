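# Fuzzy partitions, compatibility, certainty factors and winner-rule
# inference.

test_that("triangular memberships follow the uniform partition geometry", {
  # don't care and missing values are vacuously true
  expect_equal(membership("0", c(0, 0.37, 1)), c(1, 1, 1))
  expect_equal(membership("4", NA_real_), 1)
  # apexes and feet
  expect_equal(membership("4", 0.5), 1)          # M3 apex
  expect_equal(membership("6", 1 / 6), 0.5)      # S4 halfway down
  expect_equal(membership("2", 0), 0)            # L2 opposite foot
  expect_equal(membership("1", 0), 1)            # S2 apex at 0
  expect_equal(membership("e", 1), 1)            # L5 apex at 1
  expect_equal(membership("b", 0.25), 1)         # MS5 apex
  expect_error(membership("z", 0.5), "invalid")
  expect_error(membership(15L, 0.5), "invalid")
})

test_that("each granularity forms a Ruspini partition on [0,1]", {
  syms <- fuzzy_symbols()
  x <- seq(0, 1, length.out = 501)
  for (K in 2:5) {
    ids <- syms$int[!is.na(syms$granularity) & syms$granularity == K]
    expect_length(ids, K)
    tot <- Reduce(`+`, lapply(ids, membership, x = x))
    expect_equal(tot, rep(1, length(x)), tolerance = 1e-14)
  }
})

test_that("the symbol alphabet is the documented bijection", {
  syms <- fuzzy_symbols()
  expect_equal(nrow(syms), 15L)
  expect_equal(syms$code, c("0", as.character(1:9), letters[1:5]))
  expect_false(any(duplicated(syms[-1, c("granularity", "index")])))
  expect_equal(syms$label[syms$code == "0"], "DC")
  expect_equal(syms$label[syms$code == "1"], "S2")
  expect_equal(syms$label[syms$code == "b"], "MS5")
})

test_that("rule compatibility is the product of per-attribute memberships", {
  all_dc <- fuzzy_rule("000000", "A")
  x <- runif(6)
  expect_equal(rule_compatibility(all_dc, x), 1)
  # the worked encoding: if x2 is S2, x3 is L3, x5 is MS5 — value 1 at apexes
  r <- decode_rule("0150b0", "0")
  expect_equal(rule_compatibility(r, c(0.9, 0, 1, 0.1, 0.25, 0.4)), 1)
  # one zero factor annihilates the product
  expect_equal(rule_compatibility(r, c(0.9, 1, 1, 0.1, 0.25, 0.4)), 0)
  # two independent factors multiply
  expect_equal(rule_compatibility(r, c(0, 0.5, 1, 0, 0.25, 0)),
               membership("1", 0.5))
  expect_error(rule_compatibility(r, runif(4)), "antecedents")
})

test_that("replacing any antecedent with don't-care never lowers compatibility", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    ant <- sample(0:14, n, replace = TRUE)
    x <- runif(n)
    base <- rule_compatibility(fuzzy_rule(ant, "A"), x)
    j <- sample(n, 1)
    ant[j] <- 0L
    expect_gte(rule_compatibility(fuzzy_rule(ant, "A"), x), base)
  }
})

test_that("class compatibility sums are normalized by class size", {
  # rule S2 on one attribute: mu = 1 - x
  d <- weighted_dataset(matrix(c(0, 0.5, 1, 0.5), ncol = 1),
                        c("A", "A", "B", "B"))
  cc <- class_compatibility(fuzzy_rule("1", NA), d)
  expect_equal(unname(cc$beta), c(0.75, 0.25))
  expect_equal(unname(cc$counts), c(2L, 2L))
  # an all-DC rule has beta 1 for every class
  cc_dc <- class_compatibility(fuzzy_rule("0", NA), d)
  expect_equal(unname(cc_dc$beta), c(1, 1))
  # zero-compatibility rule
  d2 <- weighted_dataset(matrix(c(1, 1), ncol = 1), c("A", "B"))
  cc0 <- class_compatibility(fuzzy_rule("1", NA), d2)
  expect_equal(unname(cc0$beta), c(0, 0))
})

test_that("certainty factor rewards pure rules and vanishes on symmetry", {
  expect_equal(certainty_factor(c(A = 1, B = 0)),
               list(consequent = "A", cf = 1, tied = FALSE))
  tied <- certainty_factor(c(A = 0.5, B = 0.5))
  expect_identical(tied$cf, 0)
  expect_true(tied$tied)
  got <- certainty_factor(c(A = 0.75, B = 0.25))
  expect_equal(got$consequent, "A")
  expect_equal(got$cf, 0.5)
  expect_error(certainty_factor(c(A = 0, B = 0)), "vacuous")
  # three classes: winner share against the mean of the rest
  got3 <- certainty_factor(c(A = 0.6, B = 0.3, C = 0.1))
  expect_equal(got3$cf, (0.6 - 0.2) / 1)
  # two-class CF stays in [-1, 1]
  set.seed(5)
  for (i in 1:50) {
    b <- runif(2)
    cf <- certainty_factor(c(A = b[1], B = b[2]))$cf
    expect_true(cf >= -1 && cf <= 1)
  }
})

test_that("winner-rule classification takes the strict maximum of mu * CF", {
  X <- matrix(c(0.1, 0.9), ncol = 1)
  expect_equal(classify(list(), X), c(NA_character_, NA_character_))
  r1 <- fuzzy_rule("1", "low", cf = 1)    # S2: mu = 1 - x
  r2 <- fuzzy_rule("2", "high", cf = 1)   # L2: mu = x
  expect_equal(classify(list(r1, r2), X), c("low", "high"))
  # strict max: products 0.30 vs 0.29
  a <- fuzzy_rule("0", "A", cf = 0.30)
  b <- fuzzy_rule("0", "B", cf = 0.29)
  expect_equal(classify(list(a, b), matrix(0.5)), "A")
  # equal maximal products from different classes -> unclassified
  tie <- classify(list(fuzzy_rule("0", "A", cf = 0.3),
                       fuzzy_rule("0", "B", cf = 0.3)), matrix(0.5))
  expect_true(is.na(tie))
  # a CF = 0 rule can never win and never changes predictions
  base <- classify(list(r1, r2), X)
  with_zero <- classify(list(r1, r2, fuzzy_rule("0", "junk", cf = 0)), X)
  expect_identical(base, with_zero)
  # all products zero -> unclassified
  expect_true(is.na(classify(list(fuzzy_rule("1", "A", cf = 1)), matrix(1))))
})

test_that("encode/decode round trips over random rules and strings", {
  r <- decode_rule("0150b0", "0")
  expect_equal(r$antecedents, c(0L, 1L, 5L, 0L, 11L, 0L))
  expect_equal(encode_rule(r), "0150b0")
  all_dc <- decode_rule("0000", "A")
  expect_true(all(all_dc$antecedents == 0L))
  set.seed(21)
  codes <- fuzzy_symbols()$code
  for (i in 1:25) {
    s <- paste(sample(codes, sample(2:12, 1), replace = TRUE), collapse = "")
    expect_equal(encode_rule(decode_rule(s, "A")), s)
    ant <- sample(0:14, 7, replace = TRUE)
    rr <- fuzzy_rule(ant, "B", runif(1))
    expect_equal(decode_rule(encode_rule(rr), "B", rr$cf), rr)
  }
  expect_error(decode_rule("01x", "A"), "invalid")
})

test_that("rule sets serialize to TSV and a structured JSON document", {
  rules <- list(fuzzy_rule("0150b0", "healthy", 0.5),
                fuzzy_rule("000002", "patient", 0.73125))
  tsv <- tempfile(fileext = ".tsv")
  write_rules(rules, tsv)
  back <- read_rules(tsv)
  expect_equal(back, rules)
  js <- tempfile(fileext = ".json")
  write_rules_json(rules, js, attribute_names = paste0("x", 1:6))
  doc <- jsonlite::read_json(js)
  expect_equal(doc$version, 1L)
  expect_equal(doc$n_attributes, 6L)
  expect_length(doc$rules, 2L)
  expect_equal(doc$rules[[1]]$antecedents, "0150b0")
  expect_equal(doc$rules[[2]]$cf, 0.73125)
})

test_that("weighted datasets validate their invariants", {
  X <- matrix(runif(6), 3, 2)
  d <- weighted_dataset(X, c("A", "B", "A"))
  expect_equal(d$weights, rep(1, 3))
  expect_error(weighted_dataset(X, c("A", "B")), "labels")
  expect_error(weighted_dataset(X, c("A", "B", "A"), weights = c(1, -1, 1)),
               "nonnegative")
  expect_error(weighted_dataset(X * 2, c("A", "B", "A")), "\\[0,1\\]")
})
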