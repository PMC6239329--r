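# schema/structure validation, parameter estimation, joint probability,
# and exact posterior computation

test_that("schema construction enforces its invariants", {
  expect_s3_class(toy_schema(), "bn_schema")
  base <- tibble::tibble(
    name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
    states = list(c("d1", "d2", "d3"), c("a", "b"))
  )
  two_dx <- base
  two_dx$kind <- c("diagnosis", "diagnosis")
  expect_error(bn_schema(two_dx), "exactly one diagnosis")
  one_state <- base
  one_state$states[[2]] <- "a"
  expect_error(bn_schema(one_state), "between 2 and 8")
  nine <- base
  nine$states[[2]] <- paste0("s", 1:9)
  expect_error(bn_schema(nine), "between 2 and 8")
  dup <- base
  dup$states[[2]] <- c("a", "a")
  expect_error(bn_schema(dup), "duplicate state")
  dup_name <- base
  dup_name$name <- c("dx", "dx")
  expect_error(bn_schema(dup_name), "duplicate variable")
})

test_that("validate_structure reports cycles, parent limits, malformed edges", {
  schema <- bn_schema(tibble::tibble(
    name = c("dx", paste0("v", 1:4)),
    kind = c("diagnosis", rep("imaging_finding", 4)),
    states = replicate(5, c("a", "b"), simplify = FALSE)
  ))
  expect_identical(validate_structure(bn_structure(schema)), character(0))

  cyc <- bn_structure(schema, tibble::tibble(parent = c("v1", "v2"),
                                             child = c("v2", "v1")))
  expect_match(validate_structure(cyc), "cycle", all = FALSE)

  over <- bn_structure(schema, tibble::tibble(
    parent = c("v1", "v2", "v3"), child = rep("v4", 3)
  ))
  expect_match(validate_structure(over), "more than two parents", all = FALSE)

  loop <- new_bn_structure(schema, tibble::tibble(parent = "v1", child = "v1"))
  expect_match(validate_structure(loop), "self-loop", all = FALSE)

  dup <- new_bn_structure(schema, tibble::tibble(parent = c("v1", "v1"),
                                                 child = c("v2", "v2")))
  expect_match(validate_structure(dup), "duplicate edge", all = FALSE)

  expect_error(bn_structure(schema, tibble::tibble(parent = "zz", child = "v1")),
               "not in schema")
})

test_that("estimate_parameters applies smoothed available-case counting", {
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
    states = list(c("d1", "d2", "d3"), c("a", "b"))
  ))
  s0 <- bn_structure(schema)
  cases <- tibble::tibble(dx = c("d1", "d1", "d1", "d2"),
                          f = c("a", "a", "a", "b"))
  # parentless binary node, observations {a,a,a,b}, pseudocount 1
  cpt <- estimate_parameters(cases, s0, pseudocount = 1)
  expect_equal(as.numeric(cpt$f), c(4 / 6, 2 / 6))
  # zero observations with pseudocount 1: uniform by symmetry
  empty <- tibble::tibble(dx = rep(NA_character_, 3), f = rep(NA_character_, 3))
  cpt0 <- estimate_parameters(empty, s0, pseudocount = 1)
  expect_equal(as.numeric(cpt0$f), c(0.5, 0.5))
  expect_equal(as.numeric(cpt0$dx), rep(1 / 3, 3))
  # maximum likelihood with one parent and pseudocount 0
  s1 <- bn_structure(schema, tibble::tibble(parent = "dx", child = "f"))
  ml_cases <- tibble::tibble(dx = rep("d1", 4), f = c("a", "a", "a", "b"))
  expect_error(estimate_parameters(ml_cases, s1, pseudocount = 0),
               "zero usable cases")  # rows for d2/d3 are empty
  ml_cases2 <- tibble::tibble(dx = c(rep("d1", 4), "d2", "d3"),
                              f = c("a", "a", "a", "b", "a", "b"))
  cpt_ml <- estimate_parameters(ml_cases2, s1, pseudocount = 0)
  expect_equal(unname(cpt_ml$f["a", "d1"]), 0.75)
  # zero usable cases with pseudocount 0 is an error
  expect_error(estimate_parameters(empty, s0, pseudocount = 0),
               "zero usable cases")
  # pseudocount 0 on complete data reproduces empirical frequencies
  expect_equal(as.numeric(estimate_parameters(cases, s0, 0)$dx),
               c(3 / 4, 1 / 4, 0))
  # available-case counting skips rows where the family is unobserved
  miss <- tibble::tibble(dx = c("d1", "d1", NA, "d2"),
                         f = c("a", NA, "b", "b"))
  cpt_m <- estimate_parameters(miss, s0, pseudocount = 0)
  expect_equal(as.numeric(cpt_m$dx), c(2 / 3, 1 / 3, 0))
  expect_equal(as.numeric(cpt_m$f), c(1 / 3, 2 / 3))
  # illegal state is rejected with a pointer to the cell
  bad <- tibble::tibble(dx = "d1", f = "zz")
  expect_error(estimate_parameters(bad, s0), "illegal state 'zz'")
})

test_that("joint_probability is the product of CPT entries and normalises", {
  m <- blocked_model()
  # single factors multiply: p(d1) * p(x_a=yes) * p(x_b=yes | yes, d1)
  expect_equal(
    joint_probability(m, c(dx = "d1", x_a = "yes", x_b = "yes")),
    0.5 * 0.75 * 0.25
  )
  expect_error(joint_probability(m, c(dx = "d1")), "missing variable")
  expect_error(joint_probability(m, c(dx = "d1", x_a = "zz", x_b = "yes")),
               "illegal state")
  # sums to one over all full assignments, for several random models
  for (seed in 1:5) {
    rm <- random_model(seed, n_nodes = 4)
    st <- stats::setNames(rm$structure$schema$states,
                          rm$structure$schema$name)
    grid <- expand.grid(st, stringsAsFactors = FALSE)
    total <- sum(vapply(seq_len(nrow(grid)), function(i) {
      joint_probability(rm, as.list(grid[i, , drop = FALSE]))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("posterior matches the brute-force enumeration oracle", {
  for (seed in 1:40) {
    m <- random_model(seed)
    ev <- random_evidence(m)
    p <- posterior(m, ev)
    b <- brute_posterior(m, ev)
    expect_equal(p, b, tolerance = 1e-9)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("posterior handles empty, blocked, and inconsistent evidence", {
  m <- blocked_model()
  marg <- posterior(m, NULL)
  expect_equal(marg, c(d1 = 0.5, d2 = 0.25, d3 = 0.25))
  # collider blocks propagation: evidence on x_a leaves dx unchanged
  expect_identical(posterior(m, c(x_a = "yes")), marg)
  expect_identical(posterior(m, c(x_a = "no")), marg)
  # diagnosis cannot be evidence; unknown variables rejected
  expect_error(posterior(m, c(dx = "d1")), "diagnosis")
  expect_error(posterior(m, c(zz = "a")), "unknown variable")
  # evidence of probability zero is inconsistent
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
    states = list(c("d1", "d2"), c("a", "b"))
  ))
  s1 <- bn_structure(schema, tibble::tibble(parent = "dx", child = "f"))
  mz <- bn_model(s1, list(dx = c(1, 0),
                          f = array(c(1, 0, 0.5, 0.5), dim = c(2, 2))))
  expect_error(posterior(mz, c(f = "b")), "inconsistent")
})

test_that("evidence disconnected from the query leaves its marginal unchanged", {
  # two-component graph: dx -> v1 in one component, v2 isolated
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "v1", "v2"),
    kind = c("diagnosis", "imaging_finding", "clinical"),
    states = list(c("d1", "d2"), c("a", "b"), c("a", "b"))
  ))
  struct <- bn_structure(schema, tibble::tibble(parent = "dx", child = "v1"))
  m <- bn_model(struct, list(
    dx = c(0.625, 0.375),
    v1 = array(c(0.25, 0.75, 0.5, 0.5), dim = c(2, 2)),
    v2 = c(0.125, 0.875)
  ))
  expect_identical(posterior(m, c(v2 = "a")), posterior(m, NULL))
})

test_that("infer_diagnosis takes the argmax with schema-order tie-break", {
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
    states = list(c("d1", "d2", "d3"), c("a", "b"))
  ))
  s0 <- bn_structure(schema)
  m1 <- bn_model(s0, list(dx = c(0.6, 0.3, 0.1), f = c(0.5, 0.5)))
  expect_identical(infer_diagnosis(m1, NULL)$d_f, "d1")
  # exact tie: first state in schema order wins
  m2 <- bn_model(s0, list(dx = c(0.5, 0.5, 0), f = c(0.5, 0.5)))
  expect_identical(infer_diagnosis(m2, NULL)$d_f, "d1")
  m3 <- bn_model(s0, list(dx = c(0.1, 0.45, 0.45), f = c(0.5, 0.5)))
  expect_identical(infer_diagnosis(m3, NULL)$d_f, "d2")
})

test_that("fitted models reject structures that violate the constraints", {
  schema <- toy_schema()
  cyc <- bn_structure(schema, tibble::tibble(
    parent = c("size", "cavitation"), child = c("cavitation", "size")
  ))
  cases <- tibble::tibble(dx = "cancer", size = "small",
                          cavitation = "present")
  expect_error(fit_model(cases, cyc), "cycle")
})
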