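# move enumeration, annealed acceptance, and the search loop

three_node_schema <- function() {
  bn_schema(tibble::tibble(
    name = c("a", "b", "c"),
    kind = c("diagnosis", "imaging_finding", "imaging_finding"),
    states = replicate(3, c("s1", "s2"), simplify = FALSE)
  ))
}

test_that("initial structures encode prior knowledge as diagnosis links", {
  schema <- toy_schema()
  s0 <- build_initial_structure(schema)
  expect_identical(nrow(s0$edges), 0L)
  s1 <- build_initial_structure(schema, c("size", "cavitation"))
  expect_identical(nrow(s1$edges), 2L)
  expect_true(all(s1$edges$parent == "dx"))
  expect_setequal(s1$edges$child, c("size", "cavitation"))
  s2 <- build_initial_structure(schema, "size",
                                direction = "variable_to_diagnosis")
  expect_identical(s2$edges$parent, "size")
  expect_identical(s2$edges$child, "dx")
  expect_error(build_initial_structure(schema, "nope"), "unknown variable")
  expect_error(build_initial_structure(schema, "dx"), "diagnosis variable")
})

test_that("enumerate_moves lists exactly the legal successors", {
  schema <- three_node_schema()
  # empty graph on 3 nodes: no deletes or reverses, all 6 joins
  mv0 <- enumerate_moves(bn_structure(schema))
  expect_identical(sort(unique(mv0$type)), "join")
  expect_identical(nrow(mv0), 6L)
  # chain a -> b -> c: 2 deletes, 2 reverses, 1 join (c -> a would cycle)
  chain <- bn_structure(schema, tibble::tibble(parent = c("a", "b"),
                                               child = c("b", "c")))
  mv <- enumerate_moves(chain)
  expect_identical(nrow(mv), 5L)
  expect_identical(sum(mv$type == "delete"), 2L)
  expect_identical(sum(mv$type == "reverse"), 2L)
  joins <- mv[mv$type == "join", ]
  expect_identical(nrow(joins), 1L)
  expect_identical(joins$parent, "a")
  expect_identical(joins$child, "c")
  # every enumerated move yields a valid structure
  for (i in seq_len(nrow(mv))) {
    nxt <- reasonbn:::apply_move(chain, mv$type[i], mv$parent[i], mv$child[i])
    expect_identical(validate_structure(nxt), character(0))
  }
})

test_that("no join adds a third parent", {
  schema <- bn_schema(tibble::tibble(
    name = c("d", "p1", "p2", "x"),
    kind = c("diagnosis", rep("imaging_finding", 3)),
    states = replicate(4, c("s1", "s2"), simplify = FALSE)
  ))
  two_parents <- bn_structure(schema, tibble::tibble(
    parent = c("p1", "p2"), child = c("x", "x")
  ))
  mv <- enumerate_moves(two_parents)
  expect_false(any(mv$type == "join" & mv$child == "x"))
  # reversing p1 -> x would give p1 a first parent: legal; but a reverse
  # that would give a node a third parent must be absent
  full <- bn_structure(schema, tibble::tibble(
    parent = c("p1", "p2", "d"), child = c("x", "x", "p1")
  ))
  mv2 <- enumerate_moves(full)
  for (i in which(mv2$type == "reverse")) {
    nxt <- reasonbn:::apply_move(full, "reverse", mv2$parent[i], mv2$child[i])
    expect_identical(validate_structure(nxt), character(0))
  }
})

test_that("proposals are uniform over the legal moves and reproducible", {
  schema <- three_node_schema()
  chain <- bn_structure(schema, tibble::tibble(parent = c("a", "b"),
                                               child = c("b", "c")))
  set.seed(99)
  p1 <- propose_update(chain)
  set.seed(99)
  p2 <- propose_update(chain)
  expect_identical(p1$move, p2$move)
  expect_identical(p1$structure$edges, p2$structure$edges)
  # frequencies over the 5 legal successors: uniform within 3 sigma
  set.seed(123)
  n <- 5000
  keys <- character(n)
  for (i in seq_len(n)) {
    keys[i] <- reasonbn:::edge_key(propose_update(chain)$structure$edges)
  }
  tab <- table(keys)
  expect_identical(length(tab), 5L)
  p <- 1 / 5
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(tab - n * p) < 3 * sigma))
  # no legal move exists only for degenerate graphs
  one_node <- bn_schema(tibble::tibble(
    name = "d", kind = "diagnosis", states = list(c("s1", "s2"))
  ))
  expect_error(propose_update(bn_structure(one_node)), "no legal move")
})

test_that("the acceptance rule follows the annealing schedule", {
  # better proposals are always accepted
  expect_identical(acceptance_probability(0.61, 0.6, m = 1, beta = 0.999), 1)
  expect_identical(acceptance_probability(0.01, 0, m = 500, beta = 0.5), 1)
  # equal scores at the first iteration: exp(-1), any beta
  expect_equal(acceptance_probability(0.5, 0.5, m = 1, beta = 0.999),
               exp(-1))
  expect_equal(acceptance_probability(0.3, 0.3, m = 1, beta = 0.5), exp(-1))
  # direct substitution of the damped exponent
  expect_equal(acceptance_probability(0.5, 0.6, m = 1, beta = 0.999),
               exp(-1.2))
  expect_equal(acceptance_probability(0.5, 0.6, m = 10, beta = 0.9),
               exp(-1.2 * 0.9^-9))
  # strictly decreasing in the iteration count for a worse proposal
  ms <- c(1, 2, 5, 10, 100, 1000)
  ps <- vapply(ms, function(m) {
    acceptance_probability(0.5, 0.6, m = m, beta = 0.999)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # non-increasing in the score ratio
  expect_lt(acceptance_probability(0.4, 0.6, 5, 0.999),
            acceptance_probability(0.5, 0.6, 5, 0.999))
  # a zero-score proposal is never accepted over a nonzero incumbent
  expect_identical(acceptance_probability(0, 0.5, 1, 0.999), 0)
})

test_that("run_search honours the iteration limit and is deterministic", {
  ds <- recovery_dataset(n = 150, seed = 5)
  schema <- ds$model$structure$schema
  prior_links <- ds$model$structure$edges$child
  init <- build_initial_structure(schema, prior_links)
  cfg1 <- search_config(max_iterations = 1, seed = 4)
  r1 <- run_search(ds$cases, init, cfg1)
  expect_identical(r1$iterations, 1L)
  expect_identical(nrow(r1$trace), 1L)

  cfg <- search_config(max_iterations = 40, seed = 4)
  a <- run_search(ds$cases, init, cfg)
  b <- run_search(ds$cases, init, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$structure$edges, b$structure$edges)
  expect_identical(glance(a), glance(b))
  # improving proposals (probability 1) are always accepted
  sure <- a$trace$accept_prob == 1
  expect_true(all(a$trace$accepted[sure]))
  expect_true(all(a$trace$v_temp[sure] > a$trace$v_current[sure]))
  # the scored-candidate count equals the iterations used
  expect_identical(nrow(a$trace), a$iterations)
})

test_that("every structure visited by the search is legal", {
  ds <- recovery_dataset(n = 150, seed = 5)
  schema <- ds$model$structure$schema
  init <- build_initial_structure(schema, ds$model$structure$edges$child)
  res <- run_search(ds$cases, init, search_config(max_iterations = 60,
                                                  seed = 8))
  for (key in unique(res$trace$structure_key)) {
    st <- bn_structure(schema, reasonbn:::edges_from_key(key))
    expect_identical(validate_structure(st), character(0))
  }
  expect_identical(validate_structure(res$structure), character(0))
})

test_that("stagnation stops the search before the iteration limit", {
  ds <- recovery_dataset(n = 150, seed = 5)
  schema <- ds$model$structure$schema
  init <- build_initial_structure(schema, ds$model$structure$edges$child)
  cfg <- search_config(max_iterations = 5000, stagnation_limit = 25,
                       seed = 15)
  res <- run_search(ds$cases, init, cfg)
  expect_lt(res$iterations, 5000L)
  tail_acc <- utils::tail(res$trace$accepted, 25)
  expect_identical(sum(tail_acc), 0L)
})

test_that("search configuration validates its parameters", {
  expect_error(search_config(beta = 1), "beta")
  expect_error(search_config(beta = 0), "beta")
  expect_error(search_config(folds = 1), "folds")
  cfg <- search_config()
  expect_identical(cfg$beta, 0.999)
  expect_identical(cfg$max_iterations, 10000L)
  expect_identical(cfg$stagnation_limit, 2500L)
  expect_identical(cfg$accuracy_floor, 0.70)
  expect_identical(cfg$folds, 5L)
})
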