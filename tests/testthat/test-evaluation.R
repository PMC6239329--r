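# F-measure, accuracy, combined metric, and cross-validated scoring

test_that("reason F-measure pools counts across cases (micro-averaging)", {
  # perfect agreement and total disagreement
  expect_equal(
    reason_f_measure(list(c("a=1", "b=2")), list(c("a=1", "b=2"))),
    tibble::tibble(precision = 1, recall = 1, f_measure = 1)
  )
  expect_equal(
    reason_f_measure(list(c("a=1")), list(c("b=2")))$f_measure, 0
  )
  # hand-computed single case: R_g = {a,b,c}, R_d = {b,c,d,e}
  fm <- reason_f_measure(list(c("a=1", "b=1", "c=1")),
                         list(c("b=1", "c=1", "d=1", "e=1")))
  expect_equal(fm$precision, 0.5)
  expect_equal(fm$recall, 2 / 3)
  expect_equal(fm$f_measure, 4 / 7)
  # micro-averaging differs from the mean of per-case F values
  ref <- list(c("a=1"), c("b=1", "c=1", "d=1", "e=1"))
  der <- list(c("a=1"), c("b=1"))
  pooled <- reason_f_measure(ref, der)
  expect_equal(pooled$precision, 2 / 2)
  expect_equal(pooled$recall, 2 / 5)
  expect_equal(pooled$f_measure, 2 * 1 * 0.4 / 1.4)
  per_case_mean <- mean(c(1, 2 * 1 * 0.25 / 1.25))
  expect_false(isTRUE(all.equal(pooled$f_measure, per_case_mean)))
  # empty derived sets: 0/0 ratios are defined as 0
  expect_equal(reason_f_measure(list(c("a=1")), list(character(0)))$f_measure,
               0)
})

test_that("inference accuracy is the exact-match fraction", {
  expect_equal(inference_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(inference_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(inference_accuracy(rep(c("a", "b"), c(72, 28)),
                                  rep("a", 100)), 0.72)
  expect_error(inference_accuracy("a", c("a", "b")), "length")
  expect_error(inference_accuracy(character(0), character(0)), "zero cases")
})

test_that("the combined metric is the mean of its components", {
  expect_equal(combined_metric(0, 0), 0)
  expect_equal(combined_metric(1, 1), 1)
  expect_equal(combined_metric(0.4, 0.6), 0.5)
  # symmetric and monotone
  expect_equal(combined_metric(0.3, 0.8), combined_metric(0.8, 0.3))
  expect_lt(combined_metric(0.3, 0.5), combined_metric(0.3, 0.6))
  expect_lt(combined_metric(0.2, 0.5), combined_metric(0.3, 0.5))
  expect_error(combined_metric(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(combined_metric(0.5, 1.2), "\\[0, 1\\]")
})

test_that("cross-validated scoring is deterministic and stratified", {
  ds <- recovery_dataset(n = 150, seed = 5)
  st <- ds$model$structure
  a <- cross_validated_score(ds$cases, st, folds = 5, seed = 42)
  b <- cross_validated_score(ds$cases, st, folds = 5, seed = 42)
  expect_identical(glance(a), glance(b))
  expect_identical(a$per_fold, b$per_fold)
  # a different fold seed may change the folds but stays a valid result
  c_ <- cross_validated_score(ds$cases, st, folds = 5, seed = 43)
  expect_true(c_$v >= 0 && c_$v <= 1)
  expect_equal(a$v, combined_metric(a$v_r, a$v_i))
  expect_identical(sum(a$per_fold$n_test), nrow(ds$cases))
})

test_that("low cross-validated accuracy short-circuits V to V_i", {
  # effect strength 0: findings carry no signal, accuracy ~ class share
  spec <- generator_spec(n_findings = 4, n_clinical = 0, states_min = 2,
                         states_max = 2, n_informative = 4,
                         edge_density = 0, effect_strength = 0,
                         missing_rate = 0, seed = 3)
  ds <- simulate_dataset(spec, 120)
  ev <- cross_validated_score(ds$cases, ds$model$structure, folds = 5,
                              seed = 1, accuracy_floor = 0.70)
  expect_true(ev$short_circuited)
  expect_identical(ev$v_r, 0)
  expect_identical(ev$v, ev$v_i)
  expect_lt(ev$v_i, 0.70)
  # with the floor lowered below the attained accuracy, reasons are scored
  ev2 <- cross_validated_score(ds$cases, ds$model$structure, folds = 5,
                               seed = 1, accuracy_floor = 0)
  expect_false(ev2$short_circuited)
  expect_equal(ev2$v, (ev2$v_r + ev2$v_i) / 2)
})

test_that("a separable dataset reaches perfect cross-validated accuracy", {
  # diagnosis is a deterministic function of one finding
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
    states = list(c("d1", "d2", "d3"), c("a", "b", "c"))
  ))
  struct <- bn_structure(schema, tibble::tibble(parent = "dx", child = "f"))
  cases <- tibble::tibble(
    dx = rep(c("d1", "d2", "d3"), each = 20),
    f = rep(c("a", "b", "c"), each = 20)
  )
  cases$reference_reasons <- lapply(paste0("f=", cases$f), identity)
  ev <- cross_validated_score(cases, struct, folds = 5, seed = 2)
  expect_equal(ev$v_i, 1)
  expect_equal(ev$v_r, 1)  # the single finding is always the reason
  expect_equal(ev$v, 1)
})

test_that("folds whose training split lacks a class are rejected", {
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
    states = list(c("d1", "d2", "d3"), c("a", "b"))
  ))
  struct <- bn_structure(schema)
  cases <- tibble::tibble(
    dx = c(rep("d1", 5), rep("d2", 5), "d3"),
    f = rep("a", 11),
    reference_reasons = replicate(11, "f=a", simplify = FALSE)
  )
  expect_error(cross_validated_score(cases, struct, folds = 2, seed = 1),
               "lacks diagnosis class")
})

test_that("compiled-joint scoring equals per-case variable elimination", {
  spec <- generator_spec(n_findings = 5, n_clinical = 3, states_min = 2,
                         states_max = 4, n_informative = 4,
                         edge_density = 0.15, effect_strength = 0.75,
                         missing_rate = 0.15, seed = 21)
  ds <- simulate_dataset(spec, 120)
  st <- ds$model$structure
  fast <- cross_validated_score(ds$cases, st, folds = 5, seed = 3)
  slow <- cross_validated_score(ds$cases, st, folds = 5, seed = 3,
                                joint_limit = 0)
  expect_equal(fast$v, slow$v, tolerance = 1e-12)
  expect_equal(fast$v_r, slow$v_r, tolerance = 1e-12)
  expect_identical(fast$v_i, slow$v_i)
  expect_equal(fast$precision, slow$precision, tolerance = 1e-12)
  expect_equal(fast$recall, slow$recall, tolerance = 1e-12)
  # the per-case scorer itself agrees path-by-path
  m <- fit_model(ds$cases, st)
  a <- reasonbn:::score_cases_joint(m, ds$cases[1:40, ], derive = TRUE)
  b <- reasonbn:::score_cases_ve(m, ds$cases[1:40, ], derive = TRUE)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$reasons, lapply(b$reasons, as.character))
})

test_that("evaluate_model scores a fixed split and applies the floor", {
  ds <- recovery_dataset(n = 200, seed = 13)
  train <- ds$cases[1:120, ]
  test <- ds$cases[121:200, ]
  tr <- evaluate_model(train, ds$model$structure)
  expect_false(tr$short_circuited)
  te <- evaluate_model(test, ds$model$structure, train_cases = train)
  expect_true(te$v_i > 0.7)
  expect_equal(te$v, (te$v_r + te$v_i) / 2)
  # floor above the attained accuracy forces the short-circuit
  hi <- evaluate_model(test, ds$model$structure, train_cases = train,
                       accuracy_floor = 0.999)
  if (hi$v_i < 0.999) {
    expect_true(hi$short_circuited)
    expect_identical(hi$v, hi$v_i)
  }
})
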