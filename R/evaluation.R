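# Scoring a structure on a dataset: explanation adequacy V_r
# (micro-averaged F-measure of derived vs reference reasons), inference
# accuracy V_i, and the combined metric V = (V_r + V_i) / 2, with 5-fold
# cross-validation and a low-accuracy short-circuit that skips the
# expensive reason derivation.

#' Micro-averaged F-measure of derived reasons
#'
#' Precision and recall are pooled over cases before forming the
#' harmonic mean: precision \eqn{= \sum_i |R_g^i \cap R_d^i| / \sum_i
#' |R_d^i|} and recall \eqn{= \sum_i |R_g^i \cap R_d^i| / \sum_i |R_g^i|}.
#' Any 0/0 ratio is defined as 0. Elements match on exact
#' "variable=state" identity.
#'
#' @param reference List of character vectors: each case's reference
#'   reason elements \eqn{R_g} (expert-chosen in clinical use).
#' @param derived List of character vectors: each case's derived reason
#'   elements \eqn{R_d} (possibly empty).
#' @return A one-row tibble with `precision`, `recall`, `f_measure`.
#' @examples
#' reason_f_measure(list(c("a=1", "b=1", "c=1")),
#'                  list(c("b=1", "c=1", "d=1", "e=1")))
#' @export
reason_f_measure <- function(reference, derived) {
  stopifnot(is.list(reference), is.list(derived),
            length(reference) == length(derived))
  inter <- sum(mapply(function(g, d) length(intersect(unique(g), unique(d))),
                      reference, derived))
  n_d <- sum(vapply(derived, function(d) length(unique(d)), integer(1)))
  n_g <- sum(vapply(reference, function(g) length(unique(g)), integer(1)))
  precision <- if (n_d == 0) 0 else inter / n_d
  recall <- if (n_g == 0) 0 else inter / n_g
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(precision = precision, recall = recall, f_measure = f)
}

#' Inference accuracy
#'
#' Fraction of cases whose inferred diagnosis equals the recorded
#' clinical diagnosis (m correct out of n cases).
#'
#' @param predictions Character vector of inferred diagnosis states.
#' @param truths Character vector of true diagnosis labels.
#' @return A number in \[0, 1\].
#' @export
inference_accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths differ in length", call. = FALSE)
  }
  if (length(predictions) == 0L) {
    stop("cannot compute accuracy on zero cases", call. = FALSE)
  }
  mean(predictions == truths)
}

#' Combined model metric
#'
#' The arithmetic mean of explanation adequacy \eqn{V_r} and inference
#' accuracy \eqn{V_i}: \eqn{V = (V_r + V_i) / 2}. Symmetric and monotone
#' in both arguments.
#'
#' @param v_r Explanation adequacy in \[0, 1\] (micro-averaged F-measure).
#' @param v_i Inference accuracy in \[0, 1\] (as a fraction, not percent).
#' @return \eqn{V} in \[0, 1\]. Vectorised.
#' @examples
#' combined_metric(0.399, 0.759)
#' @export
combined_metric <- function(v_r, v_i) {
  if (any(v_r < 0 | v_r > 1) || any(v_i < 0 | v_i > 1)) {
    stop("v_r and v_i must lie in [0, 1]", call. = FALSE)
  }
  (v_r + v_i) / 2
}

# ---- internal: fast exact scorer over a fitted model ------------------

# Posterior function factory: compiled full-joint tables when the state
# space is small, memoised variable elimination otherwise. Both are exact.
make_post_fun <- function(model, joint_limit = 2^20) {
  dx <- model$diagnosis
  if (joint_size(model) <= joint_limit) {
    ja <- compile_joint(model)
    vars <- names(dimnames(ja))
    cache <- new.env(parent = emptyenv())
    function(sub) {
      key <- if (length(sub)) {
        paste(names(sub), sub, sep = "=", collapse = ";")
      } else {
        "."
      }
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      res <- posterior_from_joint(ja, sub, dx)
      cache[[key]] <- res
      res
    }
  } else {
    cache <- new.env(parent = emptyenv())
    function(sub) {
      key <- if (length(sub)) {
        paste(names(sub), sub, sep = "=", collapse = ";")
      } else {
        "."
      }
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      res <- posterior(model, sub, dx)
      cache[[key]] <- res
      res
    }
  }
}

# evidence of one case row: all observed non-diagnosis variables
case_evidence <- function(row, var_names, dx) {
  v <- setdiff(var_names, dx)
  ev <- unlist(row[v])
  ev <- ev[!is.na(ev)]
  ev
}

# predict d_f (and optionally derive reasons) for every row of `cases`;
# dispatches to the vectorised compiled-joint scorer for small state
# spaces and to per-case memoised variable elimination otherwise (both
# exact; equality is asserted in the test suite)
score_cases <- function(model, cases, derive = FALSE, max_reasons = 3,
                        threshold_frac = 0.05, joint_limit = 2^20) {
  if (joint_size(model) <= joint_limit) {
    score_cases_joint(model, cases, derive, max_reasons, threshold_frac)
  } else {
    score_cases_ve(model, cases, derive, max_reasons, threshold_frac)
  }
}

score_cases_ve <- function(model, cases, derive = FALSE, max_reasons = 3,
                           threshold_frac = 0.05) {
  schema <- model$structure$schema
  check_case_columns(cases, schema)
  dx <- model$diagnosis
  post_fun <- make_post_fun(model, joint_limit = 0)
  prior <- post_fun(stats::setNames(character(0), character(0)))
  n <- nrow(cases)
  preds <- character(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- case_evidence(cases[i, , drop = FALSE], schema$name, dx)
    post <- post_fun(ev)
    preds[i] <- names(post)[which.max(post)]
    if (derive && length(ev)) {
      rs <- derive_reasons_core(ev, post, prior, post_fun,
                                max_reasons, threshold_frac)
      reasons[[i]] <- rs$derived_elements
    } else {
      reasons[[i]] <- character(0)
    }
  }
  list(predictions = preds, reasons = reasons)
}

# marginalise an array onto the dimensions `keep_idx` (order preserved)
array_marginal <- function(a, keep_idx) {
  nd <- length(dim(a))
  drop_idx <- setdiff(seq_len(nd), keep_idx)
  b <- aperm(a, c(keep_idx, drop_idx))
  db <- dim(b)
  k <- length(keep_idx)
  dim(b) <- c(prod(db[seq_len(k)]), prod(db[-seq_len(k)], 1))
  array(rowSums(b), db[seq_len(k)])
}

# Vectorised exact scorer over the compiled full joint. All candidate
# posteriors come from marginal tables of the joint; predictions are
# grouped by missingness pattern so each pattern's marginal is built once.
score_cases_joint <- function(model, cases, derive = FALSE, max_reasons = 3,
                              threshold_frac = 0.05) {
  schema <- model$structure$schema
  check_case_columns(cases, schema)
  dx <- model$diagnosis
  st <- schema_states(schema)
  vars <- setdiff(schema$name, dx)
  nv <- length(vars)
  n <- nrow(cases)
  sizes <- lengths(st[vars])
  k_dx <- length(st[[dx]])

  # integer state matrix (NA = missing)
  X <- matrix(NA_integer_, nrow = n, ncol = nv,
              dimnames = list(NULL, vars))
  for (j in seq_len(nv)) {
    X[, j] <- match(cases[[vars[j]]], st[[vars[j]]])
  }

  ja <- compile_joint(model)
  ja <- aperm(ja, match(c(dx, vars), names(dimnames(ja))))
  prior <- as.numeric(array_marginal(ja, 1L))

  # ---- predictions, grouped by missingness pattern
  obs_mask <- !is.na(X)
  pat <- apply(obs_mask, 1L, function(r) paste(which(r), collapse = ","))
  preds_idx <- integer(n)
  for (p in unique(pat)) {
    rows <- which(pat == p)
    obs <- if (nzchar(p)) as.integer(strsplit(p, ",")[[1]]) else integer(0)
    if (!length(obs)) {
      preds_idx[rows] <- which.max(prior)
      next
    }
    marg <- array_marginal(ja, c(1L, obs + 1L))
    m <- matrix(marg, nrow = k_dx)
    mult <- cumprod(c(1L, sizes[obs][-length(obs)]))
    col <- 1L + as.integer((X[rows, obs, drop = FALSE] - 1L) %*% mult)
    pm <- m[, col, drop = FALSE]
    tot <- colSums(pm)
    if (any(tot <= 0)) {
      stop("evidence has probability zero under the model (inconsistent evidence)",
           call. = FALSE)
    }
    preds_idx[rows] <- max.col(t(pm), ties.method = "first")
  }
  preds <- st[[dx]][preds_idx]
  if (!derive) {
    return(list(predictions = preds,
                reasons = replicate(n, character(0), simplify = FALSE)))
  }

  # ---- influence tables: singleton and pair conditionals minus prior
  # single_shift[[j]]: k_dx x s_j matrix of p(d | v_j = s) - p(d)
  single_shift <- vector("list", nv)
  for (j in seq_len(nv)) {
    m <- matrix(array_marginal(ja, c(1L, j + 1L)), nrow = k_dx)
    cond <- sweep(m, 2L, colSums(m), "/")
    single_shift[[j]] <- cond - prior
  }
  pair_idx <- if (nv >= 2L) utils::combn(nv, 2L) else
    matrix(integer(0), nrow = 2)
  n_pairs <- ncol(pair_idx)
  pair_shift <- vector("list", n_pairs)
  for (q in seq_len(n_pairs)) {
    i <- pair_idx[1L, q]; j <- pair_idx[2L, q]
    marg <- array_marginal(ja, c(1L, i + 1L, j + 1L))
    m <- matrix(marg, nrow = k_dx)
    cond <- sweep(m, 2L, colSums(m), "/")
    arr <- array(cond - prior, dim = c(k_dx, sizes[i], sizes[j]))
    pair_shift[[q]] <- arr
  }

  # per-case shift of every candidate (NA where a variable is missing)
  prior_df <- prior[preds_idx]
  s_single <- matrix(NA_real_, nrow = n, ncol = nv)
  for (j in seq_len(nv)) {
    s_single[, j] <- single_shift[[j]][cbind(preds_idx, X[, j])]
  }
  i_pair <- matrix(NA_real_, nrow = n, ncol = n_pairs)
  p_pair <- matrix(NA_real_, nrow = n, ncol = n_pairs)
  for (q in seq_len(n_pairs)) {
    i <- pair_idx[1L, q]; j <- pair_idx[2L, q]
    pd <- pair_shift[[q]][cbind(preds_idx, X[, i], X[, j])]
    s1 <- s_single[, i]; s2 <- s_single[, j]
    f_p <- ifelse(s1 >= 0, s1^2, 0) + ifelse(s2 >= 0, s2^2, 0)
    f_n <- ifelse(s1 < 0, s1^2, 0) + ifelse(s2 < 0, s2^2, 0)
    net <- f_p - f_n
    f <- ifelse(sign(pd) * sign(net) < 0, 0,
                ifelse(abs(pd) >= abs(net), net, pd))
    p_pair[, q] <- pd
    i_pair[, q] <- pd - f
  }

  # element strings for union-building
  el <- matrix(NA_character_, nrow = n, ncol = nv)
  for (j in seq_len(nv)) {
    obs <- which(obs_mask[, j])
    el[obs, j] <- element_string(vars[j], st[[vars[j]]][X[obs, j]])
  }

  reasons <- vector("list", n)
  threshold <- threshold_frac * prior_df
  for (c_ in seq_len(n)) {
    obs <- which(obs_mask[c_, ])
    if (!length(obs)) {
      reasons[[c_]] <- character(0)
      next
    }
    both <- obs_mask[c_, pair_idx[1L, ]] & obs_mask[c_, pair_idx[2L, ]]
    cand_i <- c(s_single[c_, obs], i_pair[c_, both])
    cand_size <- c(rep(1L, length(obs)), rep(2L, sum(both)))
    # element indices: singles then pairs
    cand_a <- c(obs, pair_idx[1L, both])
    cand_b <- c(rep(NA_integer_, length(obs)), pair_idx[2L, both])
    keep <- which(cand_i >= threshold[c_])
    if (!length(keep)) {
      reasons[[c_]] <- character(0)
      next
    }
    ka <- el[c_, cand_a[keep]]
    kb <- el[c_, cand_b[keep]]
    keys <- ifelse(is.na(kb), ka,
                   ifelse(ka < kb, paste(ka, kb, sep = " & "),
                          paste(kb, ka, sep = " & ")))
    ord <- order(-cand_i[keep], cand_size[keep], keys)
    sel <- keep[utils::head(ord, max_reasons)]
    els <- c(el[c_, cand_a[sel]], el[c_, cand_b[sel]])
    reasons[[c_]] <- sort(unique(els[!is.na(els)]))
  }
  list(predictions = preds, reasons = reasons)
}

new_bn_eval <- function(v_r, v_i, n_cases, accuracy_floor, short_circuited,
                        per_fold = NULL, precision = NA_real_,
                        recall = NA_real_) {
  v <- if (short_circuited) v_i else combined_metric(v_r, v_i)
  structure(
    list(v_r = v_r, v_i = v_i, v = v, n_cases = n_cases,
         accuracy_floor = accuracy_floor,
         short_circuited = short_circuited, per_fold = per_fold,
         precision = precision, recall = recall),
    class = "bn_eval"
  )
}

#' @export
print.bn_eval <- function(x, ...) {
  cat(sprintf(
    "<bn_eval> V = %.3f (V_r = %.3f, V_i = %.1f%%) on %d cases%s\n",
    x$v, x$v_r, 100 * x$v_i, x$n_cases,
    if (x$short_circuited) " [low-accuracy short-circuit]" else ""
  ))
  invisible(x)
}

# pull reference reasons from the argument or a list-column of `cases`
resolve_reference_reasons <- function(cases, reference_reasons) {
  if (is.null(reference_reasons) &&
      "reference_reasons" %in% names(cases)) {
    reference_reasons <- cases$reference_reasons
  }
  if (!is.null(reference_reasons) &&
      length(reference_reasons) != nrow(cases)) {
    stop("reference_reasons must have one element per case", call. = FALSE)
  }
  reference_reasons
}

#' Cross-validated structure score
#'
#' Scores a candidate structure by stratified k-fold cross-validation of
#' the case table: each fold's model is fitted on the other folds, the
#' held-out cases' diagnoses are inferred, and (unless short-circuited)
#' their reasons derived; predictions and reasons are pooled across folds
#' before computing \eqn{V_i} and \eqn{V_r}. When pooled accuracy falls
#' below `accuracy_floor`, \eqn{V_r} is set to 0 and \eqn{V = V_i} without
#' deriving any reasons — the time-consuming part of the score — mirroring
#' the low-accuracy short-circuit used during structure search.
#'
#' The function is deterministic given `(cases, structure,
#' reference_reasons, folds, seed, accuracy_floor)`; fold assignment is
#' stratified by diagnosis label and derived from `seed` without touching
#' the caller's RNG stream.
#'
#' @param cases Case table (tibble), one row per case; may carry a
#'   `reference_reasons` list-column.
#' @param structure A valid [bn_structure].
#' @param reference_reasons Optional list of character vectors ("var=state"
#'   elements) overriding the `reference_reasons` column.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param accuracy_floor Accuracy below which the short-circuit fires
#'   (default 0.70).
#' @param pseudocount Smoothing constant for [estimate_parameters()].
#' @param max_reasons,threshold_frac Passed to reason derivation.
#' @param joint_limit State-space size up to which the compiled full-joint
#'   inference path is used (exact either way).
#' @return A `bn_eval` object with fields `v_r`, `v_i`, `v`, `n_cases`,
#'   `short_circuited`, `per_fold` (tibble), `precision`, `recall`.
#' @export
cross_validated_score <- function(cases, structure, reference_reasons = NULL,
                                  folds = 5, seed = 1,
                                  accuracy_floor = 0.70, pseudocount = 1,
                                  max_reasons = 3, threshold_frac = 0.05,
                                  joint_limit = 2^20) {
  stopifnot(folds >= 2, nrow(cases) >= folds)
  schema <- structure$schema
  dx <- diagnosis_variable(schema)
  labels <- as.character(cases[[dx]])
  if (anyNA(labels)) {
    stop("every case must carry a diagnosis label", call. = FALSE)
  }
  reference_reasons <- resolve_reference_reasons(cases, reference_reasons)
  if (prod(lengths(schema_states(schema))) <= joint_limit) {
    ctx <- make_eval_context(cases, schema, reference_reasons, folds, seed,
                             pseudocount)
    return(ctx_score(ctx, structure, accuracy_floor, max_reasons,
                     threshold_frac))
  }
  cv_score_percase(cases, structure, reference_reasons, folds, seed,
                   accuracy_floor, pseudocount, max_reasons, threshold_frac,
                   labels, schema)
}

# fallback for state spaces too large to compile: per-case variable
# elimination fold by fold (identical results; see tests)
cv_score_percase <- function(cases, structure, reference_reasons, folds,
                             seed, accuracy_floor, pseudocount, max_reasons,
                             threshold_frac, labels, schema) {
  dx <- diagnosis_variable(schema)
  fold_id <- stratified_folds(labels, folds, seed,
                              schema$states[[match(dx, schema$name)]])
  for (k in seq_len(folds)) {
    absent <- setdiff(unique(labels), unique(labels[fold_id != k]))
    if (length(absent)) {
      stop("training split of fold ", k, " lacks diagnosis class: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  models <- vector("list", folds)
  preds <- character(nrow(cases))
  for (k in seq_len(folds)) {
    train <- cases[fold_id != k, , drop = FALSE]
    test <- cases[fold_id == k, , drop = FALSE]
    m <- fit_model(train, structure, pseudocount)
    models[[k]] <- m
    sc <- score_cases_ve(m, test, derive = FALSE)
    preds[fold_id == k] <- sc$predictions
  }
  v_i <- inference_accuracy(preds, labels)
  per_fold <- tibble::tibble(
    fold = seq_len(folds),
    n_test = vapply(seq_len(folds), function(k) sum(fold_id == k), integer(1)),
    accuracy = vapply(seq_len(folds), function(k) {
      mean(preds[fold_id == k] == labels[fold_id == k])
    }, numeric(1))
  )
  if (v_i < accuracy_floor) {
    return(new_bn_eval(0, v_i, nrow(cases), accuracy_floor,
                       short_circuited = TRUE, per_fold = per_fold))
  }
  if (is.null(reference_reasons)) {
    stop("reference reasons are required to compute V_r ",
         "(supply `reference_reasons` or a reference_reasons column)",
         call. = FALSE)
  }
  derived <- vector("list", nrow(cases))
  for (k in seq_len(folds)) {
    test_idx <- which(fold_id == k)
    sc <- score_cases_ve(models[[k]], cases[test_idx, , drop = FALSE],
                         derive = TRUE, max_reasons = max_reasons,
                         threshold_frac = threshold_frac)
    derived[test_idx] <- sc$reasons
  }
  fm <- reason_f_measure(reference_reasons, derived)
  new_bn_eval(fm$f_measure, v_i, nrow(cases), accuracy_floor,
              short_circuited = FALSE, per_fold = per_fold,
              precision = fm$precision, recall = fm$recall)
}

# deterministic stratified fold assignment (round-robin within class,
# classes visited in schema state order)
stratified_folds <- function(labels, folds, seed, class_order) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in class_order) {
      idx <- which(labels == cl)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold_id
}

#' Evaluate a structure without cross-validation
#'
#' Fits on `train_cases` (or on `cases` itself when `train_cases` is
#' `NULL`, the resubstitution/training-table style) and scores predictions
#' and derived reasons on `cases`. The same low-accuracy short-circuit as
#' [cross_validated_score()] applies.
#'
#' @inheritParams cross_validated_score
#' @param train_cases Optional case table to fit the parameters on; when
#'   `NULL` the model is fitted and scored on `cases` (training-data
#'   report); pass the training table here to produce a held-out test
#'   report.
#' @return A `bn_eval`.
#' @export
evaluate_model <- function(cases, structure, reference_reasons = NULL,
                           train_cases = NULL, pseudocount = 1,
                           accuracy_floor = 0.70, max_reasons = 3,
                           threshold_frac = 0.05, joint_limit = 2^20) {
  dx <- diagnosis_variable(structure$schema)
  labels <- as.character(cases[[dx]])
  if (anyNA(labels)) {
    stop("every case must carry a diagnosis label", call. = FALSE)
  }
  reference_reasons <- resolve_reference_reasons(cases, reference_reasons)
  m <- fit_model(train_cases %||% cases, structure, pseudocount)
  sc <- score_cases(m, cases, derive = FALSE, joint_limit = joint_limit)
  v_i <- inference_accuracy(sc$predictions, labels)
  if (v_i < accuracy_floor) {
    return(new_bn_eval(0, v_i, nrow(cases), accuracy_floor,
                       short_circuited = TRUE))
  }
  if (is.null(reference_reasons)) {
    stop("reference reasons are required to compute V_r ",
         "(supply `reference_reasons` or a reference_reasons column)",
         call. = FALSE)
  }
  sc <- score_cases(m, cases, derive = TRUE, max_reasons = max_reasons,
                    threshold_frac = threshold_frac,
                    joint_limit = joint_limit)
  fm <- reason_f_measure(reference_reasons, sc$reasons)
  new_bn_eval(fm$f_measure, v_i, nrow(cases), accuracy_floor,
              short_circuited = FALSE,
              precision = fm$precision, recall = fm$recall)
}
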