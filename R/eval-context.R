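# Internal evaluation context: everything about (cases, folds, seed) that
# does not depend on the candidate structure is computed once and reused
# across the thousands of structures scored during a search. Fitted CPTs
# are cached per (fold, node, parent set), since consecutive structures
# share almost all node families; reason elements are handled as integer
# ids into a fixed variable=state dictionary. Results are identical to
# the plain per-structure path; the test suite asserts as much.

make_eval_context <- function(cases, schema, reference_reasons, folds, seed,
                              pseudocount) {
  dx <- diagnosis_variable(schema)
  st <- schema_states(schema)
  vars <- setdiff(schema$name, dx)
  n <- nrow(cases)
  sizes <- lengths(st)

  X <- matrix(NA_integer_, nrow = n, ncol = length(schema$name),
              dimnames = list(NULL, schema$name))
  for (nm in schema$name) X[, nm] <- match(cases[[nm]], st[[nm]])
  labels <- as.character(cases[[dx]])
  if (anyNA(labels)) {
    stop("every case must carry a diagnosis label", call. = FALSE)
  }

  fold_id <- stratified_folds(labels, folds, seed, st[[dx]])
  for (k in seq_len(folds)) {
    absent <- setdiff(unique(labels), unique(labels[fold_id != k]))
    if (length(absent)) {
      stop("training split of fold ", k, " lacks diagnosis class: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }

  # element dictionary: one id per variable=state of non-diagnosis vars
  offsets <- c(0L, cumsum(unname(sizes[vars])))[seq_along(vars)]
  names(offsets) <- vars
  el_dict <- unlist(lapply(vars, function(v) element_string(v, st[[v]])))

  obs_mask <- !is.na(X[, vars, drop = FALSE])
  el_id <- sweep(X[, vars, drop = FALSE], 2L, offsets, "+")
  el <- matrix(el_dict[el_id], nrow = n)

  ref_ids <- NULL
  if (!is.null(reference_reasons)) {
    ref_ids <- lapply(reference_reasons, function(rr) {
      ids <- match(unique(as.character(rr)), el_dict)
      ids[is.na(ids)] <- -seq_len(sum(is.na(ids)))  # never match derived
      ids
    })
  }

  nv <- length(vars)
  pair_idx <- if (nv >= 2L) utils::combn(nv, 2L) else
    matrix(integer(0), nrow = 2)

  pat_key <- apply(obs_mask, 1L, function(r) paste(which(r), collapse = ","))
  fold_info <- lapply(seq_len(folds), function(k) {
    test_rows <- which(fold_id == k)
    pats <- split(seq_along(test_rows), pat_key[test_rows])
    patterns <- lapply(names(pats), function(p) {
      obs <- if (nzchar(p)) as.integer(strsplit(p, ",")[[1]]) else integer(0)
      both_q <- which(pair_idx[1L, ] %in% obs & pair_idx[2L, ] %in% obs)
      list(obs = obs, both_q = both_q, rows = pats[[p]])
    })
    list(test_rows = test_rows, train_rows = which(fold_id != k),
         patterns = patterns,
         X_test = X[test_rows, vars, drop = FALSE],
         el_test = el[test_rows, , drop = FALSE],
         elid_test = el_id[test_rows, , drop = FALSE])
  })

  list(
    schema = schema, dx = dx, st = st, vars = vars, sizes = sizes,
    X = X, labels = labels, label_idx = match(labels, st[[dx]]),
    fold_id = fold_id, folds = folds, fold_info = fold_info,
    pair_idx = pair_idx, el_dict = el_dict,
    reference_reasons = reference_reasons, ref_ids = ref_ids,
    pseudocount = pseudocount,
    cpt_cache = new.env(parent = emptyenv())
  )
}

# smoothed available-case CPT from the integer state matrix
fit_cpt_int <- function(ctx, node, parents, rows) {
  fam <- c(node, parents)
  sub <- ctx$X[rows, fam, drop = FALSE]
  ok <- !rowSums(is.na(sub))
  sub <- sub[ok, , drop = FALSE]
  dims <- unname(ctx$sizes[fam])
  if (nrow(sub) == 0L && ctx$pseudocount == 0) {
    stop(sprintf(
      "node '%s' has zero usable cases and pseudocount is 0: distribution undefined",
      node), call. = FALSE)
  }
  mult <- cumprod(c(1L, dims[-length(dims)]))
  idx <- 1L + as.integer((sub - 1L) %*% mult)
  counts <- tabulate(idx, nbins = prod(dims)) + ctx$pseudocount
  m <- matrix(counts, nrow = dims[1L])
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop(sprintf(
      "node '%s': some parent configuration has zero usable cases and pseudocount is 0",
      node), call. = FALSE)
  }
  m <- sweep(m, 2L, tot, "/")
  array(as.numeric(m), dim = dims,
        dimnames = stats::setNames(ctx$st[fam], fam))
}

ctx_fold_cpts <- function(ctx, structure, fold) {
  pl <- parents_list(structure)
  cpts <- stats::setNames(vector("list", length(pl)), names(pl))
  for (nm in names(pl)) {
    key <- paste0(fold, "|", nm, "|", paste(pl[[nm]], collapse = ","))
    hit <- ctx$cpt_cache[[key]]
    if (is.null(hit)) {
      hit <- fit_cpt_int(ctx, nm, pl[[nm]],
                         ctx$fold_info[[fold]]$train_rows)
      ctx$cpt_cache[[key]] <- hit
    }
    cpts[[nm]] <- hit
  }
  cpts
}

# predictions (diagnosis state indices) for one fold's test rows from a
# compiled joint with dims ordered (dx, vars)
ctx_fold_predict <- function(ja, fi, sizes_vars, k_dx, prior) {
  preds <- integer(nrow(fi$X_test))
  for (p in fi$patterns) {
    if (!length(p$obs)) {
      preds[p$rows] <- which.max(prior)
      next
    }
    marg <- array_marginal(ja, c(1L, p$obs + 1L))
    m <- matrix(marg, nrow = k_dx)
    mult <- cumprod(c(1L, sizes_vars[p$obs][-length(p$obs)]))
    col <- 1L + as.integer((fi$X_test[p$rows, p$obs, drop = FALSE] - 1L) %*%
                             mult)
    pm <- m[, col, drop = FALSE]
    if (any(colSums(pm) <= 0)) {
      stop("evidence has probability zero under the model (inconsistent evidence)",
           call. = FALSE)
    }
    preds[p$rows] <- max.col(t(pm), ties.method = "first")
  }
  preds
}

# derived reason id-sets for one fold's test rows
ctx_fold_reasons <- function(ja, ctx, fi, preds, prior, sizes_vars, k_dx,
                             max_reasons, threshold_frac) {
  Xk <- fi$X_test
  n <- nrow(Xk)
  nv <- ncol(Xk)
  pair_idx <- ctx$pair_idx
  n_pairs <- ncol(pair_idx)

  single_shift <- vector("list", nv)
  for (j in seq_len(nv)) {
    m <- matrix(array_marginal(ja, c(1L, j + 1L)), nrow = k_dx)
    single_shift[[j]] <- sweep(m, 2L, colSums(m), "/") - prior
  }
  prior_df <- prior[preds]
  s_single <- matrix(NA_real_, nrow = n, ncol = nv)
  for (j in seq_len(nv)) {
    s_single[, j] <- single_shift[[j]][cbind(preds, Xk[, j])]
  }
  i_pair <- matrix(NA_real_, nrow = n, ncol = n_pairs)
  for (q in seq_len(n_pairs)) {
    i <- pair_idx[1L, q]; j <- pair_idx[2L, q]
    marg <- array_marginal(ja, c(1L, i + 1L, j + 1L))
    m <- matrix(marg, nrow = k_dx)
    cond <- sweep(m, 2L, colSums(m), "/")
    arr <- array(cond - prior, dim = c(k_dx, sizes_vars[i], sizes_vars[j]))
    pd <- arr[cbind(preds, Xk[, i], Xk[, j])]
    s1 <- s_single[, i]; s2 <- s_single[, j]
    f_p <- s1 * s1 * (s1 >= 0) + s2 * s2 * (s2 >= 0)
    f_n <- s1 * s1 * (s1 < 0) + s2 * s2 * (s2 < 0)
    net <- f_p - f_n
    f <- pd
    i2 <- which(abs(pd) >= abs(net))
    f[i2] <- net[i2]
    i1 <- which(sign(pd) * sign(net) < 0)
    f[i1] <- 0
    i_pair[, q] <- pd - f
  }

  reasons <- vector("list", n)
  threshold <- threshold_frac * prior_df
  for (p in fi$patterns) {
    obs <- p$obs
    if (!length(obs)) {
      reasons[p$rows] <- list(integer(0))
      next
    }
    both_q <- p$both_q
    cand_a <- c(obs, pair_idx[1L, both_q])
    cand_b <- c(rep(NA_integer_, length(obs)), pair_idx[2L, both_q])
    ci <- cbind(s_single[p$rows, obs, drop = FALSE],
                i_pair[p$rows, both_q, drop = FALSE])
    pass <- ci >= threshold[p$rows]
    np <- rowSums(pass)
    cand_size <- c(rep(1L, length(obs)), rep(2L, length(both_q)))
    for (r in seq_along(p$rows)) {
      row <- p$rows[r]
      if (np[r] == 0L) {
        reasons[[row]] <- integer(0)
        next
      }
      keep <- which(pass[r, ])
      sel <- if (np[r] <= max_reasons) {
        keep
      } else {
        ka <- fi$el_test[row, cand_a[keep]]
        kb <- fi$el_test[row, cand_b[keep]]
        keys <- ifelse(is.na(kb), ka,
                       ifelse(ka < kb, paste(ka, kb, sep = " & "),
                              paste(kb, ka, sep = " & ")))
        keep[utils::head(order(-ci[r, keep], cand_size[keep], keys),
                         max_reasons)]
      }
      ids <- c(fi$elid_test[row, cand_a[sel]], fi$elid_test[row, cand_b[sel]])
      reasons[[row]] <- unique(ids[!is.na(ids)])
    }
  }
  reasons
}

# cross-validated score of one structure against a prepared context
ctx_score <- function(ctx, structure, accuracy_floor = 0.70,
                      max_reasons = 3, threshold_frac = 0.05) {
  k_dx <- unname(ctx$sizes[[ctx$dx]])
  sizes_vars <- unname(ctx$sizes[ctx$vars])
  n <- length(ctx$labels)
  perm <- match(c(ctx$dx, ctx$vars), ctx$schema$name)

  joints <- vector("list", ctx$folds)
  priors <- vector("list", ctx$folds)
  preds_idx <- integer(n)
  for (k in seq_len(ctx$folds)) {
    cpts <- ctx_fold_cpts(ctx, structure, k)
    ja <- compile_joint(new_bn_model(structure, cpts))
    ja <- aperm(ja, perm)
    prior <- as.numeric(array_marginal(ja, 1L))
    joints[[k]] <- ja
    priors[[k]] <- prior
    fi <- ctx$fold_info[[k]]
    preds_idx[fi$test_rows] <- ctx_fold_predict(ja, fi, sizes_vars, k_dx,
                                                prior)
  }
  v_i <- mean(preds_idx == ctx$label_idx)
  per_fold <- tibble::tibble(
    fold = seq_len(ctx$folds),
    n_test = vapply(ctx$fold_info, function(fi) length(fi$test_rows),
                    integer(1)),
    accuracy = vapply(ctx$fold_info, function(fi) {
      mean(preds_idx[fi$test_rows] == ctx$label_idx[fi$test_rows])
    }, numeric(1))
  )
  if (v_i < accuracy_floor) {
    return(new_bn_eval(0, v_i, n, accuracy_floor, short_circuited = TRUE,
                       per_fold = per_fold))
  }
  if (is.null(ctx$ref_ids)) {
    stop("reference reasons are required to compute V_r ",
         "(supply `reference_reasons` or a reference_reasons column)",
         call. = FALSE)
  }
  derived <- vector("list", n)
  for (k in seq_len(ctx$folds)) {
    fi <- ctx$fold_info[[k]]
    derived[fi$test_rows] <- ctx_fold_reasons(
      joints[[k]], ctx, fi, preds_idx[fi$test_rows], priors[[k]],
      sizes_vars, k_dx, max_reasons, threshold_frac
    )
  }
  inter <- 0L; n_d <- 0L; n_g <- 0L
  for (i in seq_len(n)) {
    d <- derived[[i]]
    g <- ctx$ref_ids[[i]]
    inter <- inter + sum(match(d, g, nomatch = 0L) > 0L)
    n_d <- n_d + length(d)
    n_g <- n_g + length(g)
  }
  precision <- if (n_d == 0) 0 else inter / n_d
  recall <- if (n_g == 0) 0 else inter / n_g
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  new_bn_eval(f, v_i, n, accuracy_floor, short_circuited = FALSE,
              per_fold = per_fold, precision = precision, recall = recall)
}
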