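# Annealed MCMC search over network structures maximising the combined
# metric V(S), with delete / reverse / join moves constrained to acyclic
# graphs with at most two parents per node.

#' Search configuration
#'
#' Collects the tunable parameters of [run_search()]. Defaults are the
#' study settings: damping ratio beta = 0.999, iteration limit
#' M_l = 10000, stagnation limit M_c = 2500 consecutive non-replacements,
#' accuracy floor 0.70, and 5-fold cross-validation.
#'
#' @param beta Damping ratio in (0, 1): larger values keep downhill moves
#'   acceptable for longer.
#' @param max_iterations Iteration limit \eqn{M_l}.
#' @param stagnation_limit Stop after this many consecutive iterations
#'   without replacement (\eqn{M_c}).
#' @param accuracy_floor Cross-validated accuracy below which a
#'   structure's score short-circuits to \eqn{V_i} and below which the
#'   final model is discarded.
#' @param folds Cross-validation folds.
#' @param seed Integer seed: drives move proposals, acceptance draws, and
#'   fold assignment.
#' @param pseudocount Smoothing constant for parameter estimation.
#' @param joint_limit Passed through to the scorer.
#' @return A list of class `bn_search_config`.
#' @export
search_config <- function(beta = 0.999, max_iterations = 10000,
                          stagnation_limit = 2500, accuracy_floor = 0.70,
                          folds = 5, seed = 1, pseudocount = 1,
                          joint_limit = 2^20) {
  stopifnot(beta > 0, beta < 1, max_iterations >= 1, stagnation_limit >= 1,
            accuracy_floor >= 0, accuracy_floor <= 1, folds >= 2)
  structure(
    list(beta = beta, max_iterations = as.integer(max_iterations),
         stagnation_limit = as.integer(stagnation_limit),
         accuracy_floor = accuracy_floor, folds = as.integer(folds),
         seed = as.integer(seed), pseudocount = pseudocount,
         joint_limit = joint_limit),
    class = "bn_search_config"
  )
}

#' Initial structure, optionally seeded with expert links
#'
#' Without prior knowledge the initial model has no links. With prior
#' knowledge, each listed variable is connected to the diagnosis node by a
#' single edge; by default the edge points from the diagnosis node to the
#' variable (the generative reading: a diagnosis expresses itself in
#' findings), configurable via `direction`. Prior-knowledge edges are
#' ordinary edges: the search may later delete or reverse them.
#'
#' @param schema A [bn_schema].
#' @param prior_links Optional character vector of variable names the
#'   experts consider directly related to the diagnosis.
#' @param direction `"diagnosis_to_variable"` (default) or
#'   `"variable_to_diagnosis"`.
#' @return A [bn_structure].
#' @export
build_initial_structure <- function(schema, prior_links = NULL,
                                    direction = c("diagnosis_to_variable",
                                                  "variable_to_diagnosis")) {
  if (!inherits(schema, "bn_schema")) schema <- bn_schema(schema)
  direction <- match.arg(direction)
  if (is.null(prior_links) || !length(prior_links)) {
    return(bn_structure(schema))
  }
  prior_links <- as.character(prior_links)
  unknown <- setdiff(prior_links, schema$name)
  if (length(unknown)) {
    stop("prior link(s) to unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dx <- diagnosis_variable(schema)
  if (dx %in% prior_links) {
    stop("prior links cannot target the diagnosis variable itself",
         call. = FALSE)
  }
  edges <- if (direction == "diagnosis_to_variable") {
    tibble::tibble(parent = dx, child = prior_links)
  } else {
    tibble::tibble(parent = prior_links, child = dx)
  }
  bn_structure(schema, edges)
}

#' Enumerate all legal moves from a structure
#'
#' A move is one of: *delete* an existing edge, *reverse* an existing edge,
#' or *join* an ordered unlinked pair with a new edge. Only moves whose
#' result is acyclic and keeps every node at two parents or fewer are
#' returned.
#'
#' @param structure A valid [bn_structure].
#' @return A tibble with columns `type` (`"delete"`, `"reverse"`,
#'   `"join"`), `parent`, `child` describing the edge acted upon.
#' @export
enumerate_moves <- function(structure) {
  nodes <- structure$schema$name
  edges <- structure$edges
  adj <- adjacency_list(nodes, edges)
  n_par <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges$child)
    n_par[names(tab)] <- as.integer(tab)
  }
  has_edge <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    assign(paste0(edges$parent[i], ">", edges$child[i]), TRUE,
           envir = has_edge)
  }

  out <- list()
  # deletes: always legal
  if (nrow(edges)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      type = "delete", parent = edges$parent, child = edges$child
    )
  }
  # reverses: p->c becomes c->p; legal iff p gains at most a 2nd parent
  # and no other path p ~> c exists (which would close a cycle)
  if (nrow(edges)) {
    ok <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      p <- edges$parent[i]; ch <- edges$child[i]
      if (n_par[[p]] + 1L > 2L) next
      adj2 <- adj
      adj2[[p]] <- setdiff(adj2[[p]], ch)
      ok[i] <- !reachable(adj2, p, ch)
    }
    if (any(ok)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        type = "reverse", parent = edges$parent[ok], child = edges$child[ok]
      )
    }
  }
  # joins: new edge u->v; v must have < 2 parents and u must not be
  # reachable from v (no cycle)
  join_p <- character(0); join_c <- character(0)
  for (v in nodes) {
    if (n_par[[v]] >= 2L) next
    for (u in nodes) {
      if (u == v) next
      if (!is.null(has_edge[[paste0(u, ">", v)]])) next
      if (reachable(adj, v, u)) next
      join_p <- c(join_p, u); join_c <- c(join_c, v)
    }
  }
  if (length(join_p)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      type = "join", parent = join_p, child = join_c
    )
  }
  if (!length(out)) {
    return(tibble::tibble(type = character(), parent = character(),
                          child = character()))
  }
  dplyr::bind_rows(out)
}

apply_move <- function(structure, type, parent, child) {
  edges <- structure$edges
  if (type == "delete") {
    keep <- !(edges$parent == parent & edges$child == child)
    edges <- edges[keep, , drop = FALSE]
  } else if (type == "reverse") {
    keep <- !(edges$parent == parent & edges$child == child)
    flipped <- tibble::tibble(parent = character(1), child = character(1))
    flipped$parent <- child
    flipped$child <- parent
    edges <- dplyr::bind_rows(edges[keep, , drop = FALSE], flipped)
  } else if (type == "join") {
    edges <- dplyr::bind_rows(edges,
                              tibble::tibble(parent = parent, child = child))
  } else {
    stop("unknown move type: ", type, call. = FALSE)
  }
  new_bn_structure(structure$schema, edges)
}

#' Propose an updated structure
#'
#' Draws one move uniformly at random from [enumerate_moves()] — so the
#' probability of each action type automatically depends on the current
#' structure — and applies it, returning a new structure (the input is
#' untouched). Illegal structures can never be proposed because only legal
#' moves are enumerated. Uses the current RNG stream; call `set.seed()`
#' first for reproducibility.
#'
#' @param structure A valid [bn_structure].
#' @return A list with `structure` (the new [bn_structure]) and `move`
#'   (one-row tibble describing the move taken).
#' @export
propose_update <- function(structure) {
  moves <- enumerate_moves(structure)
  if (nrow(moves) == 0L) {
    stop("no legal move exists from this structure", call. = FALSE)
  }
  i <- sample.int(nrow(moves), 1L)
  mv <- moves[i, , drop = FALSE]
  list(structure = apply_move(structure, mv$type, mv$parent, mv$child),
       move = mv)
}

#' Annealed acceptance probability
#'
#' Probability of replacing the current structure with the proposal:
#' 1 when \eqn{V_{temp} > V_{current}}, otherwise
#' \eqn{\exp(-(V_{current}/V_{temp})\,\beta^{-(M-1)})}. The replacement
#' probability shrinks as the score ratio worsens and as the iteration
#' count \eqn{M} grows (the annealing schedule), so early iterations
#' explore while late ones essentially hill-climb. When
#' \eqn{V_{temp} = 0} (and not better than current) the exponent diverges
#' and the probability is taken as 0.
#'
#' @param v_temp Score of the proposed structure (non-negative).
#' @param v_current Score of the current structure.
#' @param m Iteration count \eqn{M \ge 1}.
#' @param beta Damping ratio in (0, 1).
#' @return A probability in \[0, 1\].
#' @examples
#' acceptance_probability(0.5, 0.5, m = 1, beta = 0.999)  # exp(-1)
#' @export
acceptance_probability <- function(v_temp, v_current, m, beta) {
  stopifnot(m >= 1, beta > 0, beta < 1, v_temp >= 0)
  if (v_temp > v_current) return(1)
  if (v_temp == 0) return(0)
  exp(-(v_current / v_temp) * beta^(-(m - 1)))
}

#' Run the annealed MCMC structure search
#'
#' Implements the search loop: starting from `initial`, each iteration
#' proposes one legal move, scores the proposal by
#' [cross_validated_score()] (with the low-accuracy short-circuit),
#' replaces the current structure with probability
#' [acceptance_probability()], and stops at the iteration limit or after
#' `stagnation_limit` consecutive non-replacements. Scores are cached by
#' canonical edge set, so revisited structures are not re-scored. The
#' final structure is refitted on all cases and evaluated on the training
#' table; the model is flagged `discarded` when its training accuracy
#' falls below the accuracy floor.
#'
#' @param cases Training case table (tibble) with a `reference_reasons`
#'   list-column or a `reference_reasons` argument.
#' @param initial A valid [bn_structure] (see
#'   [build_initial_structure()]).
#' @param config A [search_config()].
#' @param reference_reasons Optional list of reference reason sets.
#' @param max_reasons,threshold_frac Reason-derivation settings.
#' @return An object of class `bn_search`: list with `structure`, `model`
#'   (refit on all cases), `final_eval` (training-table `bn_eval`),
#'   `cv_eval` (the final structure's cross-validated `bn_eval`),
#'   `discarded`, `iterations`, `trace` (one row per iteration), and
#'   `config`.
#' @export
run_search <- function(cases, initial, config = search_config(),
                       reference_reasons = NULL, max_reasons = 3,
                       threshold_frac = 0.05) {
  stopifnot(inherits(initial, "bn_structure"),
            inherits(config, "bn_search_config"), nrow(cases) >= 1)
  viol <- validate_structure(initial)
  if (length(viol)) {
    stop("invalid initial structure: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  reference_reasons <- resolve_reference_reasons(cases, reference_reasons)
  fold_seed <- config$seed + 1L
  score_cache <- new.env(parent = emptyenv())
  schema <- initial$schema
  ctx <- if (prod(lengths(schema_states(schema))) <= config$joint_limit) {
    make_eval_context(cases, schema, reference_reasons, config$folds,
                      fold_seed, config$pseudocount)
  } else {
    NULL
  }
  score_of <- function(struct) {
    key <- edge_key(struct$edges)
    hit <- score_cache[[paste0("k", key)]]
    if (!is.null(hit)) return(hit)
    ev <- if (!is.null(ctx)) {
      ctx_score(ctx, struct, config$accuracy_floor, max_reasons,
                threshold_frac)
    } else {
      cross_validated_score(
        cases, struct, reference_reasons = reference_reasons,
        folds = config$folds, seed = fold_seed,
        accuracy_floor = config$accuracy_floor,
        pseudocount = config$pseudocount, max_reasons = max_reasons,
        threshold_frac = threshold_frac, joint_limit = config$joint_limit
      )
    }
    score_cache[[paste0("k", key)]] <- ev
    ev
  }

  m_l <- config$max_iterations
  trace <- vector("list", m_l)
  with_seed(config$seed, {
    s_current <- initial
    v_current <- score_of(s_current)$v
    stagnation <- 0L
    m <- 0L
    while (m < m_l && stagnation < config$stagnation_limit) {
      m <- m + 1L
      prop <- propose_update(s_current)
      s_temp <- prop$structure
      v_temp <- score_of(s_temp)$v
      p_m <- acceptance_probability(v_temp, v_current, m, config$beta)
      accepted <- stats::runif(1) < p_m
      trace[[m]] <- tibble::tibble(
        iteration = m,
        move = prop$move$type,
        edge = paste0(prop$move$parent, ">", prop$move$child),
        structure_key = edge_key(s_temp$edges),
        v_temp = v_temp,
        v_current = v_current,
        accept_prob = p_m,
        accepted = accepted
      )
      if (accepted) {
        s_current <- s_temp
        v_current <- v_temp
        stagnation <- 0L
      } else {
        stagnation <- stagnation + 1L
      }
    }
  })
  trace <- dplyr::bind_rows(trace[seq_len(m)])
  final_model <- fit_model(cases, s_current, config$pseudocount)
  final_eval <- evaluate_model(
    cases, s_current, reference_reasons = reference_reasons,
    pseudocount = config$pseudocount,
    accuracy_floor = config$accuracy_floor, max_reasons = max_reasons,
    threshold_frac = threshold_frac, joint_limit = config$joint_limit
  )
  structure(
    list(structure = s_current, model = final_model,
         final_eval = final_eval, cv_eval = score_of(s_current),
         discarded = final_eval$v_i < config$accuracy_floor,
         iterations = m, trace = trace, config = config),
    class = "bn_search"
  )
}

#' @export
print.bn_search <- function(x, ...) {
  cat(sprintf(
    "<bn_search> %d iterations, %d edges; training V = %.3f (V_r = %.3f, V_i = %.1f%%)%s\n",
    x$iterations, nrow(x$structure$edges), x$final_eval$v,
    x$final_eval$v_r, 100 * x$final_eval$v_i,
    if (x$discarded) " [DISCARDED: accuracy below floor]" else ""
  ))
  invisible(x)
}
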