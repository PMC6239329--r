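# Exact inference: factor algebra, variable elimination with a min-fill
# ordering, and a compiled full-joint path for small state spaces.

new_factor <- function(vars, val) {
  list(vars = vars, val = val)
}

factor_from_cpt <- function(node, parents, prob) {
  new_factor(c(node, parents), prob)
}

# expand a factor's array to a superset of variables (extra dims replicate)
expand_factor_array <- function(f, vars_out, st) {
  a <- f$val
  if (!length(f$vars)) {
    # scalar factor
    a <- array(as.numeric(a), dim = lengths(st[vars_out]),
               dimnames = stats::setNames(st[vars_out], vars_out))
    return(a)
  }
  extra <- setdiff(vars_out, f$vars)
  if (is.null(dim(a))) {
    a <- array(a, dim = length(a),
               dimnames = stats::setNames(st[f$vars], f$vars))
  }
  if (length(extra)) {
    dn <- c(dimnames(a), stats::setNames(st[extra], extra))
    a <- array(a, dim = lengths(dn), dimnames = dn)
  }
  aperm(a, match(vars_out, c(f$vars, extra)))
}

factor_product <- function(f1, f2, st) {
  vars_out <- union(f1$vars, f2$vars)
  if (!length(vars_out)) {
    return(new_factor(character(0), as.numeric(f1$val) * as.numeric(f2$val)))
  }
  a1 <- expand_factor_array(f1, vars_out, st)
  a2 <- expand_factor_array(f2, vars_out, st)
  new_factor(vars_out, a1 * a2)
}

factor_marginalize <- function(f, var, st) {
  i <- match(var, f$vars)
  stopifnot(!is.na(i))
  if (length(f$vars) == 1L) {
    return(new_factor(character(0), sum(f$val)))
  }
  perm <- c(i, seq_along(f$vars)[-i])
  a <- aperm(f$val, perm)
  new_factor(f$vars[-i], colSums(a, dims = 1L))
}

# condition on evidence: slice the array at the observed state, drop the dim
factor_reduce <- function(f, evidence, st) {
  hit <- intersect(f$vars, names(evidence))
  if (!length(hit)) return(f)
  a <- f$val
  if (is.null(dim(a))) {
    a <- array(a, dim = length(a),
               dimnames = stats::setNames(st[f$vars], f$vars))
  }
  idx <- rep(list(quote(expr = )), length(f$vars))
  for (v in hit) {
    k <- match(evidence[[v]], st[[v]])
    if (is.na(k)) {
      stop(sprintf("illegal state '%s' for variable '%s'", evidence[[v]], v),
           call. = FALSE)
    }
    idx[[match(v, f$vars)]] <- k
  }
  a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  keep <- !(f$vars %in% hit)
  if (!any(keep)) {
    return(new_factor(character(0), as.numeric(a)))
  }
  dn <- dimnames(a)[keep]
  a <- array(as.numeric(a), dim = lengths(dn), dimnames = dn)
  new_factor(f$vars[keep], a)
}

# greedy min-fill elimination ordering over the factors' interaction graph
min_fill_order <- function(scopes, to_eliminate) {
  all_vars <- unique(unlist(scopes))
  nbr <- stats::setNames(vector("list", length(all_vars)), all_vars)
  for (v in all_vars) nbr[[v]] <- character(0)
  for (sc in scopes) {
    for (v in sc) nbr[[v]] <- union(nbr[[v]], setdiff(sc, v))
  }
  out <- character(0)
  remaining <- to_eliminate
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- nbr[[v]]
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L)) {
        for (j in seq(i + 1L, length(nb))) {
          if (!(nb[j] %in% nbr[[nb[i]]])) cnt <- cnt + 1L
        }
      }
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]
    nb <- nbr[[v]]
    for (u in nb) nbr[[u]] <- union(setdiff(nbr[[u]], v), setdiff(nb, u))
    nbr[[v]] <- NULL
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
  }
  out
}

#' Joint probability of a complete assignment
#'
#' Multiplies each node's CPT entry at the assignment's states: the chain
#' rule of the network. Mainly useful for testing and as the basis of
#' brute-force checks of the propagation engine.
#'
#' @param model A `bn_model`.
#' @param assignment Named character vector or list mapping every schema
#'   variable to one of its states.
#' @return A single probability.
#' @export
joint_probability <- function(model, assignment) {
  schema <- model$structure$schema
  assignment <- unlist(assignment)
  missing_vars <- setdiff(schema$name, names(assignment))
  if (length(missing_vars)) {
    stop("assignment is missing variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  st <- schema_states(schema)
  pl <- parents_list(model$structure)
  p <- 1
  for (nm in schema$name) {
    fam <- c(nm, pl[[nm]])
    ks <- vapply(fam, function(v) {
      k <- match(assignment[[v]], st[[v]])
      if (is.na(k)) {
        stop(sprintf("illegal state '%s' for variable '%s'",
                     assignment[[v]], v), call. = FALSE)
      }
      k
    }, integer(1))
    a <- model$cpts[[nm]]
    if (is.null(dim(a))) {
      p <- p * a[[ks[[1L]]]]
    } else {
      p <- p * a[matrix(ks, nrow = 1L)]
    }
  }
  unname(p)
}

#' Exact posterior distribution of a query variable
#'
#' Computes \eqn{p(\mathrm{query} \mid E)} exactly by variable elimination
#' with a greedy min-fill ordering. Evidence on variables d-separated from
#' the query leaves its marginal unchanged; evidence with probability zero
#' under the model is rejected as inconsistent.
#'
#' @param model A `bn_model`.
#' @param evidence Named character vector or list of observed
#'   variable = state assignments (possibly empty). Must not include the
#'   query variable.
#' @param query Name of the variable whose posterior is wanted; defaults
#'   to the diagnosis variable.
#' @return Named numeric vector over the query variable's states, summing
#'   to one.
#' @examples
#' schema <- bn_schema(tibble::tibble(
#'   name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
#'   states = list(c("d1", "d2", "d3"), c("yes", "no"))
#' ))
#' cases <- tibble::tibble(dx = c("d1", "d2", "d3", "d1"),
#'                         f = c("yes", "no", "no", "yes"))
#' m <- fit_model(cases, bn_structure(schema, data.frame(parent = "dx", child = "f")))
#' posterior(m, c(f = "yes"))
#' @export
posterior <- function(model, evidence = NULL, query = model$diagnosis) {
  schema <- model$structure$schema
  st <- schema_states(schema)
  evidence <- as_evidence(evidence, model, allow_diagnosis = query != model$diagnosis)
  if (query %in% names(evidence)) {
    stop("query variable appears in the evidence", call. = FALSE)
  }
  if (!(query %in% schema$name)) {
    stop("unknown query variable: ", query, call. = FALSE)
  }
  pl <- parents_list(model$structure)
  factors <- lapply(schema$name, function(nm) {
    factor_reduce(factor_from_cpt(nm, pl[[nm]], model$cpts[[nm]]),
                  evidence, st)
  })
  scopes <- lapply(factors, `[[`, "vars")
  elim <- setdiff(unique(unlist(scopes)), query)
  ord <- min_fill_order(scopes, elim)
  for (v in ord) {
    has <- vapply(factors, function(f) v %in% f$vars, logical(1))
    fv <- factors[has]
    factors <- factors[!has]
    prod_f <- Reduce(function(a, b) factor_product(a, b, st), fv)
    factors <- c(factors, list(factor_marginalize(prod_f, v, st)))
  }
  res <- Reduce(function(a, b) factor_product(a, b, st), factors)
  if (!length(res$vars)) {
    stop("internal error: query eliminated", call. = FALSE)
  }
  vec <- as.numeric(expand_factor_array(res, query, st))
  names(vec) <- st[[query]]
  # the unnormalised vector is p(query, evidence); a zero total means the
  # evidence itself has probability zero under the model
  if (sum(vec) <= 0) {
    stop("evidence has probability zero under the model (inconsistent evidence)",
         call. = FALSE)
  }
  vec / sum(vec)
}

# normalise user evidence: named character vector, no diagnosis, no NAs
as_evidence <- function(evidence, model, allow_diagnosis = FALSE) {
  if (is.null(evidence) || length(evidence) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  ev <- unlist(evidence)
  ev <- ev[!is.na(ev)]
  if (is.null(names(ev)) || any(names(ev) == "")) {
    stop("evidence must be a named variable = state mapping", call. = FALSE)
  }
  if (anyDuplicated(names(ev))) {
    stop("evidence assigns more than one state to: ",
         paste(unique(names(ev)[duplicated(names(ev))]), collapse = ", "),
         call. = FALSE)
  }
  schema <- model$structure$schema
  unknown <- setdiff(names(ev), schema$name)
  if (length(unknown)) {
    stop("evidence on unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!allow_diagnosis && model$diagnosis %in% names(ev)) {
    stop("the diagnosis variable cannot be used as evidence", call. = FALSE)
  }
  st <- schema_states(schema)
  for (v in names(ev)) {
    if (!(ev[[v]] %in% st[[v]])) {
      stop(sprintf("illegal state '%s' for variable '%s'", ev[[v]], v),
           call. = FALSE)
    }
  }
  ev
}

#' Infer the diagnosis for one case
#'
#' Computes the diagnosis posterior given the evidence and returns the
#' state with the highest posterior probability; ties are broken by schema
#' state order (the first listed state wins).
#'
#' @inheritParams posterior
#' @return A list with `d_f` (the inferred diagnosis state) and
#'   `posterior` (the named posterior vector).
#' @export
infer_diagnosis <- function(model, evidence = NULL) {
  post <- posterior(model, evidence, query = model$diagnosis)
  list(d_f = names(post)[which.max(post)], posterior = post)
}

# ---- compiled full-joint path (exact; used when the state space is small)

joint_size <- function(model) {
  prod(lengths(schema_states(model$structure$schema)))
}

# full joint array, dims in schema order
compile_joint <- function(model) {
  schema <- model$structure$schema
  st <- schema_states(schema)
  pl <- parents_list(model$structure)
  f <- new_factor(character(0), 1)
  for (nm in schema$name) {
    f <- factor_product(f, factor_from_cpt(nm, pl[[nm]], model$cpts[[nm]]), st)
  }
  a <- expand_factor_array(f, schema$name, st)
  a
}

# p(query | evidence) from a compiled joint array
posterior_from_joint <- function(joint, evidence, query) {
  vars <- names(dimnames(joint))
  idx <- rep(list(quote(expr = )), length(vars))
  for (v in names(evidence)) {
    k <- match(evidence[[v]], dimnames(joint)[[v]])
    idx[[match(v, vars)]] <- k
  }
  a <- do.call(`[`, c(list(joint), idx, list(drop = FALSE)))
  qi <- match(query, vars)
  perm <- c(qi, seq_along(vars)[-qi])
  a <- aperm(a, perm)
  vec <- rowSums(a, dims = 1L)
  vec <- as.numeric(vec)
  names(vec) <- dimnames(joint)[[query]]
  if (sum(vec) <= 0) {
    stop("evidence has probability zero under the model (inconsistent evidence)",
         call. = FALSE)
  }
  vec / sum(vec)
}
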