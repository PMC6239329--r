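# Influence-based derivation of reasons for an inferred diagnosis.
#
# A reason candidate R_c is a subset of the case's evidence of size 1 or 2.
# Its influence I(R_c) measures how much presenting ONLY that subset to the
# network shifts the posterior of the inferred diagnosis d_f away from its
# prior. For pairs, a signed synergy penalty subtracts the element-wise
# (non-synergetic) part of the shift so that a pair only scores well when
# the combination genuinely adds something beyond its elements.

#' Posterior shift of a diagnosis state under an evidence subset
#'
#' \eqn{p_d(R_c) = p(d_f \mid R_c) - p(d_f)}: the change in the inferred
#' diagnosis' probability when only the subset `subset` is entered as
#' evidence, relative to the model's marginal (prior) for that state.
#' Evidence d-separated from the diagnosis node yields a shift of exactly
#' zero.
#'
#' @param model A `bn_model`.
#' @param subset Named character vector: the candidate's variable = state
#'   assignments (all other observed findings are removed).
#' @param d_f The diagnosis state whose probability is tracked.
#' @param prior Optional precomputed marginal distribution of the
#'   diagnosis variable (named numeric); computed from the model if `NULL`.
#' @return A signed real number.
#' @export
posterior_shift <- function(model, subset, d_f, prior = NULL) {
  stopifnot(length(subset) >= 1L)
  if (is.null(prior)) prior <- posterior(model, NULL, model$diagnosis)
  if (!(d_f %in% names(prior))) {
    stop("unknown diagnosis state: ", d_f, call. = FALSE)
  }
  post <- posterior(model, subset, model$diagnosis)
  unname(post[[d_f]] - prior[[d_f]])
}

#' Synergy penalty for a two-element reason candidate
#'
#' For a pair, the element-wise net effect is \eqn{f_p - f_n}, where
#' \eqn{f_p} sums the squared non-negative singleton shifts and \eqn{f_n}
#' the squared negative ones. The penalty is 0 when that net effect opposes
#' the pair's own shift in sign; it is \eqn{f_p - f_n} when the pair's
#' shift dominates it in magnitude; otherwise it equals the pair's shift
#' itself, so the pair's influence collapses to zero (the synergy is
#' considered negligible). `sgn(0) = 0` by convention, so a zero net
#' element-wise effect never triggers the opposite-sign branch.
#'
#' @param p_d_pair Signed posterior shift of the pair.
#' @param p_d_singletons Numeric vector of the two elements' singleton
#'   shifts.
#' @return The penalty \eqn{f(R_c)}, a signed real.
#' @export
synergy_penalty <- function(p_d_pair, p_d_singletons) {
  stopifnot(is.numeric(p_d_pair), length(p_d_pair) == 1L,
            is.numeric(p_d_singletons))
  f_p <- sum(p_d_singletons[p_d_singletons >= 0]^2)
  f_n <- sum(p_d_singletons[p_d_singletons < 0]^2)
  net <- f_p - f_n
  if (sgn(p_d_pair) * sgn(net) < 0) {
    0
  } else if (abs(p_d_pair) >= abs(net)) {
    sgn(net) * abs(net)
  } else {
    p_d_pair
  }
}

#' Influence of a reason candidate on the inferred diagnosis
#'
#' For a single-element candidate the influence is its posterior shift; for
#' a pair it is the pair's shift minus the [synergy_penalty()]. Positive
#' influence supports the inferred diagnosis, negative influence opposes
#' it.
#'
#' @inheritParams posterior_shift
#' @param candidate Named character vector of 1 or 2 variable = state
#'   assignments (a subset of the case's evidence).
#' @return A signed real number \eqn{I(R_c)}.
#' @export
influence <- function(model, candidate, d_f, prior = NULL) {
  n <- length(candidate)
  if (n < 1L || n > 2L) {
    stop("a reason candidate has 1 or 2 elements (got ", n, ")",
         call. = FALSE)
  }
  if (is.null(prior)) prior <- posterior(model, NULL, model$diagnosis)
  p_d <- posterior_shift(model, candidate, d_f, prior)
  if (n == 1L) return(p_d)
  singles <- vapply(seq_len(n), function(i) {
    posterior_shift(model, candidate[i], d_f, prior)
  }, numeric(1))
  p_d - synergy_penalty(p_d, singles)
}

#' Derive the reasons justifying a case's inferred diagnosis
#'
#' Enumerates every subset of the evidence of size 1 or 2, scores each by
#' its influence on the inferred diagnosis \eqn{d_f}, rejects candidates
#' with influence below `threshold_frac` times the prior \eqn{p(d_f)}, and
#' selects up to `max_reasons` of the remainder with the highest influence
#' (ties broken by smaller candidate size, then lexicographically by
#' element names). The derived reason set \eqn{R_d} is the union of the
#' selected candidates' elements; it is empty when every candidate is
#' rejected.
#'
#' @inheritParams posterior
#' @param max_reasons Maximum number of selected candidates (default 3).
#' @param threshold_frac Rejection threshold as a fraction of the prior
#'   \eqn{p(d_f)} (default 0.05); applied to the signed influence, so
#'   negative-influence candidates are always rejected.
#' @return An object of class `bn_reasons`: list with `d_f`, `posterior`
#'   (given the full evidence), `prior` (marginal of \eqn{d_f}),
#'   `candidates` (tibble of all scored candidates), `selected` (tibble of
#'   the chosen ones, descending influence), and `derived_elements`
#'   (character vector of "variable=state" strings, the set \eqn{R_d}).
#' @examples
#' schema <- bn_schema(tibble::tibble(
#'   name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
#'   states = list(c("d1", "d2", "d3"), c("yes", "no"))
#' ))
#' cases <- tibble::tibble(dx = c("d1", "d2", "d3", "d1"),
#'                         f = c("yes", "no", "no", "yes"))
#' m <- fit_model(cases, bn_structure(schema, data.frame(parent = "dx", child = "f")))
#' derive_reasons(m, c(f = "yes"))
#' @export
derive_reasons <- function(model, evidence, max_reasons = 3,
                           threshold_frac = 0.05) {
  ev <- as_evidence(evidence, model)
  if (!length(ev)) stop("evidence must be nonempty", call. = FALSE)
  post_fun <- function(sub) posterior(model, sub, model$diagnosis)
  prior <- posterior(model, NULL, model$diagnosis)
  post <- post_fun(ev)
  derive_reasons_core(ev, post, prior, post_fun, max_reasons, threshold_frac)
}

# Shared scoring/selection core. `post_fun(subset)` must return the exact
# diagnosis posterior given ONLY that subset as evidence; both the
# variable-elimination path and the compiled-joint path plug in here, so
# candidate scoring and selection are identical by construction.
derive_reasons_core <- function(ev, post, prior, post_fun,
                                max_reasons = 3, threshold_frac = 0.05) {
  d_f <- names(post)[which.max(post)]
  p0 <- prior[[d_f]]
  vars <- names(ev)
  n <- length(vars)
  singles <- vapply(vars, function(v) {
    unname(post_fun(ev[v])[[d_f]]) - p0
  }, numeric(1))

  cand <- enumerate_candidates(vars)
  rows <- purrr::map(cand, function(idx) {
    vs <- vars[idx]
    sub <- ev[vs]
    if (length(idx) == 1L) {
      p_d <- singles[[vs]]
      infl <- p_d
    } else {
      p_d <- unname(post_fun(sub)[[d_f]]) - p0
      infl <- p_d - synergy_penalty(p_d, unname(singles[vs]))
    }
    tibble::tibble(
      elements = list(stats::setNames(as.character(sub), vs)),
      key = paste(sort(element_string(vs, as.character(sub))),
                  collapse = " & "),
      size = length(idx),
      p_d = p_d,
      influence = infl
    )
  })
  candidates <- dplyr::bind_rows(rows)
  threshold <- threshold_frac * p0
  candidates$rejected <- candidates$influence < threshold
  kept <- candidates[!candidates$rejected, , drop = FALSE]
  kept <- kept[order(-kept$influence, kept$size, kept$key), , drop = FALSE]
  selected <- utils::head(kept, max_reasons)
  derived <- sort(unique(unlist(lapply(selected$elements, function(e) {
    element_string(names(e), unname(e))
  })))) %||% character(0)
  structure(
    list(d_f = d_f, posterior = post, prior = prior,
         threshold = threshold, candidates = candidates,
         selected = selected,
         derived_elements = as.character(derived)),
    class = "bn_reasons"
  )
}

# all index subsets of size 1 and 2, in enumeration-order-independent form
enumerate_candidates <- function(vars) {
  n <- length(vars)
  singles <- as.list(seq_len(n))
  pairs <- if (n >= 2L) {
    cmb <- utils::combn(n, 2L)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    list()
  }
  c(singles, pairs)
}

#' @export
print.bn_reasons <- function(x, ...) {
  cat(sprintf("<bn_reasons> d_f = %s (posterior %.3f, prior %.3f)\n",
              x$d_f, x$posterior[[x$d_f]], x$prior[[x$d_f]]))
  if (nrow(x$selected) == 0L) {
    cat("  no reason passed the acceptance threshold\n")
  } else {
    for (i in seq_len(nrow(x$selected))) {
      cat(sprintf("  %d. %s  (p_d = %+.3f, I = %+.3f)\n", i,
                  x$selected$key[i], x$selected$p_d[i],
                  x$selected$influence[i]))
    }
  }
  invisible(x)
}
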