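# broom-style accessors and ggplot2 autoplot methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted diagnostic model
#'
#' One row per conditional-probability-table entry: the node, its state,
#' the parent configuration (as a single string, empty for parentless
#' nodes), and the probability.
#'
#' @param x A `bn_model`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `state`, `parents`, `probability`.
#' @export
tidy.bn_model <- function(x, ...) {
  schema <- x$structure$schema
  st <- schema_states(schema)
  pl <- parents_list(x$structure)
  purrr::map_dfr(schema$name, function(nm) {
    a <- x$cpts[[nm]]
    fam <- c(nm, pl[[nm]])
    grid <- expand.grid(st[fam], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    tibble::tibble(
      node = nm,
      state = grid[[1L]],
      parents = if (length(pl[[nm]])) {
        apply(grid, 1L, function(r) {
          paste(element_string(pl[[nm]], as.character(r[-1L])),
                collapse = ", ")
        })
      } else {
        ""
      },
      probability = as.numeric(a)
    )
  })
}

#' @rdname tidy.bn_model
#' @export
glance.bn_model <- function(x, ...) {
  np <- lengths(parents_list(x$structure))
  tibble::tibble(
    n_nodes = nrow(x$structure$schema),
    n_edges = nrow(x$structure$edges),
    max_parents = max(np),
    diagnosis = x$diagnosis,
    joint_size = joint_size(x)
  )
}

#' Tidy an evaluation result
#'
#' @param x A `bn_eval` from [cross_validated_score()] or
#'   [evaluate_model()].
#' @param ... Unused.
#' @return `tidy()`: per-fold accuracies when available (else a one-row
#'   summary); `glance()`: one row with `v_r`, `v_i`, `v`, `precision`,
#'   `recall`, `n_cases`, `short_circuited`.
#' @export
tidy.bn_eval <- function(x, ...) {
  if (!is.null(x$per_fold)) {
    x$per_fold
  } else {
    glance.bn_eval(x)
  }
}

#' @rdname tidy.bn_eval
#' @export
glance.bn_eval <- function(x, ...) {
  tibble::tibble(
    v_r = x$v_r, v_i = x$v_i, v = x$v,
    precision = x$precision, recall = x$recall,
    n_cases = x$n_cases, short_circuited = x$short_circuited
  )
}

#' Tidy a structure-search result
#'
#' @param x A `bn_search` from [run_search()].
#' @param ... Unused.
#' @return `tidy()`: the per-iteration trace tibble; `glance()`: one row
#'   with the final scores, iteration count, and discard flag.
#' @export
tidy.bn_search <- function(x, ...) {
  x$trace
}

#' @rdname tidy.bn_search
#' @export
glance.bn_search <- function(x, ...) {
  tibble::tibble(
    v = x$final_eval$v, v_r = x$final_eval$v_r, v_i = x$final_eval$v_i,
    cv_v = x$cv_eval$v, iterations = x$iterations,
    n_edges = nrow(x$structure$edges), discarded = x$discarded,
    seed = x$config$seed
  )
}

#' Tidy derived reasons
#'
#' @param x A `bn_reasons` from [derive_reasons()].
#' @param ... Unused.
#' @return A tibble of all scored candidates with their shift, influence,
#'   rejection flag, and selection rank (NA when unselected).
#' @export
tidy.bn_reasons <- function(x, ...) {
  out <- x$candidates
  out$rank <- match(out$key, x$selected$key)
  out[order(-out$influence, out$size, out$key), ]
}

#' Plot a structure-search trace
#'
#' Shows the score of each proposal and of the retained structure across
#' iterations; acceptances are marked.
#'
#' @param object A `bn_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_search <- function(object, ...) {
  tr <- object$trace
  long <- tidyr::pivot_longer(
    tr[c("iteration", "v_temp", "v_current")],
    cols = c("v_temp", "v_current"),
    names_to = "series", values_to = "score"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$score,
                                     colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(
      data = tr[tr$accepted, , drop = FALSE],
      ggplot2::aes(x = .data$iteration, y = .data$v_temp),
      inherit.aes = FALSE, size = 0.8
    ) +
    ggplot2::scale_colour_manual(
      values = c(v_current = "#1b61a8", v_temp = "grey60"),
      labels = c(v_current = "retained", v_temp = "proposed")
    ) +
    ggplot2::labs(x = "iteration", y = "structure score V",
                  colour = NULL,
                  title = "Annealed structure search") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation result
#'
#' Bar chart of the explanation adequacy, inference accuracy, and
#' combined metric.
#'
#' @param object A `bn_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_eval <- function(object, ...) {
  df <- tibble::tibble(
    component = factor(c("V_r (F-measure)", "V_i (accuracy)", "V (metric)"),
                       levels = c("V_r (F-measure)", "V_i (accuracy)",
                                  "V (metric)")),
    value = c(object$v_r, object$v_i, object$v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col(fill = "#1b61a8", width = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Model evaluation") +
    ggplot2::theme_minimal()
}
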