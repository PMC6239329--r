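#' Estimate conditional probability tables from case records
#'
#' Fits one conditional probability table (CPT) per node by smoothed
#' counting. For a node with states \eqn{s_1..s_K} and a given joint parent
#' configuration, each entry is \eqn{(n_k + a) / (n + aK)} where \eqn{n_k}
#' is the count of cases with that state and parent configuration, \eqn{n}
#' their total, and \eqn{a} the pseudocount (Laplace smoothing by default,
#' so sparse tables never assign probability zero to observed evidence).
#' Counting is available-case: a case contributes to a node's table only
#' when the node and all its parents are observed (clinical variables may
#' be missing).
#'
#' @param cases A data frame of case records, one row per case and one
#'   column per schema variable; values are state labels, `NA` = missing.
#' @param structure A [bn_structure].
#' @param pseudocount Non-negative smoothing constant added to every cell
#'   count. Default 1.
#' @return A named list (one element per variable, schema order). Each
#'   element is a numeric array whose first dimension indexes the node's
#'   states and whose remaining dimensions index parent states, with
#'   `dimnames` named by the variables; every slice along the first
#'   dimension sums to one.
#' @examples
#' schema <- bn_schema(tibble::tibble(
#'   name = c("dx", "f"), kind = c("diagnosis", "imaging_finding"),
#'   states = list(c("d1", "d2", "d3"), c("yes", "no"))
#' ))
#' cases <- tibble::tibble(dx = c("d1", "d1", "d2"), f = c("yes", "no", "no"))
#' estimate_parameters(cases, bn_structure(schema))
#' @seealso [fit_model()] which bundles the tables with the structure.
#' @export
estimate_parameters <- function(cases, structure, pseudocount = 1) {
  stopifnot(inherits(structure, "bn_structure"),
            is.data.frame(cases), pseudocount >= 0)
  schema <- structure$schema
  check_case_columns(cases, schema)
  pl <- parents_list(structure)
  st <- schema_states(schema)
  cpts <- stats::setNames(vector("list", nrow(schema)), schema$name)
  for (nm in schema$name) {
    cpts[[nm]] <- fit_cpt(cases, nm, pl[[nm]], st, pseudocount)
  }
  cpts
}

# validate that every non-NA cell holds a legal state for its column
check_case_columns <- function(cases, schema) {
  missing_cols <- setdiff(schema$name, names(cases))
  if (length(missing_cols)) {
    stop("case table is missing variable column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  st <- schema_states(schema)
  for (nm in schema$name) {
    v <- cases[[nm]]
    bad <- !is.na(v) & !(v %in% st[[nm]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("illegal state '%s' for variable '%s' (row %d)",
                   v[i], nm, i), call. = FALSE)
    }
  }
  invisible(TRUE)
}

fit_cpt <- function(cases, node, parents, st, pseudocount) {
  fam <- c(node, parents)
  sub <- cases[fam]
  complete <- !Reduce(`|`, lapply(sub, is.na), rep(FALSE, nrow(sub)))
  sub <- sub[complete, , drop = FALSE]
  if (nrow(sub) == 0L && pseudocount == 0) {
    stop(sprintf(
      "node '%s' has zero usable cases and pseudocount is 0: distribution undefined",
      node), call. = FALSE)
  }
  fs <- lapply(fam, function(v) factor(sub[[v]], levels = st[[v]]))
  counts <- do.call(table, fs)
  dn <- stats::setNames(st[fam], fam)
  counts <- array(as.numeric(counts), dim = lengths(dn), dimnames = dn)
  smoothed <- counts + pseudocount
  totals <- if (length(parents)) {
    colSums(smoothed, dims = 1L)
  } else {
    sum(smoothed)
  }
  if (any(totals == 0)) {
    stop(sprintf(
      "node '%s': some parent configuration has zero usable cases and pseudocount is 0",
      node), call. = FALSE)
  }
  prob <- if (length(parents)) {
    sweep(smoothed, seq_along(parents) + 1L, totals, "/")
  } else {
    smoothed / totals
  }
  prob
}

#' Fit a diagnostic model on case records
#'
#' Bundles a network structure with CPTs estimated by
#' [estimate_parameters()] into a ready-to-query diagnostic model.
#'
#' @inheritParams estimate_parameters
#' @return An object of class `bn_model`: list with `structure`, `cpts`,
#'   and `diagnosis` (the diagnosis variable's name).
#' @export
fit_model <- function(cases, structure, pseudocount = 1) {
  viol <- validate_structure(structure)
  if (length(viol)) {
    stop("invalid structure: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  cpts <- estimate_parameters(cases, structure, pseudocount)
  new_bn_model(structure, cpts)
}

new_bn_model <- function(structure, cpts) {
  structure(
    list(structure = structure, cpts = cpts,
         diagnosis = diagnosis_variable(structure$schema)),
    class = "bn_model"
  )
}

#' Assemble a diagnostic model from explicit probability tables
#'
#' Used for hand-specified toy networks and by the synthetic-data
#' generator. Each table must be an array shaped as documented in
#' [estimate_parameters()]; distributions are checked to sum to one.
#'
#' @param structure A valid [bn_structure].
#' @param cpts Named list of CPT arrays, one per schema variable.
#' @return A `bn_model`.
#' @export
bn_model <- function(structure, cpts) {
  viol <- validate_structure(structure)
  if (length(viol)) {
    stop("invalid structure: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  schema <- structure$schema
  pl <- parents_list(structure)
  st <- schema_states(schema)
  missing_tabs <- setdiff(schema$name, names(cpts))
  if (length(missing_tabs)) {
    stop("missing CPT(s) for: ", paste(missing_tabs, collapse = ", "),
         call. = FALSE)
  }
  for (nm in schema$name) {
    a <- cpts[[nm]]
    fam <- c(nm, pl[[nm]])
    want <- lengths(st[fam])
    got <- if (is.null(dim(a))) length(a) else dim(a)
    if (!identical(as.integer(got), as.integer(want))) {
      stop(sprintf("CPT for '%s' has dimensions (%s), expected (%s)",
                   nm, paste(got, collapse = ","),
                   paste(want, collapse = ",")), call. = FALSE)
    }
    a <- array(as.numeric(a), dim = want,
               dimnames = stats::setNames(st[fam], fam))
    sums <- if (length(fam) > 1L) colSums(a, dims = 1L) else sum(a)
    if (any(abs(sums - 1) > 1e-9) || any(a < 0) || any(a > 1)) {
      stop(sprintf("CPT for '%s' is not a stochastic table", nm),
           call. = FALSE)
    }
    cpts[[nm]] <- a
  }
  new_bn_model(structure, cpts[schema$name])
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf(
    "<bn_model> %d nodes, %d edges; diagnosis variable: %s\n",
    nrow(x$structure$schema), nrow(x$structure$edges), x$diagnosis
  ))
  invisible(x)
}
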