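#' Define a variable schema for a diagnostic network
#'
#' A schema lists every random variable of a diagnostic Bayesian network:
#' its name, its ordered categorical states, and its kind. Exactly one
#' variable must be of kind `"diagnosis"` (the inference target, e.g. a
#' three-way label such as primary lung cancer / lung metastasis / benign
#' nodule); the remaining variables are coded imaging findings or clinical
#' data with between 2 and 8 states each.
#'
#' @param variables A data frame (or tibble) with columns `name`
#'   (character), `kind` (one of `"diagnosis"`, `"imaging_finding"`,
#'   `"clinical"`), and `states` (a list column of character vectors giving
#'   each variable's ordered state labels).
#'
#' @return A tibble of class `bn_schema` with columns `name`, `kind`,
#'   `states`.
#' @examples
#' schema <- bn_schema(tibble::tibble(
#'   name = c("diagnosis", "shape", "cavitation"),
#'   kind = c("diagnosis", "imaging_finding", "imaging_finding"),
#'   states = list(c("cancer", "metastasis", "benign"),
#'                 c("round", "irregular"),
#'                 c("present", "absent"))
#' ))
#' @export
bn_schema <- function(variables) {
  stopifnot(is.data.frame(variables))
  req <- c("name", "kind", "states")
  missing_cols <- setdiff(req, names(variables))
  if (length(missing_cols)) {
    stop("schema is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(variables[req])
  out$name <- as.character(out$name)
  out$kind <- as.character(out$kind)
  if (!is.list(out$states)) out$states <- as.list(out$states)
  out$states <- lapply(out$states, as.character)

  if (anyDuplicated(out$name)) {
    stop("duplicate variable names in schema: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         call. = FALSE)
  }
  ok_kind <- out$kind %in% c("diagnosis", "imaging_finding", "clinical")
  if (!all(ok_kind)) {
    stop("unknown variable kind(s): ",
         paste(unique(out$kind[!ok_kind]), collapse = ", "), call. = FALSE)
  }
  n_dx <- sum(out$kind == "diagnosis")
  if (n_dx != 1L) {
    stop("schema must contain exactly one diagnosis variable (found ",
         n_dx, ")", call. = FALSE)
  }
  ns <- lengths(out$states)
  if (any(ns < 2L | ns > 8L)) {
    bad <- out$name[ns < 2L | ns > 8L]
    stop("each variable must have between 2 and 8 states; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup_states <- vapply(out$states, anyDuplicated, integer(1)) > 0L
  if (any(dup_states)) {
    stop("duplicate state labels within variable(s): ",
         paste(out$name[dup_states], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("bn_schema", class(tibble::tibble()))
  out
}

#' @export
print.bn_schema <- function(x, ...) {
  dx <- x$name[x$kind == "diagnosis"]
  cat(sprintf(
    "<bn_schema> %d variables (%d finding, %d clinical), diagnosis: %s (%d states)\n",
    nrow(x), sum(x$kind == "imaging_finding"), sum(x$kind == "clinical"),
    dx, length(x$states[[match(dx, x$name)]])
  ))
  NextMethod()
  invisible(x)
}

schema_states <- function(schema) {
  stats::setNames(schema$states, schema$name)
}

diagnosis_variable <- function(schema) {
  schema$name[schema$kind == "diagnosis"][1L]
}
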