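# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions never perturb user-level streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

sgn <- function(x) sign(x)

# canonical string key for an edge set; used for score caching and traces
edge_key <- function(edges) {
  if (nrow(edges) == 0L) return("")
  paste(sort(paste0(edges$parent, ">", edges$child)), collapse = ";")
}

edges_from_key <- function(key) {
  if (identical(key, "")) {
    return(tibble::tibble(parent = character(), child = character()))
  }
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], ">", fixed = TRUE)
  tibble::tibble(
    parent = vapply(parts, `[[`, character(1), 1L),
    child = vapply(parts, `[[`, character(1), 2L)
  )
}

# "variable=state" element strings used for reasons and their set algebra
element_string <- function(variable, state) paste0(variable, "=", state)

parse_elements <- function(x) {
  parts <- strsplit(x, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed reason element(s): ", paste(x[bad], collapse = ", "),
         " (expected \"variable=state\")", call. = FALSE)
  }
  tibble::tibble(
    variable = vapply(parts, `[[`, character(1), 1L),
    state = vapply(parts, `[[`, character(1), 2L)
  )
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
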