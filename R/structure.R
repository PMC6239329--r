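#' Create a network structure over a variable schema
#'
#' A structure is a directed acyclic graph over the schema's variables in
#' which each node has at most two parents. Edge endpoints must exist in
#' the schema; cycles and parent-limit violations may be present in a
#' freshly constructed object and are reported by [validate_structure()]
#' (the structure search never visits an invalid structure).
#'
#' @param schema A [bn_schema].
#' @param edges A data frame with character columns `parent` and `child`,
#'   one row per directed link. Defaults to the empty edge set.
#' @return An object of class `bn_structure`: a list with elements
#'   `schema` and `edges` (a tibble).
#' @examples
#' schema <- bn_schema(tibble::tibble(
#'   name = c("dx", "a", "b"),
#'   kind = c("diagnosis", "imaging_finding", "imaging_finding"),
#'   states = list(c("d1", "d2", "d3"), c("yes", "no"), c("yes", "no"))
#' ))
#' s <- bn_structure(schema, data.frame(parent = "dx", child = "a"))
#' validate_structure(s)
#' @export
bn_structure <- function(schema, edges = NULL) {
  if (!inherits(schema, "bn_schema")) schema <- bn_schema(schema)
  if (is.null(edges)) {
    edges <- tibble::tibble(parent = character(), child = character())
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges <- tibble::tibble(parent = as.character(edges$parent),
                          child = as.character(edges$child))
  unknown <- setdiff(unique(c(edges$parent, edges$child)), schema$name)
  if (length(unknown)) {
    stop("edge endpoint(s) not in schema: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  new_bn_structure(schema, edges)
}

# hot-path constructor: no endpoint checks
new_bn_structure <- function(schema, edges) {
  structure(list(schema = schema, edges = edges), class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("<bn_structure> %d nodes, %d edges\n",
              nrow(x$schema), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$parent, " -> ", x$edges$child, "\n"), sep = "")
  }
  invisible(x)
}

# named list: variable -> character vector of parents (schema order)
parents_list <- function(structure) {
  pl <- stats::setNames(
    vector("list", nrow(structure$schema)), structure$schema$name
  )
  for (nm in names(pl)) pl[[nm]] <- character(0)
  if (nrow(structure$edges)) {
    sp <- split(structure$edges$parent, structure$edges$child)
    pl[names(sp)] <- sp
  }
  pl
}

# Kahn's algorithm; returns NULL if the graph has a cycle
topological_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges$child)
    indeg[names(tab)] <- as.integer(tab)
    sp <- split(edges$child, edges$parent)
    adj[names(sp)] <- sp
  }
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

# TRUE iff `to` is reachable from `from` along directed edges (DFS on an
# adjacency list); used for incremental acyclicity checks in move legality
reachable <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- character(0)
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (w == to) return(TRUE)
      if (!(w %in% seen)) {
        seen <- c(seen, w)
        stack <- c(stack, w)
      }
    }
  }
  FALSE
}

adjacency_list <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nm in nodes) adj[[nm]] <- character(0)
  if (nrow(edges)) {
    sp <- split(edges$child, edges$parent)
    adj[names(sp)] <- sp
  }
  adj
}

#' Validate a network structure
#'
#' Checks the structural constraints of a diagnostic network: edge
#' endpoints exist, no self-loops or duplicate edges, the graph is acyclic,
#' and no node has more than two parents (a complexity cap on the
#' conditional probability tables). Violations are described, not raised,
#' so callers can report all problems at once.
#'
#' @param structure A [bn_structure].
#' @return A character vector of human-readable violation descriptions;
#'   empty if the structure is valid.
#' @export
validate_structure <- function(structure) {
  stopifnot(inherits(structure, "bn_structure"))
  edges <- structure$edges
  nodes <- structure$schema$name
  out <- character(0)

  unknown <- setdiff(unique(c(edges$parent, edges$child)), nodes)
  if (length(unknown)) {
    out <- c(out, paste0("unknown endpoint(s): ",
                         paste(unknown, collapse = ", ")))
  }
  loops <- edges$parent == edges$child
  if (any(loops)) {
    out <- c(out, paste0("self-loop at: ",
                         paste(unique(edges$parent[loops]), collapse = ", ")))
  }
  key <- paste0(edges$parent, ">", edges$child)
  if (anyDuplicated(key)) {
    out <- c(out, paste0("duplicate edge(s): ",
                         paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  np <- table(edges$child)
  over <- names(np)[np > 2L]
  if (length(over)) {
    out <- c(out, paste0("more than two parents at: ",
                         paste(over, collapse = ", ")))
  }
  if (!length(unknown) && !any(loops) &&
      is.null(topological_order(nodes, edges))) {
    out <- c(out, "graph contains a cycle")
  }
  out
}
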