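# File formats: schema JSON, cases CSV (empty cell = missing), reference
# reasons JSON, prior-links JSON, model JSON, and XMLBIF export.

#' Write and read a dataset bundle
#'
#' A dataset bundle is a schema JSON file (`variables`: name, kind,
#' states), a cases CSV (one column per variable, one row per case, a
#' mandatory `case_id` column, empty cell = missing), and optionally a
#' reference-reasons JSON (case id to a list of "variable=state" strings).
#' `read_dataset()` validates every cell against the schema and reports
#' the offending row, column, and value.
#'
#' @param cases Case tibble (with `case_id`; a `reference_reasons`
#'   list-column is written to `reasons_path` if given).
#' @param schema A [bn_schema].
#' @param schema_path,cases_path,reasons_path File paths (reasons
#'   optional).
#' @return `write_dataset()` returns the paths invisibly;
#'   `read_dataset()` returns a list with `schema`, `cases` (tibble, row
#'   order preserved, `reference_reasons` list-column if a reasons file
#'   was given).
#' @export
write_dataset <- function(cases, schema, schema_path, cases_path,
                          reasons_path = NULL) {
  write_schema(schema, schema_path)
  cols <- c("case_id", schema$name)
  if (!("case_id" %in% names(cases))) {
    cases <- dplyr::mutate(cases,
                           case_id = sprintf("case%05d", dplyr::row_number()))
  }
  readr::write_csv(cases[cols], cases_path, na = "")
  if (!is.null(reasons_path)) {
    rr <- cases$reference_reasons
    if (is.null(rr)) {
      stop("cases carry no reference_reasons column to write", call. = FALSE)
    }
    names(rr) <- cases$case_id
    jsonlite::write_json(lapply(rr, as.character), reasons_path,
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(c(schema_path, cases_path, reasons_path))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(schema_path, cases_path, reasons_path = NULL) {
  schema <- read_schema(schema_path)
  cases <- readr::read_csv(
    cases_path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE
  )
  if (!("case_id" %in% names(cases))) {
    stop("cases file lacks a case_id column", call. = FALSE)
  }
  if (anyDuplicated(cases$case_id)) {
    stop("duplicate case id(s): ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]),
               collapse = ", "), call. = FALSE)
  }
  dx <- diagnosis_variable(schema)
  if (!(dx %in% names(cases))) {
    stop("cases file lacks the mandatory diagnosis column '", dx, "'",
         call. = FALSE)
  }
  missing_cols <- setdiff(schema$name, names(cases))
  if (length(missing_cols)) {
    stop("cases file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  st <- schema_states(schema)
  for (nm in schema$name) {
    v <- cases[[nm]]
    bad <- !is.na(v) & !(v %in% st[[nm]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "illegal value '%s' in column '%s', row %d (case %s): not a state of the schema",
        v[i], nm, i, cases$case_id[i]), call. = FALSE)
    }
  }
  out <- list(schema = schema, cases = cases[c("case_id", schema$name)])
  if (!is.null(reasons_path)) {
    rr <- jsonlite::read_json(reasons_path, simplifyVector = TRUE)
    if (is.data.frame(rr)) rr <- as.list(rr)
    missing_ids <- setdiff(cases$case_id, names(rr))
    if (length(missing_ids)) {
      stop("reference reasons missing for case(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           call. = FALSE)
    }
    rr <- lapply(rr[cases$case_id], as.character)
    for (id in names(rr)) {
      el <- parse_elements(rr[[id]])
      for (j in seq_len(nrow(el))) {
        v <- el$variable[j]
        if (!(v %in% schema$name) || !(el$state[j] %in% st[[v]])) {
          stop(sprintf(
            "reference reason '%s' of case %s does not match the schema",
            rr[[id]][j], id), call. = FALSE)
        }
      }
    }
    out$cases$reference_reasons <- unname(rr)
  }
  out
}

write_schema <- function(schema, path) {
  jsonlite::write_json(
    list(variables = lapply(seq_len(nrow(schema)), function(i) {
      list(name = jsonlite::unbox(schema$name[i]),
           kind = jsonlite::unbox(schema$kind[i]),
           states = schema$states[[i]])
    })),
    path, pretty = TRUE, digits = NA
  )
  invisible(path)
}

read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- raw$variables
  bn_schema(tibble::tibble(
    name = vapply(vars, function(v) v$name, character(1)),
    kind = vapply(vars, function(v) v$kind, character(1)),
    states = lapply(vars, function(v) unlist(v$states))
  ))
}

#' Read or write a prior-knowledge link list
#'
#' A JSON array of variable names that experts consider directly related
#' to the diagnosis node; consumed by [build_initial_structure()].
#'
#' @param links Character vector of variable names.
#' @param path File path.
#' @return The links (character vector) or the path, invisibly.
#' @export
write_prior_links <- function(links, path) {
  jsonlite::write_json(as.character(links), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_prior_links
#' @export
read_prior_links <- function(path) {
  as.character(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Model serialisation to and from JSON
#'
#' Writes a `bn_model` as a single JSON document `{schema, edges, tables}`
#' with states as strings and probabilities at full precision, so a
#' write-read-write cycle is byte-identical. Table values are flattened in
#' array order (node states fastest, then parents in their listed order).
#'
#' @param model A `bn_model`.
#' @param path File path.
#' @return `read_model()` returns the `bn_model`; `write_model()` the
#'   path, invisibly.
#' @export
write_model <- function(model, path) {
  schema <- model$structure$schema
  pl <- parents_list(model$structure)
  doc <- list(
    schema = lapply(seq_len(nrow(schema)), function(i) {
      list(name = jsonlite::unbox(schema$name[i]),
           kind = jsonlite::unbox(schema$kind[i]),
           states = schema$states[[i]])
    }),
    edges = lapply(seq_len(nrow(model$structure$edges)), function(i) {
      list(parent = jsonlite::unbox(model$structure$edges$parent[i]),
           child = jsonlite::unbox(model$structure$edges$child[i]))
    }),
    tables = stats::setNames(lapply(schema$name, function(nm) {
      list(parents = pl[[nm]],
           values = as.numeric(model$cpts[[nm]]))
    }), schema$name)
  )
  jsonlite::write_json(doc, path, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- bn_schema(tibble::tibble(
    name = vapply(raw$schema, function(v) v$name, character(1)),
    kind = vapply(raw$schema, function(v) v$kind, character(1)),
    states = lapply(raw$schema, function(v) unlist(v$states))
  ))
  edges <- if (length(raw$edges)) {
    tibble::tibble(
      parent = vapply(raw$edges, function(e) e$parent, character(1)),
      child = vapply(raw$edges, function(e) e$child, character(1))
    )
  } else {
    NULL
  }
  struct <- bn_structure(schema, edges)
  st <- schema_states(schema)
  pl <- parents_list(struct)
  cpts <- stats::setNames(lapply(schema$name, function(nm) {
    tab <- raw$tables[[nm]]
    pars <- as.character(unlist(tab$parents))
    if (!identical(pars, pl[[nm]])) {
      # parents must match the edge set (order as stored)
      if (!setequal(pars, pl[[nm]])) {
        stop(sprintf("table parents for '%s' disagree with the edges", nm),
             call. = FALSE)
      }
    }
    fam <- c(nm, pars)
    array(as.numeric(unlist(tab$values)), dim = lengths(st[fam]),
          dimnames = stats::setNames(st[fam], fam))
  }), schema$name)
  bn_model(struct, cpts)
}

#' Export a model to XMLBIF
#'
#' Writes the interchange format understood by common Bayesian-network
#' tools (XMLBIF 0.3). Probabilities are written in the XMLBIF convention:
#' for each node, the table lists the node's distribution for every joint
#' parent configuration, parents varying as listed.
#'
#' @param model A `bn_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_xmlbif <- function(model, path) {
  schema <- model$structure$schema
  pl <- parents_list(model$structure)
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  net <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(net, "NAME", "diagnostic_network")
  for (i in seq_len(nrow(schema))) {
    v <- xml2::xml_add_child(net, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(v, "NAME", schema$name[i])
    for (s in schema$states[[i]]) xml2::xml_add_child(v, "OUTCOME", s)
  }
  for (nm in schema$name) {
    d <- xml2::xml_add_child(net, "DEFINITION")
    xml2::xml_add_child(d, "FOR", nm)
    for (p in pl[[nm]]) xml2::xml_add_child(d, "GIVEN", p)
    a <- model$cpts[[nm]]
    # one distribution block per parent configuration, the node's states
    # varying fastest (our array order)
    vals <- format(as.numeric(a), digits = 17, scientific = FALSE,
                   trim = TRUE)
    xml2::xml_add_child(d, "TABLE", paste(vals, collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
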