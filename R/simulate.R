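# Synthetic diagnostic-network generator. Emulates the SHAPE of a coded
# lung-nodule case table — a 3-state diagnosis, categorical imaging
# findings and clinical variables with 2-8 states, missing clinical
# values, and per-case reference reasons of 1-7 elements — with a known
# ground-truth network. Reference reasons are ORACLE-DERIVED from the
# ground-truth model, not expert-chosen: they exercise the evaluation
# machinery but are no substitute for clinical annotations.

#' Specification for the synthetic ground-truth generator
#'
#' Defaults reproduce the emulated study schema: 49 imaging-finding
#' variables and 37 clinical variables with between 2 and 8 states each,
#' and a diagnosis variable with three states (primary lung cancer, lung
#' metastasis, benign lung nodule).
#'
#' @param n_findings Number of imaging-finding variables.
#' @param n_clinical Number of clinical variables.
#' @param states_min,states_max Range of state counts for non-diagnosis
#'   variables (2 to 8).
#' @param n_diagnosis_states Number of diagnosis states (3 in the study
#'   schema).
#' @param n_informative Number of finding variables attached as children
#'   of the diagnosis node (the signal carriers).
#' @param edge_density Expected extra finding/clinical edges per
#'   non-diagnosis variable (beyond the diagnosis-to-finding links),
#'   respecting acyclicity and the two-parent limit.
#' @param effect_strength In \[0, 1\): 0 makes every child row uniform
#'   (diagnosis independent of findings); values near 1 sharpen the rows
#'   towards deterministic finding-diagnosis relationships.
#' @param missing_rate Probability that a clinical value is masked in
#'   sampled cases.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the spec.
#' @return A list of class `bn_generator_spec`.
#' @export
generator_spec <- function(n_findings = 49, n_clinical = 37,
                           states_min = 2, states_max = 8,
                           n_diagnosis_states = 3,
                           n_informative = min(12, n_findings),
                           edge_density = 0.1, effect_strength = 0.8,
                           missing_rate = 0.1, seed = 1) {
  stopifnot(n_findings >= 1, n_clinical >= 0,
            states_min >= 2, states_max <= 8, states_min <= states_max,
            n_diagnosis_states >= 2, n_diagnosis_states <= 8,
            n_informative >= 0, n_informative <= n_findings,
            edge_density >= 0, effect_strength >= 0, effect_strength < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(n_findings = as.integer(n_findings),
         n_clinical = as.integer(n_clinical),
         states_min = as.integer(states_min),
         states_max = as.integer(states_max),
         n_diagnosis_states = as.integer(n_diagnosis_states),
         n_informative = as.integer(n_informative),
         edge_density = edge_density, effect_strength = effect_strength,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "bn_generator_spec"
  )
}

#' Generate a ground-truth diagnostic model
#'
#' Builds a random schema and DAG satisfying the structural constraints
#' (acyclic, at most two parents): the diagnosis node is parentless with a
#' mildly imbalanced prior, `n_informative` findings are its children, and
#' extra finding/clinical edges are added at `edge_density`. CPT rows are
#' drawn from a symmetric Dirichlet and sharpened by tempering with
#' exponent \eqn{s/(1-s)} where \eqn{s} is `effect_strength` — at
#' \eqn{s = 0} every row is exactly uniform.
#'
#' @param spec A [generator_spec()].
#' @return A `bn_model` whose schema, structure, and tables are fully
#'   determined by `spec` (including its seed).
#' @export
make_ground_truth <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "bn_generator_spec"))
  with_seed(spec$seed, {
    dx_states <- if (spec$n_diagnosis_states == 3L) {
      c("primary_lung_cancer", "lung_metastasis", "benign_nodule")
    } else {
      paste0("d", seq_len(spec$n_diagnosis_states))
    }
    f_names <- sprintf("finding_%02d", seq_len(spec$n_findings))
    c_names <- if (spec$n_clinical) {
      sprintf("clinical_%02d", seq_len(spec$n_clinical))
    } else {
      character(0)
    }
    n_states <- function(n) {
      if (spec$states_min == spec$states_max) {
        rep(spec$states_min, n)
      } else {
        sample(spec$states_min:spec$states_max, n, replace = TRUE)
      }
    }
    schema <- bn_schema(tibble::tibble(
      name = c("diagnosis", f_names, c_names),
      kind = c("diagnosis", rep("imaging_finding", spec$n_findings),
               rep("clinical", length(c_names))),
      states = c(list(dx_states),
                 lapply(n_states(spec$n_findings),
                        function(k) paste0("s", seq_len(k))),
                 lapply(n_states(length(c_names)),
                        function(k) paste0("s", seq_len(k))))
    ))

    informative <- if (spec$n_informative) {
      sort(sample(f_names, spec$n_informative))
    } else {
      character(0)
    }
    edges <- tibble::tibble(parent = rep("diagnosis", length(informative)),
                            child = informative)
    # extra edges among non-diagnosis variables, respecting constraints;
    # orientation follows schema order so acyclicity is automatic
    others <- c(f_names, c_names)
    n_extra <- if (length(others) >= 2L) {
      stats::rpois(1, spec$edge_density * length(others))
    } else {
      0L
    }
    n_par <- stats::setNames(integer(nrow(schema)), schema$name)
    if (nrow(edges)) {
      tabp <- table(edges$child)
      n_par[names(tabp)] <- as.integer(tabp)
    }
    tries <- 0L
    while (n_extra > 0L && tries < 50L * n_extra + 50L) {
      tries <- tries + 1L
      uv <- sample(others, 2L)
      # orient by schema position: earlier -> later
      pos <- match(uv, schema$name)
      u <- uv[which.min(pos)]; v <- uv[which.max(pos)]
      dup <- any(edges$parent == u & edges$child == v)
      if (dup || n_par[[v]] >= 2L) next
      edges <- dplyr::bind_rows(edges, tibble::tibble(parent = u, child = v))
      n_par[[v]] <- n_par[[v]] + 1L
      n_extra <- n_extra - 1L
    }
    struct <- bn_structure(schema, edges)
    viol <- validate_structure(struct)
    if (length(viol)) {
      stop("generator produced an invalid structure: ",
           paste(viol, collapse = "; "), call. = FALSE)
    }

    st <- schema_states(schema)
    pl <- parents_list(struct)
    tau <- spec$effect_strength / (1 - spec$effect_strength)
    sharpen <- function(p) {
      if (tau == 0) return(rep(1 / length(p), length(p)))
      q <- p^tau
      q / sum(q)
    }
    cpts <- stats::setNames(vector("list", nrow(schema)), schema$name)
    for (nm in schema$name) {
      fam <- c(nm, pl[[nm]])
      dims <- lengths(st[fam])
      k <- dims[[1L]]
      n_rows <- prod(dims) / k
      rows <- vapply(seq_len(n_rows), function(i) {
        if (nm == "diagnosis") {
          # mildly imbalanced but never degenerate prior
          g <- stats::rgamma(k, shape = 3)
          g / sum(g)
        } else {
          sharpen(stats::rgamma(k, shape = 1) / 1)
        }
      }, numeric(k))
      a <- array(as.numeric(rows), dim = dims,
                 dimnames = stats::setNames(st[fam], fam))
      cpts[[nm]] <- a
    }
    bn_model(struct, cpts)
  })
}

#' Sample synthetic case records from a model
#'
#' Ancestral sampling: each node is drawn after its parents in topological
#' order. Clinical values are then masked independently at `missing_rate`;
#' the diagnosis label is always retained.
#'
#' @param model A `bn_model` (typically from [make_ground_truth()]).
#' @param n Number of cases.
#' @param missing_rate Probability in \[0, 1) that a clinical value is
#'   set to `NA`.
#' @param seed Integer seed.
#' @return A tibble with a `case_id` column and one character column per
#'   schema variable.
#' @export
sample_cases <- function(model, n, missing_rate = 0, seed = 1) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1)
  schema <- model$structure$schema
  st <- schema_states(schema)
  pl <- parents_list(model$structure)
  ord <- topological_order(schema$name, model$structure$edges)
  with_seed(seed, {
    out <- stats::setNames(
      replicate(nrow(schema), character(n), simplify = FALSE), schema$name
    )
    for (nm in ord) {
      pars <- pl[[nm]]
      a <- model$cpts[[nm]]
      k <- length(st[[nm]])
      if (!length(pars)) {
        probs <- as.numeric(a)
        idx <- sample.int(k, n, replace = TRUE, prob = probs)
      } else {
        # row index into the CPT for each case from its parents' states
        pidx <- lapply(pars, function(p) match(out[[p]], st[[p]]))
        mult <- cumprod(c(1, lengths(st[pars])))
        row0 <- Reduce(`+`, Map(function(ix, m) (ix - 1L) * m,
                                pidx, mult[seq_along(pars)]), rep(0L, n))
        amat <- matrix(as.numeric(a), nrow = k)
        u <- stats::runif(n)
        idx <- integer(n)
        for (r in unique(row0)) {
          sel <- row0 == r
          cum <- cumsum(amat[, r + 1L])
          idx[sel] <- findInterval(u[sel], cum) + 1L
        }
      }
      out[[nm]] <- st[[nm]][idx]
    }
    clin <- schema$name[schema$kind == "clinical"]
    if (missing_rate > 0 && length(clin)) {
      for (nm in clin) {
        mask <- stats::runif(n) < missing_rate
        out[[nm]][mask] <- NA_character_
      }
    }
    tibble::as_tibble(c(list(case_id = sprintf("case%05d", seq_len(n))), out))
  })
}

#' Oracle reference reasons for synthetic cases
#'
#' For each case, every observed singleton is scored by the absolute
#' posterior shift it induces on the TRUE diagnosis state under the
#' ground-truth model; elements with shift at least `shift_floor` are
#' kept, best first, up to `k_max`, and the single best element is kept
#' when none clears the floor (so every set has 1 to `k_max` elements).
#' These oracle sets emulate the ROLE of expert-chosen reference reasons;
#' they are not clinical ground truth.
#'
#' @param model The ground-truth `bn_model` the cases were sampled from.
#' @param cases Case tibble from [sample_cases()].
#' @param k_max Maximum set size (default 7).
#' @param shift_floor Minimum absolute posterior shift for inclusion
#'   (default 0.05).
#' @return A list (one character vector of "variable=state" elements per
#'   case), suitable as `reference_reasons`.
#' @export
annotate_reference_reasons <- function(model, cases, k_max = 7,
                                       shift_floor = 0.05) {
  stopifnot(k_max >= 1)
  schema <- model$structure$schema
  dx <- model$diagnosis
  post_fun <- make_post_fun(model)
  prior <- post_fun(stats::setNames(character(0), character(0)))
  purrr::map(seq_len(nrow(cases)), function(i) {
    row <- cases[i, , drop = FALSE]
    ev <- case_evidence(row, schema$name, dx)
    truth <- as.character(row[[dx]])
    shifts <- vapply(names(ev), function(v) {
      unname(post_fun(ev[v])[[truth]]) - prior[[truth]]
    }, numeric(1))
    ord <- order(-abs(shifts), names(ev))
    keep <- ord[abs(shifts)[ord] >= shift_floor]
    if (!length(keep)) keep <- ord[1L]
    keep <- utils::head(keep, k_max)
    vs <- names(ev)[keep]
    element_string(vs, as.character(ev[vs]))
  })
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: generates the ground-truth model, samples `n`
#' cases, and attaches oracle reference reasons as a list-column.
#'
#' @param spec A [generator_spec()].
#' @param n Number of cases.
#' @return A list with `model` (ground truth), `cases` (tibble including a
#'   `reference_reasons` list-column), and `spec`.
#' @export
simulate_dataset <- function(spec = generator_spec(), n = 179) {
  model <- make_ground_truth(spec)
  cases <- sample_cases(model, n, missing_rate = spec$missing_rate,
                        seed = spec$seed + 1L)
  cases$reference_reasons <- annotate_reference_reasons(model, cases)
  list(model = model, cases = cases, spec = spec)
}
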