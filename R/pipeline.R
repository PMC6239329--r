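# Workflow driver behind the command-line interface: each command reads
# validated inputs, runs the corresponding module, and writes plain-text
# artifacts (JSON / CSV / TSV). All randomness flows from a single seed
# option. Identical invocations produce identical outputs.

#' Run a named workflow command
#'
#' Ties the modules into end-to-end workflows:
#' \describe{
#'   \item{simulate}{Generate a ground-truth model and synthetic cases;
#'     writes `schema.json`, `cases.csv`, `reasons.json`,
#'     `ground_truth_model.json`, `prior_links.json`.}
#'   \item{train}{Fit parameters on a fixed structure (from a model JSON);
#'     writes `model.json`.}
#'   \item{infer}{Per-case inferred diagnosis and posterior;
#'     writes `inferences.csv`.}
#'   \item{explain}{Per-case diagnosis plus derived reasons;
#'     writes `explanations.json`.}
#'   \item{evaluate}{Training-table and optional held-out report with
#'     F-measure, accuracy (%), and combined metric; writes
#'     `evaluation.tsv` and `evaluation.json`.}
#'   \item{search}{Annealed MCMC structure search; writes `model.json`,
#'     `trace.tsv`, `evaluation.json`.}
#' }
#'
#' @param command One of `"simulate"`, `"train"`, `"infer"`, `"explain"`,
#'   `"evaluate"`, `"search"`.
#' @param options Named list of options; see Details of the individual
#'   commands in the package vignette. Common options: `schema`, `cases`,
#'   `reasons`, `model`, `prior_links` (input paths), `out` (output
#'   directory), `seed`, `pseudocount`, and for `search` also `beta`,
#'   `max_iter`, `stagnation`, `accuracy_floor`, `folds`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(command, options = list()) {
  command <- match.arg(command, c("simulate", "train", "infer", "explain",
                                  "evaluate", "search"))
  out_dir <- options$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(options$seed %||% 1L)
  log_msg <- function(...) message(sprintf("[reasonbn %s] ", command), ...)
  log_msg("seed = ", seed)
  artifacts <- switch(
    command,
    simulate = pipeline_simulate(options, out_dir, seed, log_msg),
    train = pipeline_train(options, out_dir, log_msg),
    infer = pipeline_infer(options, out_dir, log_msg, explain = FALSE),
    explain = pipeline_infer(options, out_dir, log_msg, explain = TRUE),
    evaluate = pipeline_evaluate(options, out_dir, log_msg),
    search = pipeline_search(options, out_dir, seed, log_msg)
  )
  invisible(artifacts)
}

pipeline_simulate <- function(options, out_dir, seed, log_msg) {
  spec <- generator_spec(
    n_findings = as.integer(options$n_findings %||% 49L),
    n_clinical = as.integer(options$n_clinical %||% 37L),
    n_informative = as.integer(options$n_informative %||%
                                 min(12L, as.integer(options$n_findings %||% 49L))),
    edge_density = as.numeric(options$edge_density %||% 0.1),
    effect_strength = as.numeric(options$effect_strength %||% 0.8),
    missing_rate = as.numeric(options$missing_rate %||% 0.1),
    seed = seed
  )
  n <- as.integer(options$n %||% 179L)
  ds <- simulate_dataset(spec, n)
  paths <- list(
    schema = file.path(out_dir, "schema.json"),
    cases = file.path(out_dir, "cases.csv"),
    reasons = file.path(out_dir, "reasons.json"),
    model = file.path(out_dir, "ground_truth_model.json"),
    prior_links = file.path(out_dir, "prior_links.json")
  )
  write_dataset(ds$cases, ds$model$structure$schema,
                paths$schema, paths$cases, paths$reasons)
  write_model(ds$model, paths$model)
  dx_children <- ds$model$structure$edges
  write_prior_links(dx_children$child[dx_children$parent ==
                                        ds$model$diagnosis],
                    paths$prior_links)
  log_msg(n, " cases over ", nrow(ds$model$structure$schema), " variables")
  paths
}

pipeline_load_cases <- function(options) {
  stopifnot(!is.null(options$schema), !is.null(options$cases))
  read_dataset(options$schema, options$cases, options$reasons)
}

pipeline_train <- function(options, out_dir, log_msg) {
  ds <- pipeline_load_cases(options)
  struct <- if (!is.null(options$model)) {
    read_model(options$model)$structure
  } else if (!is.null(options$prior_links)) {
    build_initial_structure(ds$schema, read_prior_links(options$prior_links))
  } else {
    bn_structure(ds$schema)
  }
  m <- fit_model(ds$cases, struct,
                 pseudocount = as.numeric(options$pseudocount %||% 1))
  path <- file.path(out_dir, "model.json")
  write_model(m, path)
  log_msg("fitted ", nrow(struct$edges), " edges on ", nrow(ds$cases),
          " cases")
  list(model = path)
}

pipeline_infer <- function(options, out_dir, log_msg, explain) {
  stopifnot(!is.null(options$model))
  model <- read_model(options$model)
  ds <- pipeline_load_cases(options)
  schema <- model$structure$schema
  dx <- model$diagnosis
  post_fun <- make_post_fun(model)
  prior <- post_fun(stats::setNames(character(0), character(0)))
  rows <- list()
  blocks <- list()
  for (i in seq_len(nrow(ds$cases))) {
    ev <- case_evidence(ds$cases[i, , drop = FALSE], schema$name, dx)
    post <- post_fun(ev)
    d_f <- names(post)[which.max(post)]
    rows[[i]] <- tibble::tibble(
      case_id = ds$cases$case_id[i], d_f = d_f,
      posterior = unname(post[d_f])
    )
    if (explain) {
      rs <- if (length(ev)) {
        derive_reasons_core(ev, post, prior, post_fun)
      } else {
        NULL
      }
      blocks[[i]] <- list(
        case_id = jsonlite::unbox(ds$cases$case_id[i]),
        d_f = jsonlite::unbox(d_f),
        posterior = jsonlite::unbox(unname(post[d_f])),
        prior = jsonlite::unbox(unname(prior[d_f])),
        reasons = if (is.null(rs) || nrow(rs$selected) == 0L) {
          list()
        } else {
          lapply(seq_len(nrow(rs$selected)), function(j) {
            e <- rs$selected$elements[[j]]
            list(elements = element_string(names(e), unname(e)),
                 p_d = jsonlite::unbox(rs$selected$p_d[j]),
                 influence = jsonlite::unbox(rs$selected$influence[j]))
          })
        }
      )
    }
  }
  out <- list()
  inf_path <- file.path(out_dir, "inferences.csv")
  readr::write_csv(dplyr::bind_rows(rows), inf_path)
  out$inferences <- inf_path
  if (explain) {
    ex_path <- file.path(out_dir, "explanations.json")
    jsonlite::write_json(blocks, ex_path, pretty = TRUE, digits = NA)
    out$explanations <- ex_path
  }
  log_msg(nrow(ds$cases), " cases processed")
  out
}

pipeline_evaluate <- function(options, out_dir, log_msg) {
  stopifnot(!is.null(options$model))
  model <- read_model(options$model)
  ds <- pipeline_load_cases(options)
  pseudocount <- as.numeric(options$pseudocount %||% 1)
  floor_ <- as.numeric(options$accuracy_floor %||% 0.70)
  train_eval <- evaluate_model(ds$cases, model$structure,
                               pseudocount = pseudocount,
                               accuracy_floor = floor_)
  rows <- list(eval_report_row("training", train_eval))
  report <- list(training = eval_report_json(train_eval))
  if (!is.null(options$test_cases)) {
    test <- read_dataset(options$schema, options$test_cases,
                         options$test_reasons)
    test_eval <- evaluate_model(test$cases, model$structure,
                                train_cases = ds$cases,
                                pseudocount = pseudocount,
                                accuracy_floor = floor_)
    rows <- c(rows, list(eval_report_row("test", test_eval)))
    report$test <- eval_report_json(test_eval)
  }
  tsv_path <- file.path(out_dir, "evaluation.tsv")
  readr::write_tsv(dplyr::bind_rows(rows), tsv_path)
  json_path <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(report, json_path, pretty = TRUE, digits = NA,
                       auto_unbox = TRUE)
  log_msg("training V = ", format_metric(train_eval$v))
  list(table = tsv_path, report = json_path)
}

# Table-2-style formatting: metrics to three decimals, accuracy to one
# decimal percent
format_metric <- function(x) sprintf("%.3f", round_half_up(x, 3))

eval_report_row <- function(split, ev) {
  tibble::tibble(
    split = split,
    f_measure = format_metric(ev$v_r),
    accuracy_pct = sprintf("%.1f", round_half_up(100 * ev$v_i, 1)),
    metric = format_metric(ev$v)
  )
}

eval_report_json <- function(ev) {
  list(v_r = ev$v_r, v_i = ev$v_i, v = ev$v, n_cases = ev$n_cases,
       short_circuited = ev$short_circuited)
}

pipeline_search <- function(options, out_dir, seed, log_msg) {
  ds <- pipeline_load_cases(options)
  if (is.null(ds$cases$reference_reasons)) {
    stop("the search command requires a reference-reasons file", call. = FALSE)
  }
  prior_links <- if (!is.null(options$prior_links)) {
    read_prior_links(options$prior_links)
  } else {
    NULL
  }
  initial <- build_initial_structure(ds$schema, prior_links)
  config <- search_config(
    beta = as.numeric(options$beta %||% 0.999),
    max_iterations = as.integer(options$max_iter %||% 10000L),
    stagnation_limit = as.integer(options$stagnation %||% 2500L),
    accuracy_floor = as.numeric(options$accuracy_floor %||% 0.70),
    folds = as.integer(options$folds %||% 5L),
    seed = seed,
    pseudocount = as.numeric(options$pseudocount %||% 1)
  )
  res <- run_search(ds$cases, initial, config)
  paths <- list(model = file.path(out_dir, "model.json"),
                trace = file.path(out_dir, "trace.tsv"),
                report = file.path(out_dir, "evaluation.json"))
  write_model(res$model, paths$model)
  readr::write_tsv(res$trace, paths$trace)
  jsonlite::write_json(
    list(training = eval_report_json(res$final_eval),
         cross_validated = eval_report_json(res$cv_eval),
         iterations = res$iterations, discarded = res$discarded,
         seed = config$seed, beta = config$beta),
    paths$report, pretty = TRUE, digits = NA, auto_unbox = TRUE
  )
  log_msg(res$iterations, " iterations; training V = ",
          format_metric(res$final_eval$v),
          if (res$discarded) " (model discarded)" else "")
  paths
}
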