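# Shared fixtures, built in code: tiny hand-specified networks and a
# seeded random-model generator with a brute-force enumeration oracle.

toy_schema <- function() {
  bn_schema(tibble::tibble(
    name = c("dx", "size", "cavitation"),
    kind = c("diagnosis", "imaging_finding", "imaging_finding"),
    states = list(c("cancer", "metastasis", "benign"),
                  c("small", "large"),
                  c("present", "absent"))
  ))
}

# collider topology: evidence on x_a is d-separated from dx while x_b is
# unobserved (propagation towards the diagnosis is blocked); dyadic CPT
# entries so blocked shifts are exactly zero in floating point
blocked_model <- function() {
  schema <- bn_schema(tibble::tibble(
    name = c("dx", "x_a", "x_b"),
    kind = c("diagnosis", "imaging_finding", "imaging_finding"),
    states = list(c("d1", "d2", "d3"), c("yes", "no"), c("yes", "no"))
  ))
  struct <- bn_structure(schema, tibble::tibble(
    parent = c("x_a", "dx"), child = c("x_b", "x_b")
  ))
  cpts <- list(
    dx = c(0.5, 0.25, 0.25),
    x_a = c(0.75, 0.25),
    x_b = array(c(0.25, 0.75, 0.5, 0.5, 0.125, 0.875,
                  0.75, 0.25, 0.5, 0.5, 0.625, 0.375),
                dim = c(2, 2, 3))
  )
  bn_model(struct, cpts)
}

# fully random model: random DAG (<= 2 parents), random positive CPTs
random_model <- function(seed, n_nodes = NULL, max_states = 4) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(3:8, 1)
  nms <- c("dx", paste0("v", seq_len(n_nodes - 1)))
  states <- lapply(seq_len(n_nodes), function(i) {
    paste0("s", seq_len(sample(2:max_states, 1)))
  })
  schema <- bn_schema(tibble::tibble(
    name = nms,
    kind = c("diagnosis", rep("imaging_finding", n_nodes - 1)),
    states = states
  ))
  edges <- list()
  for (i in seq(2, n_nodes)) {
    np <- sample(0:min(2, i - 1), 1)
    if (np > 0) {
      for (p in sample(seq_len(i - 1), np)) {
        edges[[length(edges) + 1]] <- c(nms[p], nms[i])
      }
    }
  }
  ed <- if (length(edges)) {
    tibble::tibble(parent = vapply(edges, `[`, character(1), 1),
                   child = vapply(edges, `[`, character(1), 2))
  } else {
    NULL
  }
  struct <- bn_structure(schema, ed)
  st <- stats::setNames(schema$states, schema$name)
  pl <- lapply(nms, function(nm) struct$edges$parent[struct$edges$child == nm])
  names(pl) <- nms
  cpts <- lapply(nms, function(nm) {
    fam <- c(nm, pl[[nm]])
    d <- lengths(st[fam])
    a <- array(stats::rgamma(prod(d), 1) + 0.05, dim = d,
               dimnames = stats::setNames(st[fam], fam))
    tot <- if (length(fam) > 1) colSums(a, dims = 1) else sum(a)
    if (length(fam) > 1) sweep(a, seq_along(fam)[-1], tot, "/") else a / tot
  })
  names(cpts) <- nms
  bn_model(struct, cpts)
}

random_evidence <- function(model, n_items = NULL, exclude = character(0)) {
  nms <- setdiff(model$structure$schema$name,
                 c(model$diagnosis, exclude))
  if (is.null(n_items)) n_items <- sample(0:length(nms), 1)
  if (n_items == 0) return(NULL)
  st <- stats::setNames(model$structure$schema$states,
                        model$structure$schema$name)
  vars <- sample(nms, n_items)
  stats::setNames(
    vapply(vars, function(v) sample(st[[v]], 1), character(1)), vars
  )
}

# oracle: condition the fully enumerated joint (built from
# joint_probability, not from the propagation engine)
brute_posterior <- function(model, evidence, query = model$diagnosis) {
  st <- stats::setNames(model$structure$schema$states,
                        model$structure$schema$name)
  grid <- expand.grid(st, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  g <- grid[keep, , drop = FALSE]
  p <- vapply(seq_len(nrow(g)), function(i) {
    joint_probability(model, as.list(g[i, , drop = FALSE]))
  }, numeric(1))
  agg <- tapply(p, factor(g[[query]], levels = st[[query]]), sum)
  agg[is.na(agg)] <- 0
  out <- as.numeric(agg) / sum(agg)
  names(out) <- st[[query]]
  out
}

# small strongly-informative dataset used by search/evaluation tests
recovery_dataset <- function(n = 400, seed = 7, n_findings = 6,
                             effect_strength = 0.85) {
  spec <- generator_spec(
    n_findings = n_findings, n_clinical = 0, states_min = 2, states_max = 3,
    n_informative = n_findings, edge_density = 0,
    effect_strength = effect_strength, missing_rate = 0, seed = seed
  )
  simulate_dataset(spec, n)
}

local_tempdir <- function() {
  d <- tempfile("reasonbn-test-")
  dir.create(d, recursive = TRUE)
  d
}
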