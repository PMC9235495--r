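#' Prior specification for a single parameter
#'
#' Normal priors, optionally constrained to a half-line.  The benchmark
#' systems use diffuse `N(0, 10)` priors throughout, informative `N(m, 1)`
#' priors for some signaling parameters, and sign constraints that encode
#' edge types: positive weights for activating ("increase") edges, negative
#' for repressing ("decrease") ones.
#'
#' @param location prior mean.
#' @param scale prior standard deviation (> 0).
#' @param constraint `"none"`, `"positive"` or `"negative"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(location = 0, scale = 10,
                       constraint = c("none", "positive", "negative")) {
  constraint <- match.arg(constraint)
  if (!is.numeric(scale) || scale <= 0) stop("prior scale must be > 0")
  structure(list(family = "normal", location = location, scale = scale,
                 constraint = constraint), class = "prior_spec")
}

node_families <- c("gaussian_linear", "bernoulli_logit", "gamma",
                   "hill_sigmoid", "point_mass")

#' Per-node parametric specification
#'
#' Families:
#' \describe{
#'   \item{gaussian_linear}{`v = b0 + sum(b_p * parent_p) + N(0, sigma)` —
#'     relative expression / RT-PCR-style measurements.}
#'   \item{bernoulli_logit}{`P(v = 1) = logistic(b0 + sum(b_p * parent_p))`
#'     — on/off regulatory states.}
#'   \item{gamma}{log-link `mean = exp(b0 + sum(b_p * parent_p))`, shape
#'     parameter `shape` — positive fluorescent-reporter intensities.}
#'   \item{hill_sigmoid}{`v ~ N(scale_cap * logistic(b0 + sum(b_p *
#'     parent_p)), sigma)` — saturating Hill-type kinetics capped at
#'     `scale_cap` (default 100, the initial molecule count).  With this
#'     sign convention a positively constrained weight increases the mean,
#'     matching activating edges.}
#'   \item{point_mass}{constant at `value`; used internally by model
#'     mutilation for intervened nodes.}
#' }
#'
#' Parameter names are `b0` (intercept), `b_<parent>` (one weight per
#' parent), plus `sigma` (gaussian_linear, hill_sigmoid), `shape` (gamma)
#' or `value` (point_mass).  `priors` defaults to diffuse `N(0, 10)` on
#' location parameters and positive-constrained `N(0, 10)` on dispersion
#' parameters; entries can be overridden individually.
#'
#' @param name node label.
#' @param family one of the families above.
#' @param parents ordered character vector of parent labels.
#' @param priors named list of [prior_spec()] overrides.
#' @param scale_cap saturation level for `hill_sigmoid`.
#' @return An object of class `node_spec`.
#' @export
node_spec <- function(name, family, parents = character(), priors = list(),
                      scale_cap = 100) {
  family <- match.arg(family, node_families)
  pn <- param_names(family, parents)
  base <- lapply(pn, function(p) {
    if (p %in% c("sigma", "shape")) prior_spec(0, 10, "positive")
    else prior_spec(0, 10, "none")
  })
  names(base) <- pn
  bad <- setdiff(names(priors), pn)
  if (length(bad)) {
    stop("unknown parameter(s) in priors for ", name, ": ",
         paste(bad, collapse = ", "))
  }
  base[names(priors)] <- priors
  structure(list(name = name, family = family,
                 parents = as.character(parents), priors = base,
                 scale_cap = scale_cap),
            class = "node_spec")
}

param_names <- function(family, parents) {
  w <- if (length(parents)) paste0("b_", parents) else character()
  switch(family,
    gaussian_linear = c("b0", w, "sigma"),
    bernoulli_logit = c("b0", w),
    gamma = c("b0", w, "shape"),
    hill_sigmoid = c("b0", w, "sigma"),
    point_mass = "value")
}

#' Causal latent variable model
#'
#' Couples an explicit-latent DAG with one [node_spec()] per node.  The
#' joint factorizes as the product of each node's conditional given its
#' parents; latent nodes are sampled during generation and fitting but
#' never appear in returned datasets.
#'
#' @param graph an explicit-latent `mixed_graph`.
#' @param node_specs list of [node_spec()], one per graph node.
#' @return An object of class `causal_lvm`.
#' @export
causal_lvm <- function(graph, node_specs) {
  names(node_specs) <- vapply(node_specs, function(s) s$name, "")
  lvm <- structure(list(graph = graph, node_specs = node_specs),
                   class = "causal_lvm")
  issues <- validate_model(lvm)
  if (length(issues)) stop("invalid model:\n  ", paste(issues, collapse = "\n  "))
  lvm
}

#' @export
print.causal_lvm <- function(x, ...) {
  cat(sprintf("<causal_lvm: %d observed + %d latent nodes>\n",
              length(observed_nodes(x$graph)), length(x$graph$latent)))
  for (s in x$node_specs) {
    cat(sprintf("  %s%s ~ %s(%s)\n", s$name,
                if (s$name %in% x$graph$latent) "*" else "",
                s$family, paste(s$parents, collapse = ", ")))
  }
  invisible(x)
}

#' Structural validation of a causal LVM
#'
#' Checks that node specs cover the graph exactly, parent lists agree with
#' the graph, families are known, priors cover each family's parameter set
#' with positive scales, and dispersion parameters carry a positivity
#' constraint.  Returns a character vector of violations (empty when
#' valid) rather than raising, so corrupted specifications can be
#' enumerated.
#'
#' @param lvm a `causal_lvm` (or an un-validated list with the same
#'   fields).
#' @return Character vector of violation messages.
#' @export
validate_model <- function(lvm) {
  issues <- character()
  g <- lvm$graph
  specs <- lvm$node_specs
  if (!setequal(names(specs), g$nodes)) {
    issues <- c(issues, paste("node specs do not cover graph nodes:",
                              paste(symdiff(names(specs), g$nodes),
                                    collapse = ", ")))
  }
  for (s in specs) {
    if (!s$name %in% g$nodes) next
    if (!s$family %in% node_families) {
      issues <- c(issues, paste0(s$name, ": unknown family '", s$family, "'"))
      next
    }
    gp <- graph_parents(g, s$name)
    if (!setequal(s$parents, gp)) {
      issues <- c(issues, paste0(s$name, ": spec parents {",
                                 paste(s$parents, collapse = ","),
                                 "} != graph parents {",
                                 paste(gp, collapse = ","), "}"))
    }
    pn <- param_names(s$family, s$parents)
    if (!setequal(names(s$priors), pn)) {
      issues <- c(issues, paste0(s$name, ": priors cover {",
                                 paste(names(s$priors), collapse = ","),
                                 "} but family needs {",
                                 paste(pn, collapse = ","), "}"))
      next
    }
    for (p in names(s$priors)) {
      pr <- s$priors[[p]]
      if (!is.numeric(pr$scale) || pr$scale <= 0) {
        issues <- c(issues, paste0(s$name, "/", p, ": prior scale not > 0"))
      }
      if (p %in% c("sigma", "shape") && !identical(pr$constraint, "positive")) {
        issues <- c(issues, paste0(s$name, "/", p,
                                   ": dispersion parameter must be ",
                                   "constrained positive"))
      }
    }
    if (s$family == "hill_sigmoid" &&
        (!is.numeric(s$scale_cap) || s$scale_cap <= 0)) {
      issues <- c(issues, paste0(s$name, ": scale_cap must be > 0"))
    }
  }
  issues
}

symdiff <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Draw a parameter assignment from the priors
#'
#' Samples every parameter from its prior truncated to its sign
#' constraint, giving the "randomly selected true values" used to define a
#' benchmark system's ground truth.
#'
#' @param lvm a `causal_lvm`.
#' @param seed integer seed.
#' @return Named list (one element per node) of named numeric parameter
#'   vectors.
#' @export
draw_parameters <- function(lvm, seed) {
  set.seed(derive_seed(seed, "draw_parameters"))
  out <- list()
  for (s in lvm$node_specs) {
    th <- vapply(names(s$priors), function(p) {
      pr <- s$priors[[p]]
      rtrunc_normal(1, pr$location, pr$scale, pr$constraint)
    }, 0)
    out[[s$name]] <- th
  }
  out
}

rtrunc_normal <- function(n, location, scale, constraint) {
  if (constraint == "none") return(stats::rnorm(n, location, scale))
  lo <- if (constraint == "positive") 0 else -Inf
  hi <- if (constraint == "negative") 0 else Inf
  plo <- stats::pnorm(lo, location, scale)
  phi <- stats::pnorm(hi, location, scale)
  stats::qnorm(stats::runif(n, plo, phi), location, scale)
}

derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

check_theta <- function(lvm, theta) {
  for (s in lvm$node_specs) {
    pn <- param_names(s$family, s$parents)
    miss <- setdiff(pn, names(theta[[s$name]]))
    if (length(miss)) {
      stop("parameter assignment incomplete for node ", s$name,
           ": missing ", paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Low-level family sampler and analytic moments
#'
#' `sample_node()` draws `n` values of a node given its parents' columns
#' in `data`; `node_moments()` returns the analytic mean and variance of a
#' node given fixed parent values — the oracle for the family moment
#' checks.
#'
#' @param spec a [node_spec()].
#' @param theta named numeric parameter vector for the node.
#' @param data data frame holding the parent columns.
#' @param n number of draws.
#' @param parent_values named numeric vector of fixed parent values.
#' @return `sample_node()` a numeric vector of length `n`;
#'   `node_moments()` a named vector `c(mean =, var =)`.
#' @name sample_node
NULL

node_eta <- function(spec, theta, data) {
  eta <- rep(theta[["b0"]], nrow(data))
  for (p in spec$parents) eta <- eta + theta[[paste0("b_", p)]] * data[[p]]
  eta
}

#' @rdname sample_node
#' @export
sample_node <- function(spec, theta, data, n) {
  switch(spec$family,
    gaussian_linear = stats::rnorm(n, node_eta(spec, theta, data),
                                   theta[["sigma"]]),
    bernoulli_logit = stats::rbinom(n, 1,
                                    stats::plogis(node_eta(spec, theta, data))),
    gamma = {
      mu <- exp(pmin(node_eta(spec, theta, data), 30))
      stats::rgamma(n, shape = theta[["shape"]],
                    rate = theta[["shape"]] / mu)
    },
    hill_sigmoid = stats::rnorm(
      n, spec$scale_cap * stats::plogis(node_eta(spec, theta, data)),
      theta[["sigma"]]),
    point_mass = rep(theta[["value"]], n))
}

#' @rdname sample_node
#' @export
node_moments <- function(spec, theta, parent_values) {
  # analytic mean/variance given *fixed* parent values
  data <- tibble::as_tibble(as.list(parent_values))
  if (!ncol(data)) data <- tibble::tibble(.rows = 1)
  eta <- node_eta(spec, theta, data)
  switch(spec$family,
    gaussian_linear = c(mean = eta, var = theta[["sigma"]]^2),
    bernoulli_logit = {
      p <- stats::plogis(eta)
      c(mean = p, var = p * (1 - p))
    },
    gamma = {
      mu <- exp(eta)
      c(mean = mu, var = mu^2 / theta[["shape"]])
    },
    hill_sigmoid = c(mean = spec$scale_cap * stats::plogis(eta),
                     var = theta[["sigma"]]^2),
    point_mass = c(mean = theta[["value"]], var = 0))
}

#' Generative sampling from a causal LVM
#'
#' Ancestral sampling in topological order under a fixed parameter
#' assignment.  Latent columns are generated and then dropped from the
#' returned dataset (set `keep_latent = TRUE` to retain them for
#' debugging).  `sample_interventional()` samples from the mutilated model
#' with the intervened columns held at their `do` values; with equal seeds
#' it returns exactly the draws of `sample_observational()` applied to
#' [mutilate_model()] output.
#'
#' @param lvm a `causal_lvm`.
#' @param theta parameter assignment as returned by [draw_parameters()].
#' @param n number of replicates.
#' @param seed integer seed.
#' @param keep_latent keep latent columns (default drop).
#' @return A tibble with one column per observed node and attribute
#'   `provenance` (`"observational"` or `"interventional"`).
#' @export
sample_observational <- function(lvm, theta, n, seed, keep_latent = FALSE) {
  check_theta(lvm, theta)
  set.seed(derive_seed(seed, "ancestral"))
  ord <- topological_sort(lvm$graph)
  data <- tibble::tibble(.rows = n)
  for (v in ord) {
    data[[v]] <- sample_node(lvm$node_specs[[v]], theta[[v]], data, n)
  }
  if (!keep_latent) data <- data[, setdiff(ord, lvm$graph$latent)]
  attr(data, "provenance") <- "observational"
  data
}

#' @rdname sample_observational
#' @param do named numeric vector of intervention values (observed nodes
#'   only).
#' @export
sample_interventional <- function(lvm, theta, do, n, seed,
                                  keep_latent = FALSE) {
  mut <- mutilate_model(lvm, do)
  th <- theta
  for (v in names(do)) th[[v]] <- c(value = unname(do[[v]]))
  out <- sample_observational(mut, th, n, seed, keep_latent)
  attr(out, "provenance") <- "interventional"
  attr(out, "do") <- do
  out
}

#' Model mutilation
#'
#' Returns the model of the intervened system: each target's parents are
#' severed and its family replaced by a point mass at the intervention
#' value.  The input model is unmodified.  Intervening on a latent node is
#' refused: targets must be observed.
#'
#' @param lvm a `causal_lvm`.
#' @param do named numeric vector of intervention values.
#' @return A `causal_lvm`.
#' @export
mutilate_model <- function(lvm, do) {
  if (!length(do)) return(lvm)
  tg <- names(do)
  check_nodes_known(tg, lvm$graph$nodes, "mutilate_model()")
  lat <- intersect(tg, lvm$graph$latent)
  if (length(lat)) {
    stop("cannot intervene on latent node(s): ", paste(lat, collapse = ", "),
         " (targets must be observed)")
  }
  g <- mutilate_incoming(lvm$graph, tg)
  specs <- lvm$node_specs
  for (v in tg) {
    sp <- node_spec(v, "point_mass",
                    priors = list(value = prior_spec(do[[v]], 1e-6)))
    sp$priors$value$location <- do[[v]]
    specs[[v]] <- sp
  }
  out <- structure(list(graph = g, node_specs = specs),
                   class = "causal_lvm")
  out
}

#' Serialize a model configuration
#'
#' Writes/reads the full model description (nodes, families, parents,
#' priors, constraints, latent flags, edges) as JSON.
#'
#' @param lvm a `causal_lvm`.
#' @param path file path.
#' @return `lvm_from_json()` returns a `causal_lvm`; `lvm_to_json()` the
#'   JSON string, invisibly when written to a file.
#' @export
lvm_to_json <- function(lvm, path = NULL) {
  obj <- list(
    nodes = as.list(lvm$graph$nodes),
    latent = as.list(lvm$graph$latent),
    directed = apply(lvm$graph$di, 1, function(r) list(r[[1]], r[[2]])),
    specs = lapply(unname(lvm$node_specs), function(s) {
      list(name = s$name, family = s$family, parents = as.list(s$parents),
           scale_cap = s$scale_cap,
           priors = lapply(s$priors, function(p)
             list(location = p$location, scale = p$scale,
                  constraint = p$constraint)))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname lvm_to_json
#' @export
lvm_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  di <- if (length(obj$directed)) {
    do.call(rbind, lapply(obj$directed, function(e)
      c(e[[1]], e[[2]])))
  } else NULL
  g <- mixed_graph(unlist(obj$nodes), directed = di,
                   latent = unlist(obj$latent))
  specs <- lapply(obj$specs, function(s) {
    node_spec(s$name, s$family, unlist(s$parents),
              priors = lapply(s$priors, function(p)
                prior_spec(p$location, p$scale, p$constraint)),
              scale_cap = s$scale_cap)
  })
  causal_lvm(g, specs)
}

#' Write or read a dataset with its provenance sidecar
#'
#' The dataset goes to `<path>` as CSV; the provenance tag, intervention
#' map (if any) and column names go to `<path>.json`.
#'
#' @param data a dataset tibble.
#' @param path CSV file path.
#' @return `read_dataset()` returns the tibble with provenance attributes
#'   restored.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  meta <- list(provenance = attr(data, "provenance") %||% "unknown",
               columns = names(data))
  if (!is.null(attr(data, "do"))) meta$do <- as.list(attr(data, "do"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  data <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    attr(data, "provenance") <- meta$provenance
    if (!is.null(meta$do)) attr(data, "do") <- unlist(meta$do)
  }
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
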