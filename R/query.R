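#' Estimate an identifiable causal query from a trained LVM
#'
#' The mutilation + posterior-predictive estimator.  First the query is
#' checked for identifiability on the latent projection of the model's
#' graph; a non-identifiable query is refused (a typed condition carrying
#' the identification result) unless `force_nonidentifiable = TRUE`, which
#' exists solely to demonstrate the bias of non-identifiable estimation.
#' The model is then mutilated at the targets, and for each of `s_draws`
#' posterior parameter draws all variables (latent and observed) are
#' sampled `l_draws` times in topological order; the pooled outcome draws
#' estimate `P(Y|do(x'))` and their mean `E[Y|do(x')]`.
#'
#' @param trained a `trained_lvm`.
#' @param query a [causal_query()].
#' @param s_draws number of posterior parameter draws used.
#' @param l_draws ancestral samples per parameter draw.
#' @param seed integer seed.
#' @param force_nonidentifiable proceed even when the query is not
#'   identifiable (for demonstration only).
#' @return An object of class `query_estimate`: pooled draws (tibble with
#'   `.theta_draw`, `.rep` and one column per outcome), per-outcome
#'   `expectation`, kernel-density summaries on a 512-point grid, and
#'   metadata including the identification result.
#' @export
estimate_query <- function(trained, query, s_draws = 500, l_draws = 20,
                           seed = 1, force_nonidentifiable = FALSE) {
  lvm <- trained$lvm
  if (s_draws < 1 || l_draws < 1) stop("s_draws and l_draws must be >= 1")
  check_nodes_known(c(names(query$targets), query$outcomes),
                    observed_nodes(lvm$graph), "estimate_query()")
  admg <- latent_project(lvm$graph)
  ident <- identify(admg, query)
  if (ident$status != "identifiable" && !force_nonidentifiable) {
    rlang::abort(
      paste0("query ", format_query(query), " is not identifiable from ",
             "the observational distribution; refusing to estimate"),
      class = "dolvm_not_identifiable", identify_result = ident)
  }
  mut <- mutilate_model(lvm, query$targets)
  set.seed(derive_seed(seed, "estimate_query"))
  total <- nrow(trained$draws)
  idx <- if (s_draws <= total) {
    round(seq(1, total, length.out = s_draws))
  } else {
    sample.int(total, s_draws, replace = TRUE)
  }
  draws <- purrr::map_dfr(seq_along(idx), function(s) {
    th <- theta_from_draw(trained, idx[s])
    for (v in names(query$targets)) {
      th[[v]] <- c(value = unname(query$targets[[v]]))
    }
    d <- sample_observational(mut, th, n = l_draws,
                              seed = sample.int(2^31 - 2, 1))
    tibble::tibble(.theta_draw = s, .rep = seq_len(l_draws)) |>
      dplyr::bind_cols(d[, query$outcomes, drop = FALSE])
  })
  new_query_estimate(draws, query, ident,
                     meta = list(s_draws = length(idx), l_draws = l_draws,
                                 seed = seed,
                                 method = ident$method,
                                 forced = ident$status != "identifiable"))
}

format_query <- function(query) {
  paste0(if (query$form == "expectation") "E[" else "P(",
         paste(query$outcomes, collapse = ","), " | do(",
         paste(names(query$targets), "=", query$targets, collapse = ", "),
         ")", if (query$form == "expectation") "]" else ")")
}

new_query_estimate <- function(draws, query, ident, meta) {
  expectation <- vapply(query$outcomes,
                        function(v) mean(draws[[v]]), 0)
  dens <- purrr::map_dfr(query$outcomes, function(v) {
    x <- draws[[v]]
    if (length(unique(x)) < 2) {
      return(tibble::tibble(outcome = v, x = unique(x), y = Inf))
    }
    d <- stats::density(x, bw = "nrd0", n = 512, cut = 3)
    tibble::tibble(outcome = v, x = d$x, y = d$y)
  })
  per_theta <- draws |>
    dplyr::group_by(.data$.theta_draw) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(query$outcomes), mean),
                     .groups = "drop")
  structure(list(draws = draws, expectation = expectation,
                 density = dens, per_theta = per_theta,
                 query = query, identify_result = ident, meta = meta),
            class = "query_estimate")
}

#' @export
print.query_estimate <- function(x, ...) {
  cat("<query_estimate> ", format_query(x$query), "\n", sep = "")
  cat(sprintf("  method: %s, S = %d, L = %d, pooled draws = %d\n",
              x$meta$method %||% "truth", x$meta$s_draws, x$meta$l_draws,
              nrow(x$draws)))
  for (v in names(x$expectation)) {
    cat(sprintf("  E[%s | do] = %.4f (sd of draws %.4f)\n", v,
                x$expectation[[v]], stats::sd(x$draws[[v]])))
  }
  invisible(x)
}

#' @export
tidy.query_estimate <- function(x, ...) {
  purrr::map_dfr(names(x$expectation), function(v) {
    tibble::tibble(outcome = v,
                   expectation = x$expectation[[v]],
                   sd = stats::sd(x$draws[[v]]),
                   mc_se = stats::sd(x$per_theta[[v]]) /
                     sqrt(nrow(x$per_theta)),
                   n_draws = nrow(x$draws))
  })
}

#' @export
glance.query_estimate <- function(x, ...) {
  tibble::tibble(s_draws = x$meta$s_draws, l_draws = x$meta$l_draws,
                 method = x$meta$method %||% NA_character_,
                 forced = isTRUE(x$meta$forced))
}

#' Density and per-draw curve plots for a query estimate
#'
#' Pooled posterior-predictive interventional density per outcome; with
#' `per_theta = TRUE`, one thin curve per posterior parameter draw (the
#' per-draw sampling-variability display of the benchmark plots).
#'
#' @param object a `query_estimate`.
#' @param per_theta overlay per-parameter-draw densities.
#' @param max_curves cap on the number of thin curves.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.query_estimate <- function(object, per_theta = FALSE,
                                    max_curves = 50, ...) {
  p <- ggplot2::ggplot(object$density,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::facet_wrap(~outcome, scales = "free") +
    ggplot2::labs(x = "outcome value", y = "density",
                  title = format_query(object$query))
  if (per_theta) {
    keep <- unique(round(seq(1, max(object$draws$.theta_draw),
                             length.out = max_curves)))
    thin <- object$draws |>
      dplyr::filter(.data$.theta_draw %in% keep) |>
      tidyr::pivot_longer(dplyr::all_of(object$query$outcomes),
                          names_to = "outcome", values_to = "value")
    p <- p + ggplot2::geom_line(
      data = thin |>
        dplyr::group_by(.data$.theta_draw, .data$outcome) |>
        dplyr::reframe({
          d <- stats::density(.data$value, n = 128)
          tibble::tibble(x = d$x, y = d$y)
        }),
      ggplot2::aes(group = .data$.theta_draw),
      alpha = 0.2, linewidth = 0.3)
  }
  p
}

#' Simulation ground truth for a causal query
#'
#' The same estimator with the posterior replaced by a point mass at the
#' true parameters: ancestral sampling of the mutilated model under
#' `theta_true`, averaged over `n` draws.
#'
#' @param lvm a `causal_lvm`.
#' @param theta_true complete parameter assignment.
#' @param query a [causal_query()].
#' @param n number of interventional samples.
#' @param seed integer seed.
#' @return A `query_estimate`.
#' @export
ground_truth_query <- function(lvm, theta_true, query, n = 10000, seed = 1) {
  check_theta(lvm, theta_true)
  d <- sample_interventional(lvm, theta_true, query$targets, n = n,
                             seed = derive_seed(seed, "truth"))
  draws <- tibble::tibble(.theta_draw = 1L, .rep = seq_len(n)) |>
    dplyr::bind_cols(d[, query$outcomes, drop = FALSE])
  new_query_estimate(draws, query, ident = NULL,
                     meta = list(s_draws = 1L, l_draws = n, seed = seed,
                                 method = "truth", forced = FALSE))
}

# ---------------------------------------------------------------------------
# plug-in adjustment estimators, independent of the MCMC machinery

looks_discrete <- function(...) {
  cols <- list(...)
  all(vapply(cols, function(x) length(unique(x)) <= 10 &&
               all(abs(x - round(x)) < 1e-9), TRUE))
}

#' Empirical joint probability table
#'
#' Relative frequencies of the value combinations of `cols` — the discrete
#' plug-in's input to [evaluate_estimand()].
#'
#' @param data a data frame.
#' @param cols columns to tabulate.
#' @return Tibble over `cols` with a `p` column summing to 1.
#' @export
empirical_joint <- function(data, cols) {
  data |>
    dplyr::count(dplyr::across(dplyr::all_of(cols)), name = ".n") |>
    dplyr::mutate(p = .data$.n / sum(.data$.n)) |>
    dplyr::select(-".n")
}

#' Front-door plug-in estimator
#'
#' Evaluates the front-door adjustment `sum_z P(z|x') sum_x E[Y|x,z] P(x)`
#' directly from observational data, with no use of the Bayesian machinery
#' — the independent estimator used to validate the mutilation-based one.
#' Discrete data (all three variables on at most 10 integer levels) are
#' handled exactly via the empirical joint table; continuous data use a
#' quadratic-with-interaction regression for `E[Y|x,z]`, a Gaussian
#' conditional fit for `P(z|x')`, and Monte-Carlo averaging.  A standard
#' error is attached via a nonparametric bootstrap over rows.
#'
#' @param data observational dataset.
#' @param x_node,y_node,z_node column names of cause, effect, mediator.
#' @param x_value intervention value.
#' @param n_boot bootstrap replicates for the standard error (0 to skip).
#' @param mc_draws Monte-Carlo draws for the continuous case.
#' @param seed integer seed.
#' @return One-row tibble: `estimate`, `se`, `n`, `method`.
#' @export
plugin_frontdoor <- function(data, x_node, y_node, z_node, x_value,
                             n_boot = 30, mc_draws = 2000, seed = 1) {
  stopifnot(all(c(x_node, y_node, z_node) %in% names(data)))
  set.seed(derive_seed(seed, "plugin_fd"))
  est_fun <- function(d) {
    if (looks_discrete(d[[x_node]], d[[y_node]], d[[z_node]])) {
      if (!any(d[[x_node]] == x_value)) {
        stop("P(x, z) > 0 violated: no observations at x' = ", x_value)
      }
      joint <- empirical_joint(d, c(x_node, y_node, z_node))
      e <- frontdoor_estimand(x_node, y_node, z_node)
      tab <- evaluate_estimand(e, joint,
                               stats::setNames(x_value, x_node), y_node)
      return(sum(tab[[y_node]] * tab$prob))
    }
    fy <- stats::lm(stats::reformulate(
      c(x_node, z_node, paste0(x_node, ":", z_node),
        paste0("I(", x_node, "^2)"), paste0("I(", z_node, "^2)")),
      response = y_node), data = d)
    fz <- stats::lm(stats::reformulate(c(x_node, paste0("I(", x_node, "^2)")),
                                       response = z_node), data = d)
    sdz <- stats::sigma(fz)
    if (!is.finite(sdz) || sdz <= 0) {
      stop("P(x, z) > 0 violated: degenerate mediator distribution")
    }
    muz <- stats::predict(fz, stats::setNames(list(x_value), x_node))
    zb <- stats::rnorm(mc_draws, muz, sdz)
    xs <- d[[x_node]]
    if (length(xs) > 400) xs <- sample(xs, 400)
    grid <- tidyr::expand_grid(!!x_node := xs, !!z_node := zb)
    mean(stats::predict(fy, grid))
  }
  est <- est_fun(data)
  se <- NA_real_
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      est_fun(data[sample.int(nrow(data), replace = TRUE), ])
    }, 0)
    se <- stats::sd(bs)
  }
  tibble::tibble(estimate = est, se = se, n = nrow(data),
                 method = "plugin_frontdoor")
}

#' Back-door plug-in estimator
#'
#' Evaluates `sum_z E[Y|x',z] P(z)`: exact empirical tables in the discrete
#' case, otherwise a quadratic regression of the outcome on cause and
#' adjustment variables averaged over the empirical adjustment
#' distribution at `x'`.
#'
#' @inheritParams plugin_frontdoor
#' @param z_set character vector of adjustment columns (may be empty, in
#'   which case the estimator is the conditional-mean regression at `x'`).
#' @return One-row tibble: `estimate`, `se`, `n`, `method`.
#' @export
plugin_backdoor <- function(data, x_node, y_node, z_set, x_value,
                            n_boot = 30, seed = 1) {
  stopifnot(all(c(x_node, y_node, z_set) %in% names(data)))
  set.seed(derive_seed(seed, "plugin_bd"))
  est_fun <- function(d) {
    if (do.call(looks_discrete,
                unname(as.list(d[c(x_node, y_node, z_set)])))) {
      joint <- empirical_joint(d, c(x_node, y_node, z_set))
      e <- backdoor_estimand(x_node, y_node, z_set)
      tab <- evaluate_estimand(e, joint,
                               stats::setNames(x_value, x_node), y_node)
      return(sum(tab[[y_node]] * tab$prob))
    }
    terms <- c(x_node, paste0("I(", x_node, "^2)"), z_set,
               if (length(z_set)) paste0(x_node, ":", z_set))
    fy <- stats::lm(stats::reformulate(terms, response = y_node), data = d)
    nd <- d[, z_set, drop = FALSE]
    nd[[x_node]] <- x_value
    mean(stats::predict(fy, nd))
  }
  est <- est_fun(data)
  se <- NA_real_
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      est_fun(data[sample.int(nrow(data), replace = TRUE), ])
    }, 0)
    se <- stats::sd(bs)
  }
  tibble::tibble(estimate = est, se = se, n = nrow(data),
                 method = "plugin_backdoor")
}

#' Exact interventional moments for linear-Gaussian models
#'
#' Path-coefficient propagation on the mutilated graph: means and the full
#' covariance are pushed through the structural equations in topological
#' order, giving the exact interventional mean and variance of each
#' outcome.  Every node family must be `gaussian_linear` (intervened nodes
#' become point masses).
#'
#' @param lvm a `causal_lvm` with all-Gaussian nodes.
#' @param theta complete parameter assignment.
#' @param query a [causal_query()].
#' @return Tibble with columns `outcome`, `mean`, `variance`.
#' @export
closed_form_linear_gaussian <- function(lvm, theta, query) {
  fams <- vapply(lvm$node_specs, function(s) s$family, "")
  if (!all(fams %in% c("gaussian_linear", "point_mass"))) {
    stop("closed_form_linear_gaussian() requires all gaussian_linear nodes (got ",
         paste(unique(setdiff(fams, "gaussian_linear")), collapse = ", "), ")")
  }
  check_theta(lvm, theta)
  mut <- mutilate_model(lvm, query$targets)
  th <- theta
  for (v in names(query$targets)) th[[v]] <- c(value = query$targets[[v]])
  ord <- topological_sort(mut$graph)
  k <- length(ord)
  mu <- stats::setNames(numeric(k), ord)
  Sig <- matrix(0, k, k, dimnames = list(ord, ord))
  for (v in ord) {
    s <- mut$node_specs[[v]]
    if (s$family == "point_mass") {
      mu[v] <- th[[v]][["value"]]
      next
    }
    pa <- s$parents
    b <- if (length(pa)) th[[v]][paste0("b_", pa)] else numeric()
    mu[v] <- th[[v]][["b0"]] + sum(b * mu[pa])
    prior <- ord[seq_len(match(v, ord) - 1)]
    for (u in prior) {
      Sig[v, u] <- Sig[u, v] <- sum(b * Sig[pa, u])
    }
    Sig[v, v] <- sum((b %o% b) * Sig[pa, pa, drop = FALSE]) +
      th[[v]][["sigma"]]^2
  }
  tibble::tibble(outcome = query$outcomes,
                 mean = unname(mu[query$outcomes]),
                 variance = unname(diag(Sig)[query$outcomes]))
}

#' Serialize a query estimate
#'
#' Writes metadata + expectations as JSON, the pooled draws and the
#' density grid as CSV.
#'
#' @param estimate a `query_estimate`.
#' @param stem path stem; writes `<stem>.json`, `<stem>_draws.csv`,
#'   `<stem>_density.csv`.
#' @return Invisibly, the paths written.
#' @export
export_query_estimate <- function(estimate, stem) {
  js <- paste0(stem, ".json")
  jsonlite::write_json(list(
    query = list(targets = as.list(estimate$query$targets),
                 outcomes = estimate$query$outcomes,
                 form = estimate$query$form),
    expectation = as.list(estimate$expectation),
    meta = estimate$meta), js, auto_unbox = TRUE, digits = NA)
  utils::write.csv(estimate$draws, paste0(stem, "_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(estimate$density, paste0(stem, "_density.csv"),
                   row.names = FALSE)
  invisible(c(js, paste0(stem, "_draws.csv"), paste0(stem, "_density.csv")))
}
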