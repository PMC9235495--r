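#' Generate JAGS model code for a causal LVM
#'
#' Emits the model's joint density: one likelihood line per node per
#' replicate, with per-replicate latent variables sampled alongside the
#' parameters, and one prior line per parameter (sign constraints become
#' truncation).  Gamma nodes use a log link with the linear predictor
#' clamped at 30 to keep the mean finite during early adaptation.
#'
#' @param lvm a `causal_lvm`.
#' @return Character scalar of JAGS model code.
#' @export
jags_model_code <- function(lvm) {
  ord <- topological_sort(lvm$graph)
  lik <- character()
  pri <- character()
  for (v in ord) {
    s <- lvm$node_specs[[v]]
    eta <- paste(c(jp("b0", v),
                   vapply(s$parents, function(p)
                     paste0(jp("b", v, p), " * ", p, "[i]"), "")),
                 collapse = " + ")
    lik <- c(lik, switch(s$family,
      gaussian_linear = c(
        sprintf("    mu_%s[i] <- %s", v, eta),
        sprintf("    %s[i] ~ dnorm(mu_%s[i], prec_%s)", v, v, v)),
      bernoulli_logit = c(
        sprintf("    p_%s[i] <- ilogit(%s)", v, eta),
        sprintf("    %s[i] ~ dbern(p_%s[i])", v, v)),
      gamma = c(
        sprintf("    eta_%s[i] <- %s", v, eta),
        sprintf("    mu_%s[i] <- exp(ifelse(eta_%s[i] > 30, 30, eta_%s[i]))",
                v, v, v),
        sprintf("    %s[i] ~ dgamma(%s, %s / mu_%s[i])",
                v, jp("shape", v), jp("shape", v), v)),
      hill_sigmoid = c(
        sprintf("    mu_%s[i] <- %s * ilogit(%s)", v,
                format(s$scale_cap), eta),
        sprintf("    %s[i] ~ dnorm(mu_%s[i], prec_%s)", v, v, v)),
      stop("family ", s$family, " cannot be fitted")))
    for (p in names(s$priors)) {
      pr <- s$priors[[p]]
      jn <- jags_param_name(v, p)
      trunc <- switch(pr$constraint, none = "", positive = " T(0,)",
                      negative = " T(,0)")
      pri <- c(pri, sprintf("  %s ~ dnorm(%s, %s)%s", jn,
                            format(pr$location),
                            format(1 / pr$scale^2), trunc))
    }
    if (s$family %in% c("gaussian_linear", "hill_sigmoid")) {
      pri <- c(pri, sprintf("  prec_%s <- pow(%s, -2)", v, jp("sigma", v)))
    }
  }
  paste(c("model {", "  for (i in 1:N) {", lik, "  }", pri, "}"),
        collapse = "\n")
}

jp <- function(kind, v, p = NULL) {
  if (is.null(p)) paste0(kind, "_", v) else paste0(kind, "_", v, "_", p)
}

jags_param_name <- function(node, param) {
  if (param == "b0") return(jp("b0", node))
  if (param %in% c("sigma", "shape", "value")) return(jp(param, node))
  paste0("b_", node, "_", sub("^b_", "", param))
}

param_map <- function(lvm) {
  purrr::map_dfr(lvm$node_specs, function(s) {
    tibble::tibble(node = s$name, param = names(s$priors),
                   jags = vapply(names(s$priors), jags_param_name,
                                 "", node = s$name))
  })
}

#' Fit a causal LVM to observational data
#'
#' Trains the model by MCMC in JAGS: the target is the model's full joint
#' `prod_j P(V_j | Pa(V_j)) prod_l P(U_l | Pa(U_l))` with one latent value
#' per replicate sampled as a local latent parameter, and the declared
#' priors (truncated at sign constraints) over the global parameters.
#' Chain seeds are derived deterministically from `seed`.
#'
#' @param lvm a `causal_lvm` (observational form; no point-mass nodes).
#' @param data dataset whose columns are exactly the observed nodes.
#' @param chains number of MCMC chains.
#' @param warmup adaptation + burn-in iterations per chain.
#' @param iter kept iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed.
#' @param quiet suppress JAGS progress output.
#' @return An object of class `trained_lvm`: the model, a tibble of
#'   posterior draws (`.chain`, `.iteration`, one column per parameter),
#'   per-parameter convergence diagnostics (split chains: `rhat`, `ess`),
#'   and sampler metadata.
#' @export
fit <- function(lvm, data, chains = 2, warmup = 500, iter = 500, thin = 1,
                seed = 1, quiet = TRUE) {
  obs <- observed_nodes(lvm$graph)
  missing <- setdiff(obs, names(data))
  if (length(missing)) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  dat <- as.list(data[obs])
  if (!all(vapply(dat, function(x) all(is.finite(x)), TRUE))) {
    stop("data contains non-finite values")
  }
  dat$N <- nrow(data)

  code <- jags_model_code(lvm)
  mf <- tempfile(fileext = ".jags")
  writeLines(code, mf)
  on.exit(unlink(mf), add = TRUE)

  pm <- param_map(lvm)
  inits <- lapply(seq_len(chains), function(ch) {
    iv <- list(.RNG.name = "base::Mersenne-Twister",
               .RNG.seed = derive_seed(seed, paste0("chain", ch)))
    for (k in seq_len(nrow(pm))) {
      s <- lvm$node_specs[[pm$node[k]]]
      pr <- s$priors[[pm$param[k]]]
      iv[[pm$jags[k]]] <- switch(pr$constraint,
        none = 0, positive = max(0.5, pr$location),
        negative = min(-0.5, pr$location))
      if (pm$param[k] %in% c("sigma", "shape"))
        iv[[pm$jags[k]]] <- max(1, pr$location)
    }
    iv
  })

  jm <- rjags::jags.model(mf, data = dat, n.chains = chains,
                          n.adapt = min(warmup, 500), inits = inits,
                          quiet = quiet)
  burn <- warmup - min(warmup, 500)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, variable.names = unique(pm$jags),
                            n.iter = iter * thin, thin = thin,
                            progress.bar = "none")

  draws <- purrr::map_dfr(seq_along(sm), function(ch) {
    m <- as.matrix(sm[[ch]])
    tibble::as_tibble(m) |>
      dplyr::mutate(.chain = ch, .iteration = dplyr::row_number(),
                    .before = 1)
  })

  rhat <- rep(NA_real_, nrow(pm))
  if (chains >= 2) {
    gd <- try(coda::gelman.diag(sm, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) {
      rhat <- gd$psrf[unique(pm$jags), 1]
    }
  }
  ess <- try(coda::effectiveSize(sm)[unique(pm$jags)], silent = TRUE)
  if (inherits(ess, "try-error")) {
    ess <- rep(NA_real_, length(unique(pm$jags)))
  }
  diagnostics <- tibble::tibble(parameter = unique(pm$jags),
                                rhat = unname(rhat), ess = unname(ess))

  structure(list(
    lvm = lvm,
    draws = draws,
    diagnostics = diagnostics,
    param_map = pm,
    meta = list(chains = chains, warmup = warmup, iter = iter,
                thin = thin, seed = seed, n_obs = nrow(data),
                divergences = NA_integer_, engine = "jags")),
    class = "trained_lvm")
}

#' @export
print.trained_lvm <- function(x, ...) {
  cat(sprintf("<trained_lvm: %d parameters, %d draws (%d chains x %d)>\n",
              nrow(x$param_map), nrow(x$draws), x$meta$chains, x$meta$iter))
  print(utils::head(tidy(x), 10))
  invisible(x)
}

#' @export
tidy.trained_lvm <- function(x, ...) {
  long <- x$draws |>
    tidyr::pivot_longer(-c(".chain", ".iteration"),
                        names_to = "parameter", values_to = "value")
  sumry <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(estimate = mean(.data$value),
                     std.error = stats::sd(.data$value),
                     conf.low = stats::quantile(.data$value, 0.025),
                     conf.high = stats::quantile(.data$value, 0.975),
                     .groups = "drop")
  dplyr::left_join(sumry, x$diagnostics, by = "parameter")
}

#' @export
glance.trained_lvm <- function(x, ...) {
  tibble::tibble(n_parameters = nrow(x$param_map),
                 n_draws = nrow(x$draws),
                 chains = x$meta$chains,
                 max_rhat = suppressWarnings(max(x$diagnostics$rhat,
                                                 na.rm = TRUE)),
                 min_ess = min(x$diagnostics$ess),
                 n_obs = x$meta$n_obs)
}

#' Convergence report for a trained model
#'
#' Flags parameters whose split-chain R-hat exceeds `rhat_max` or whose
#' effective sample size falls below `ess_min`.  Parameter-level
#' non-convergence is reported separately from data-level adequacy: with
#' latent confounders some parameters are structurally non-identified and
#' never pin down, while the fit of the observed joint (and of identifiable
#' queries) still converges.  With fewer than 2 draws per chain the report
#' refuses to compute diagnostics.
#'
#' @param trained a `trained_lvm`.
#' @param rhat_max split-R-hat threshold.
#' @param ess_min effective-sample-size threshold.
#' @return A list with `ok` (logical), `flagged` (tibble of offending
#'   parameters), `reason` (character when refusing) and the thresholds.
#' @export
diagnostics_report <- function(trained, rhat_max = 1.05, ess_min = 50) {
  per_chain <- trained$meta$iter
  if (per_chain < 2) {
    return(list(ok = FALSE, flagged = trained$diagnostics[0, ],
                reason = "insufficient draws for diagnostics (need >= 2 per chain)",
                rhat_max = rhat_max, ess_min = ess_min))
  }
  d <- trained$diagnostics
  flagged <- d[(!is.na(d$rhat) & d$rhat > rhat_max) |
                 (!is.na(d$ess) & d$ess < ess_min), ]
  list(ok = nrow(flagged) == 0, flagged = flagged, reason = NULL,
       rhat_max = rhat_max, ess_min = ess_min)
}

#' Extract one posterior draw as a parameter assignment
#'
#' @param trained a `trained_lvm`.
#' @param index row index into the pooled draws.
#' @return Named list of named parameter vectors, as for
#'   [draw_parameters()].
#' @export
theta_from_draw <- function(trained, index) {
  row <- trained$draws[index, ]
  pm <- trained$param_map
  out <- list()
  for (nd in unique(pm$node)) {
    sub <- pm[pm$node == nd, ]
    out[[nd]] <- stats::setNames(
      vapply(sub$jags, function(j) row[[j]], 0), sub$param)
  }
  out
}

#' Export posterior draws and diagnostics
#'
#' @param trained a `trained_lvm`.
#' @param draws_csv path for the draws CSV (one column per parameter).
#' @param diagnostics_json optional path for the diagnostics JSON.
#' @return Invisibly, the paths written.
#' @export
export_posterior <- function(trained, draws_csv,
                             diagnostics_json = NULL) {
  utils::write.csv(trained$draws, draws_csv, row.names = FALSE)
  if (!is.null(diagnostics_json)) {
    jsonlite::write_json(list(
      diagnostics = trained$diagnostics, meta = trained$meta),
      diagnostics_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(draws_csv, diagnostics_json))
}
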