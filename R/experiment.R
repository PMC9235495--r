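#' Sampling-distribution experiment for a benchmark system
#'
#' Runs the benchmark evaluation protocol: for each
#' training-set size in `n_grid` and each repeat, observational data are
#' generated from the true system, the model is trained, the causal query
#' estimated, and the estimate recorded; the ground truth is computed once
#' by averaging interventional samples drawn under the true parameters
#' (or, for the Gillespie case, from interventional stochastic
#' simulations).  Both the correctly specified and the
#' latent-misspecified variants are run, giving the correct-vs-misspecified
#' convergence comparison.
#'
#' @param spec a `case_study_spec` (its query must be identifiable).
#' @param n_grid integer vector of training-set sizes.
#' @param repeats repetitions per size.
#' @param seed integer seed; every repeat derives its own seed from it.
#' @param variants subset of `c("correct", "misspecified")`.
#' @param chains,warmup,iter MCMC settings passed to [fit()].
#' @param s_draws,l_draws Monte-Carlo settings passed to
#'   [estimate_query()].
#' @param truth_n interventional samples used for the ground truth.
#' @param gillespie_t_max time horizon per stochastic-simulation
#'   replicate.
#' @return An object of class `evaluation_result`: per-run `estimates`
#'   (tibble: variant, n, rep, estimate), scalar `truth`, a `summary`
#'   tibble (bias, rmse per variant and n) and the configuration.
#' @export
run_sampling_experiment <- function(spec, n_grid, repeats = 20, seed = 1,
                                    variants = c("correct", "misspecified"),
                                    chains = 2, warmup = 400, iter = 300,
                                    s_draws = 300, l_draws = 20,
                                    truth_n = 10000,
                                    gillespie_t_max = 50) {
  variants <- intersect(variants,
                        c("correct",
                          if (!is.null(spec$misspecified)) "misspecified"))
  admg <- latent_project(spec$correct$graph)
  ident <- identify(admg, spec$query)
  if (ident$status != "identifiable") {
    rlang::abort(paste0("query of case '", spec$name,
                        "' is not identifiable; experiment refused"),
                 class = "dolvm_not_identifiable", identify_result = ident)
  }
  outcome <- spec$query$outcomes[1]

  parametric <- spec$mode == "parametric"
  theta_true <- if (parametric) case_truth(spec) else NULL
  gen_data <- function(n, gseed) {
    if (parametric) {
      sample_observational(spec$correct, theta_true, n, gseed)
    } else {
      d <- sample_gillespie_dataset(spec$network, n, gillespie_t_max,
                                    gseed,
                                    init_fn = random_growth_factor_init())
      d[, observed_nodes(spec$correct$graph)]
    }
  }
  if (parametric) {
    gt <- ground_truth_query(spec$correct, theta_true, spec$query,
                             n = truth_n, seed = derive_seed(seed, "truth"))
    truth <- gt$expectation[[outcome]]
    truth_se <- stats::sd(gt$draws[[outcome]]) / sqrt(truth_n)
  } else {
    di <- sample_gillespie_dataset(spec$network, truth_n,
                                   gillespie_t_max,
                                   derive_seed(seed, "truth"),
                                   init_fn = random_growth_factor_init(),
                                   do = spec$query$targets)
    truth <- mean(di[[outcome]])
    truth_se <- stats::sd(di[[outcome]]) / sqrt(truth_n)
  }

  runs <- tidyr::expand_grid(variant = variants, n = n_grid,
                             rep = seq_len(repeats))
  estimates <- purrr::pmap_dfr(runs, function(variant, n, rep) {
    rseed <- derive_seed(seed, paste(spec$name, variant, n, rep))
    lvm <- spec[[variant]]
    res <- tryCatch({
      d <- gen_data(n, rseed)
      tr <- fit(lvm, d[observed_nodes(lvm$graph)], chains = chains,
                warmup = warmup, iter = iter, seed = rseed)
      est <- estimate_query(tr, spec$query, s_draws = s_draws,
                            l_draws = l_draws, seed = rseed)
      est$expectation[[outcome]]
    }, error = function(e) {
      stop("experiment run failed (variant=", variant, ", n=", n,
           ", rep=", rep, "): ", conditionMessage(e))
    })
    tibble::tibble(variant = variant, n = n, rep = rep, estimate = res)
  })
  sumry <- estimates |>
    dplyr::group_by(.data$variant, .data$n) |>
    dplyr::summarise(bias = mean(.data$estimate) - truth,
                     rmse = sqrt(mean((.data$estimate - truth)^2)),
                     sd = stats::sd(.data$estimate),
                     .groups = "drop")
  structure(list(name = spec$name, estimates = estimates, truth = truth,
                 truth_se = truth_se, summary = sumry, query = spec$query,
                 config = list(n_grid = n_grid, repeats = repeats,
                               seed = seed, chains = chains,
                               warmup = warmup, iter = iter,
                               s_draws = s_draws, l_draws = l_draws,
                               truth_n = truth_n)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result:", x$name, ">  truth =",
      format(x$truth, digits = 4), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.evaluation_result <- function(x, ...) x$estimates

#' @export
glance.evaluation_result <- function(x, ...) {
  x$summary |> dplyr::mutate(truth = x$truth, case = x$name, .before = 1)
}

#' Sampling-distribution boxplots
#'
#' One box per training-set size per variant, with the ground truth as a
#' horizontal line — the convergence display of the benchmark case
#' studies.
#'
#' @param object an `evaluation_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = factor(.data$n), y = .data$estimate,
                               fill = .data$variant)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_hline(yintercept = object$truth, linetype = 2) +
    ggplot2::labs(x = "training-set size N",
                  y = format_query(object$query),
                  title = object$name, fill = NULL)
}

#' Export all artifacts of an evaluation
#'
#' Writes the graph file, model configuration, per-run estimates CSV,
#' summary JSON and a reproduction manifest into `dir`.
#'
#' @param spec the `case_study_spec` that was run.
#' @param result the `evaluation_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
export_evaluation <- function(spec, result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_graph_text(spec$correct$graph, file.path(dir, "graph.txt"))
  lvm_to_json(spec$correct, file.path(dir, "model_correct.json"))
  if (!is.null(spec$misspecified)) {
    lvm_to_json(spec$misspecified, file.path(dir, "model_misspecified.json"))
  }
  utils::write.csv(result$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(case = result$name, truth = result$truth,
         summary = result$summary, config = result$config),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(file.path(dir, "manifest.json"),
                 config = result$config,
                 inputs = list(case = spec$name,
                               theta_seed = spec$theta_seed))
  invisible(dir)
}

write_manifest <- function(path, config, inputs = list()) {
  jsonlite::write_json(list(
    config = config,
    config_hash = rlang::hash(config),
    inputs = inputs,
    seed = config$seed %||% NA,
    versions = list(
      package = as.character(utils::packageVersion("dolvm")),
      r = paste(R.version$major, R.version$minor, sep = ".")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
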