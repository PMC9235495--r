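test_that("identification catalog matches each system's known status", {
  ex_a <- build_example("fig2a")
  r <- identify(latent_project(ex_a$correct$graph), ex_a$query)
  expect_equal(r$status, "not_identifiable")

  ex_b <- build_example("fig2b")
  r <- identify(latent_project(ex_b$correct$graph), ex_b$query)
  expect_equal(r$method, "frontdoor")
  # single-confounder projection: one bidirected X <-> Y edge
  p <- latent_project(ex_a$correct$graph)
  expect_equal(paste(p$bi[, 1], p$bi[, 2]), "X Y")

  expected <- list(
    cs1_multicause_frontdoor = list(method = "frontdoor", witness = "hns"),
    cs2_napkin = list(method = "id_algorithm"),
    cs5_frontdoor = list(method = "frontdoor", witness = "rob"),
    cs6_napkin = list(method = "id_algorithm"))
  for (nm in names(expected)) {
    s <- build_case(nm)
    r <- identify(latent_project(s$correct$graph), s$query)
    expect_equal(r$status, "identifiable", info = nm)
    expect_equal(r$method, expected[[nm]]$method, info = nm)
    if (!is.null(expected[[nm]]$witness)) {
      expect_equal(r$witness, expected[[nm]]$witness, info = nm)
    }
  }

  cs4 <- build_case("cs4_sarscov2")
  admg <- latent_project(cs4$correct$graph)
  toci <- identify(admg, sarscov2_query("tocilizumab"))
  expect_equal(toci$method, "backdoor")
  gefi <- identify(admg, sarscov2_query("gefitinib"))
  expect_equal(gefi$status, "identifiable")
  expect_equal(gefi$method, "id_algorithm")
})

test_that("every builder validates and variants share one ADMG", {
  for (nm in c("cs1_multicause_frontdoor", "cs2_napkin", "cs3_signaling",
               "cs4_sarscov2", "cs5_frontdoor", "cs6_napkin")) {
    s <- build_case(nm)
    expect_length(validate_model(s$correct), 0)
    expect_length(validate_model(s$misspecified), 0)
    expect_true(graph_equal(latent_project(s$correct$graph),
                            latent_project(s$misspecified$graph)),
                info = nm)
  }
  expect_error(build_case("cs7_unknown"))
})

test_that("case truths are seeded, constraint-respecting draws", {
  s <- build_case("cs3_signaling")
  # mode gillespie: truth is simulation-defined, not parametric
  expect_error(case_truth(s), "stochastic")
  th1 <- draw_parameters(s$correct, s$theta_seed)
  th2 <- draw_parameters(s$correct, s$theta_seed)
  expect_identical(th1, th2)
  # repressive edge weight negative, activating positive
  expect_lt(th1$Raf[["b_Akt"]], 0)
  expect_gt(th1$Raf[["b_Ras"]], 0)

  s2 <- build_case("cs2_napkin")
  th <- case_truth(s2)
  expect_gt(th$hns[["shape"]], 0)
  expect_gt(th$topA[["sigma"]], 0)

  # napkin intervention value defaults to 0, overridable to 1
  expect_equal(unname(s2$query$targets["lrp"]), 0)
  s2b <- build_case("cs2_napkin", do_value = 1)
  expect_equal(unname(s2b$query$targets["lrp"]), 1)
})

test_that("SSA matches analytic birth-death moments", {
  # pure death from 100: count at t is Binomial(100, exp(-mu t))
  mu <- 0.03; t_end <- 15
  net <- reaction_network("A", list(
    list(reactants = c(A = 1L), products = stats::setNames(integer(), character()),
         rate = mu)))
  finals <- vapply(1:300, function(i)
    gillespie(net, t_end, seed = 1000 + i, record = FALSE)[["A"]], 0)
  p <- exp(-mu * t_end)
  se <- sqrt(100 * p * (1 - p) / 300)
  expect_lt(abs(mean(finals) - 100 * p), 4 * se)

  # immigration-death stationary mean lambda / mu
  net2 <- reaction_network("A", list(
    list(reactants = stats::setNames(integer(), character()),
         products = c(A = 1L), rate = 1),
    list(reactants = c(A = 1L),
         products = stats::setNames(integer(), character()), rate = 0.1)),
    init = c(A = 10L))
  finals2 <- vapply(1:300, function(i)
    gillespie(net2, 50, seed = 2000 + i, record = FALSE)[["A"]], 0)
  se2 <- stats::sd(finals2) / sqrt(300)
  expect_lt(abs(mean(finals2) - 10), 4 * se2)

  # no live propensity: trajectory constant at the initial counts
  net3 <- reaction_network("A", list(
    list(reactants = c(A = 1L), products = stats::setNames(integer(), character()),
         rate = 1)), init = c(A = 0L))
  tr <- gillespie(net3, 10, seed = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$A, 0)

  expect_error(reaction_network("A", list()), "at least one")
  expect_error(reaction_network("A", list(
    list(reactants = c(A = 1L), products = c(B = 1L), rate = 1))),
    "unknown species")
})

test_that("signaling SSA datasets behave like the modeled system", {
  net <- signaling_network()
  d <- sample_gillespie_dataset(net, n = 12, t_max = 40, seed = 5,
                                init_fn = random_growth_factor_init())
  expect_setequal(names(d), net$species)
  expect_true(all(d >= 0))
  expect_gt(stats::sd(d$EGF), 0)  # randomized inputs differ by replicate

  # clamping: SOS fixed, downstream still responds
  di <- sample_gillespie_dataset(net, n = 12, t_max = 40, seed = 5,
                                 init_fn = random_growth_factor_init(),
                                 do = c(SOS = 70))
  expect_true(all(di$SOS == 70))
  expect_equal(attr(di, "provenance"), "gillespie_interventional")

  # determinism
  d2 <- sample_gillespie_dataset(net, n = 12, t_max = 40, seed = 5,
                                 init_fn = random_growth_factor_init())
  expect_equal(as.data.frame(d), as.data.frame(d2))
})

test_that("sampling experiment wires end to end and is reproducible", {
  spec <- build_example("fig2b")
  res <- run_sampling_experiment(spec, n_grid = 40, repeats = 1, seed = 17,
                                 warmup = 150, iter = 100, s_draws = 100,
                                 l_draws = 10, truth_n = 2000)
  expect_s3_class(res, "evaluation_result")
  expect_equal(nrow(res$estimates), 1)
  expect_true(is.finite(res$truth))
  expect_gte(res$summary$rmse, abs(res$summary$bias))

  res2 <- run_sampling_experiment(spec, n_grid = 40, repeats = 1, seed = 17,
                                  warmup = 150, iter = 100, s_draws = 100,
                                  l_draws = 10, truth_n = 2000)
  expect_identical(res$estimates, res2$estimates)
  expect_identical(res$truth, res2$truth)

  expect_s3_class(autoplot(res), "ggplot")
  dir <- tempfile()
  export_evaluation(spec, res, dir)
  expect_true(file.exists(file.path(dir, "graph.txt")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 17)

  # a non-identifiable case refuses the experiment outright
  bad <- build_example("fig2a")
  expect_error(run_sampling_experiment(bad, 40, 1, 1),
               class = "dolvm_not_identifiable")
})
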