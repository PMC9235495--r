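test_that("closed-form linear-Gaussian moments are exact", {
  g <- parse_graph(c("X -> Z", "Z -> Y"))
  lvm <- causal_lvm(g, list(
    node_spec("X", "gaussian_linear"),
    node_spec("Z", "gaussian_linear", parents = "X"),
    node_spec("Y", "gaussian_linear", parents = "Z")))
  th <- list(X = c(b0 = 0, sigma = 1),
             Z = c(b0 = 0.4, b_X = 1.3, sigma = 0.7),
             Y = c(b0 = -1, b_Z = 0.6, sigma = 0.2))
  q <- causal_query(c(X = 2), "Y")
  cf <- closed_form_linear_gaussian(lvm, th, q)
  # mean: b0_Y + b_ZY * (b0_Z + b_XZ * x')
  expect_equal(cf$mean, -1 + 0.6 * (0.4 + 1.3 * 2))
  expect_equal(cf$variance, 0.6^2 * 0.7^2 + 0.2^2)

  # intervening on Y's only parent with zero upstream noise: var = sigma_Y^2
  q2 <- causal_query(c(Z = 1), "Y")
  cf2 <- closed_form_linear_gaussian(lvm, th, q2)
  expect_equal(cf2$mean, -1 + 0.6)
  expect_equal(cf2$variance, 0.2^2)

  # simulation cross-check on the confounded front-door system
  lvm2 <- linear_fd_lvm(); th2 <- linear_fd_theta()
  q3 <- causal_query(c(X = 1.5), "Y")
  cf3 <- closed_form_linear_gaussian(lvm2, th2, q3)
  gt <- ground_truth_query(lvm2, th2, q3, n = 10000, seed = 44)
  se <- stats::sd(gt$draws$Y) / sqrt(10000)
  expect_lt(abs(gt$expectation[["Y"]] - cf3$mean), 4 * se)
  expect_lt(abs(stats::var(gt$draws$Y) - cf3$variance),
            5 * cf3$variance / sqrt(10000) * 3)

  # refuses non-Gaussian families
  lvm3 <- causal_lvm(parse_graph("A -> B"), list(
    node_spec("A", "gaussian_linear"),
    node_spec("B", "bernoulli_logit", parents = "A")))
  expect_error(closed_form_linear_gaussian(
    lvm3, list(A = c(b0 = 0, sigma = 1), B = c(b0 = 0, b_A = 1)),
    causal_query(c(A = 0), "B")), "gaussian_linear")
})

test_that("mutilation estimator agrees with plug-in and closed form", {
  lvm <- linear_fd_lvm()
  th <- linear_fd_theta()
  xval <- 2
  q <- causal_query(c(X = xval), "Y", form = "expectation")
  n <- 2000
  d <- sample_observational(lvm, th, n = n, seed = 71)
  tr <- fit(lvm, d, chains = 2, warmup = 400, iter = 300, seed = 72)
  est <- estimate_query(tr, q, s_draws = 300, l_draws = 20, seed = 73)
  pf <- plugin_frontdoor(d, "X", "Y", "Z", xval, n_boot = 25, seed = 74)
  cf <- closed_form_linear_gaussian(lvm, th, q)

  est_se <- stats::sd(est$per_theta$Y) / sqrt(nrow(est$per_theta)) +
    stats::sd(est$draws$Y) / sqrt(nrow(est$draws))
  # estimator vs truth: finite-n posterior uncertainty dominates; allow the
  # posterior spread of per-draw means plus plug-in bootstrap error
  tol <- 3 * (stats::sd(est$per_theta$Y) + pf$se + est_se)
  expect_lt(abs(est$expectation[["Y"]] - cf$mean), tol)
  expect_lt(abs(pf$estimate - cf$mean), 3 * pf$se + 0.05)
  expect_lt(abs(est$expectation[["Y"]] - pf$estimate), tol)

  # query_estimate invariants
  expect_equal(est$expectation[["Y"]], mean(est$draws$Y))
  dx <- diff(est$density$x[1:2])
  expect_lt(abs(sum(est$density$y) * dx - 1), 1e-3)
  td <- tidy(est)
  expect_equal(td$outcome, "Y")
  expect_s3_class(autoplot(est, per_theta = TRUE), "ggplot")
})

test_that("non-identifiable queries are refused unless forced", {
  lvm <- bow_lvm()
  th <- bow_theta()
  d <- sample_observational(lvm, th, n = 300, seed = 81)
  tr <- fit(lvm, d, chains = 2, warmup = 200, iter = 150, seed = 82)
  q <- causal_query(c(X = 1), "Y")
  err <- tryCatch(estimate_query(tr, q, seed = 83),
                  dolvm_not_identifiable = function(e) e)
  expect_s3_class(err, "dolvm_not_identifiable")
  expect_equal(err$identify_result$status, "not_identifiable")

  forced <- estimate_query(tr, q, s_draws = 50, l_draws = 10, seed = 84,
                           force_nonidentifiable = TRUE)
  expect_s3_class(forced, "query_estimate")
  expect_true(glance(forced)$forced)
})

test_that("do on a childless node leaves other outcomes observational", {
  lvm <- linear_fd_lvm()
  th <- linear_fd_theta()
  d <- sample_observational(lvm, th, n = 1500, seed = 91)
  tr <- fit(lvm, d, chains = 2, warmup = 300, iter = 200, seed = 92)
  # Z has no directed path into X, so do(Y) leaves Z at its marginal;
  # rule 3 of do-calculus makes the estimate the observational marginal
  q <- causal_query(c(Y = 5), "Z")
  est <- estimate_query(tr, q, s_draws = 200, l_draws = 20, seed = 93)
  se <- stats::sd(d$Z) / sqrt(nrow(d)) + stats::sd(est$per_theta$Z)
  expect_lt(abs(est$expectation[["Z"]] - mean(d$Z)), 4 * se)
})

test_that("plug-in estimators are exact on discrete empirical tables", {
  set.seed(55)
  dag <- canonical_dag(frontdoor_admg())
  scm <- random_discrete_scm(dag)
  d <- sample_discrete_rows(scm, 4000)

  pf <- plugin_frontdoor(d, "X", "Y", "Z", 1, n_boot = 0)
  joint <- empirical_joint(d, c("X", "Y", "Z"))
  tab <- evaluate_estimand(frontdoor_estimand("X", "Y", "Z"), joint,
                           c(X = 1), "Y")
  expect_equal(pf$estimate, sum(tab$Y * tab$prob), tolerance = 1e-12)
  # and both converge on surgery truth
  truth <- surgery_truth(scm, c(X = 1), "Y")
  expect_lt(abs(pf$estimate - sum(truth$Y * truth$prob)), 0.05)

  dag2 <- canonical_dag(parse_graph(c("Z -> X", "Z -> Y", "X -> Y")))
  scm2 <- random_discrete_scm(dag2)
  d2 <- sample_discrete_rows(scm2, 4000)
  pb <- plugin_backdoor(d2, "X", "Y", "Z", 0, n_boot = 0)
  truth2 <- surgery_truth(scm2, c(X = 0), "Y")
  expect_lt(abs(pb$estimate - sum(truth2$Y * truth2$prob)), 0.05)
})

test_that("continuous back-door plug-in reduces to regression when z is empty", {
  set.seed(65)
  n <- 3000
  x <- stats::rnorm(n)
  y <- 2 + 1.5 * x + stats::rnorm(n, 0, 0.5)
  d <- tibble::tibble(X = x, Y = y)
  pb <- plugin_backdoor(d, "X", "Y", character(), 1, n_boot = 20)
  expect_lt(abs(pb$estimate - 3.5), 3 * pb$se + 0.05)

  # zero mediator dependence: front-door plug-in constant in x'
  dz <- tibble::tibble(X = x, Z = stats::rnorm(n),
                       Y = 1 + 0.8 * stats::rnorm(n))
  p1 <- plugin_frontdoor(dz, "X", "Y", "Z", -2, n_boot = 0)
  p2 <- plugin_frontdoor(dz, "X", "Y", "Z", 2, n_boot = 0)
  expect_lt(abs(p1$estimate - p2$estimate), 0.15)
})

test_that("ground truth query serializes and reports exact point mass meta", {
  lvm <- linear_fd_lvm()
  gt <- ground_truth_query(lvm, linear_fd_theta(),
                           causal_query(c(X = 0), "Y"), n = 500, seed = 3)
  expect_equal(gt$meta$method, "truth")
  stem <- tempfile()
  export_query_estimate(gt, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  js <- jsonlite::fromJSON(paste0(stem, ".json"))
  expect_equal(js$expectation$Y, gt$expectation[["Y"]])
  # reproducible under equal seed
  gt2 <- ground_truth_query(lvm, linear_fd_theta(),
                            causal_query(c(X = 0), "Y"), n = 500, seed = 3)
  expect_identical(gt$expectation, gt2$expectation)
})
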