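test_that("ancestral sampling matches closed-form linear-Gaussian means", {
  lvm <- linear_fd_lvm()
  th <- linear_fd_theta()
  n <- 10000
  d <- sample_observational(lvm, th, n = n, seed = 101)
  expect_setequal(names(d), c("X", "Z", "Y"))
  expect_equal(nrow(d), n)

  # closed-form mean propagation (independent of the sampler)
  mU <- 1
  mX <- 0.5 + 1.2 * mU
  mZ <- -0.3 + 0.9 * mX
  mY <- 0.2 + 0.7 * mU + 1.1 * mZ
  for (v in c("X", "Z", "Y")) {
    m <- c(X = mX, Z = mZ, Y = mY)[[v]]
    se <- stats::sd(d[[v]]) / sqrt(n)
    expect_lt(abs(mean(d[[v]]) - m), 4 * se)
  }

  # latent columns retrievable via the debug flag
  dl <- sample_observational(lvm, th, n = 10, seed = 1, keep_latent = TRUE)
  expect_true("U" %in% names(dl))
})

test_that("zero-weight models give independent intercept-only draws", {
  g <- parse_graph(c("A -> B"))
  lvm <- causal_lvm(g, list(node_spec("A", "gaussian_linear"),
                            node_spec("B", "gaussian_linear", parents = "A")))
  th <- list(A = c(b0 = 2, sigma = 1), B = c(b0 = -1, b_A = 0, sigma = 2))
  d <- sample_observational(lvm, th, n = 8000, seed = 5)
  expect_lt(abs(mean(d$B) + 1), 4 * 2 / sqrt(8000))
  expect_lt(abs(stats::cor(d$A, d$B)), 4 / sqrt(8000))
})

test_that("sampling is deterministic under a fixed seed", {
  lvm <- linear_fd_lvm()
  th <- linear_fd_theta()
  d1 <- sample_observational(lvm, th, n = 50, seed = 7)
  d2 <- sample_observational(lvm, th, n = 50, seed = 7)
  expect_identical(d1, d2)
  d3 <- sample_observational(lvm, th, n = 50, seed = 8)
  expect_false(identical(d1, d3))
})

test_that("each family passes analytic moment checks", {
  n <- 10000
  fams <- list(
    list(spec = node_spec("v", "gaussian_linear", parents = "pa"),
         theta = c(b0 = 1, b_pa = 0.5, sigma = 1.5)),
    list(spec = node_spec("v", "bernoulli_logit", parents = "pa"),
         theta = c(b0 = -0.4, b_pa = 0.8)),
    list(spec = node_spec("v", "gamma", parents = "pa"),
         theta = c(b0 = 0.5, b_pa = 0.3, shape = 3)),
    list(spec = node_spec("v", "hill_sigmoid", parents = "pa"),
         theta = c(b0 = -1, b_pa = 0.05, sigma = 4)))
  set.seed(9)
  pa_val <- 2
  data <- tibble::tibble(pa = rep(pa_val, n))
  for (f in fams) {
    x <- sample_node(f$spec, f$theta, data, n)
    mo <- node_moments(f$spec, f$theta, c(pa = pa_val))
    se <- sqrt(mo[["var"]] / n)
    expect_lt(abs(mean(x) - mo[["mean"]]), 4 * se)
    # variance within a generous band
    expect_lt(abs(stats::var(x) - mo[["var"]]), 5 * mo[["var"]] / sqrt(n) + 1e-9)
  }
})

test_that("hill_sigmoid mean always lies strictly inside (0, scale_cap)", {
  spec <- node_spec("v", "hill_sigmoid", parents = "pa", scale_cap = 100)
  for (b in c(-12, -5, 0, 5, 12)) {
    mo <- node_moments(spec, c(b0 = b, b_pa = 1, sigma = 1), c(pa = 3))
    expect_gt(mo[["mean"]], 0)
    expect_lt(mo[["mean"]], 100)
  }
})

test_that("model mutilation fixes targets and matches interventional draws", {
  lvm <- linear_fd_lvm()
  th <- linear_fd_theta()
  mut <- mutilate_model(lvm, c(X = 2))
  expect_equal(mut$node_specs$X$family, "point_mass")
  expect_equal(length(graph_parents(mut$graph, "X")), 0)
  # original untouched
  expect_equal(lvm$node_specs$X$family, "gaussian_linear")
  # empty do: unchanged model
  expect_equal(mutilate_model(lvm, stats::setNames(numeric(), character())),
               lvm)

  # mutilate + sample == sample_interventional under equal seeds
  th2 <- th; th2$X <- c(value = 2)
  d1 <- sample_observational(mut, th2, n = 40, seed = 3)
  d2 <- sample_interventional(lvm, th, c(X = 2), n = 40, seed = 3)
  expect_equal(as.data.frame(lapply(d1, c)), as.data.frame(lapply(d2, c)))
  expect_true(all(d2$X == 2))

  # closed-form interventional mean: E[Y|do(x')] = b0_Y + b_UY*E[U]
  #   + b_ZY*(b0_Z + b_XZ*x')
  d3 <- sample_interventional(lvm, th, c(X = 2), n = 10000, seed = 11)
  truth <- 0.2 + 0.7 * 1 + 1.1 * (-0.3 + 0.9 * 2)
  expect_lt(abs(mean(d3$Y) - truth), 4 * stats::sd(d3$Y) / sqrt(10000))

  # do on a childless node leaves upstream marginals unchanged
  d4 <- sample_interventional(lvm, th, c(Y = 0), n = 10000, seed = 12)
  d5 <- sample_observational(lvm, th, n = 10000, seed = 13)
  expect_gt(stats::ks.test(d4$Z, d5$Z)$p.value, 1e-4)

  expect_error(sample_interventional(lvm, th, c(U = 1), 10, 1), "latent")
  bad <- th; bad$Y <- bad$Y[names(bad$Y) != "b_Z"]
  expect_error(sample_observational(lvm, bad, 10, 1), "b_Z")
})

test_that("validate_model flags corrupted specifications", {
  lvm <- linear_fd_lvm()
  expect_length(validate_model(lvm), 0)

  # weight/parent mismatch
  bad <- lvm
  bad$node_specs$Y$parents <- "Z"
  bad$node_specs$Y$priors$b_U <- NULL
  expect_gt(length(validate_model(bad)), 0)

  # fuzz: each corruption kind is detected
  set.seed(17)
  corruptions <- list(
    function(m) { m$node_specs$Z$family <- "weibull"; m },
    function(m) { m$node_specs$X$priors$sigma$scale <- -1; m },
    function(m) { m$node_specs$X$priors$sigma$constraint <- "none"; m },
    function(m) { m$node_specs$Y$priors$b_Z <- NULL; m },
    function(m) { m$node_specs$U <- NULL; m },
    function(m) { m$node_specs$Z$parents <- c("X", "U"); m })
  for (f in corruptions) {
    expect_gt(length(validate_model(f(lvm))), 0)
  }

  expect_error(causal_lvm(lvm$graph, list(node_spec("U", "gaussian_linear"))),
               "invalid model")
})

test_that("parameter draws respect prior constraints and seeding", {
  g <- parse_graph(c("A -> B"))
  lvm <- causal_lvm(g, list(
    node_spec("A", "gaussian_linear"),
    node_spec("B", "hill_sigmoid", parents = "A",
              priors = list(b_A = prior_spec(0, 10, "positive")))))
  th1 <- draw_parameters(lvm, seed = 4)
  th2 <- draw_parameters(lvm, seed = 4)
  expect_identical(th1, th2)
  expect_gt(th1$B[["b_A"]], 0)
  expect_gt(th1$A[["sigma"]], 0)
  set.seed(1)
  draws <- replicate(200, draw_parameters(lvm, seed = sample.int(1e6, 1))$B[["b_A"]])
  expect_true(all(draws > 0))
})

test_that("model and dataset serialization round-trip", {
  lvm <- linear_fd_lvm()
  f <- tempfile(fileext = ".json")
  lvm_to_json(lvm, f)
  lvm2 <- lvm_from_json(f)
  expect_true(graph_equal(lvm$graph, lvm2$graph))
  expect_equal(lvm$node_specs$Y$priors$b_Z$scale,
               lvm2$node_specs$Y$priors$b_Z$scale)

  d <- sample_interventional(lvm, linear_fd_theta(), c(X = 1), 20, 2)
  csv <- tempfile(fileext = ".csv")
  write_dataset(d, csv)
  d2 <- read_dataset(csv)
  expect_equal(attr(d2, "provenance"), "interventional")
  expect_equal(unname(attr(d2, "do")["X"]), 1)
  expect_equal(d2$Y, d$Y, tolerance = 1e-12)
})
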