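# linear-Gaussian front-door system used across test files:
# U -> X -> Z -> Y with U -> Y, all gaussian_linear
linear_fd_lvm <- function() {
  g <- fig2b_graph()
  causal_lvm(g, list(
    node_spec("U", "gaussian_linear"),
    node_spec("X", "gaussian_linear", parents = "U"),
    node_spec("Z", "gaussian_linear", parents = "X"),
    node_spec("Y", "gaussian_linear", parents = c("U", "Z"))))
}

linear_fd_theta <- function() {
  list(U = c(b0 = 1, sigma = 1),
       X = c(b0 = 0.5, b_U = 1.2, sigma = 0.8),
       Z = c(b0 = -0.3, b_X = 0.9, sigma = 0.6),
       Y = c(b0 = 0.2, b_U = 0.7, b_Z = 1.1, sigma = 0.5))
}

# confounded bow system (non-identifiable query): U -> X -> Y, U -> Y
bow_lvm <- function() {
  causal_lvm(fig2a_graph(), list(
    node_spec("U", "gaussian_linear"),
    node_spec("X", "gaussian_linear", parents = "U"),
    node_spec("Y", "gaussian_linear", parents = c("U", "X"))))
}

bow_theta <- function() {
  list(U = c(b0 = 0, sigma = 1),
       X = c(b0 = 0, b_U = 1.5, sigma = 0.7),
       Y = c(b0 = 1, b_U = 2, b_X = 1, sigma = 0.5))
}

# sample rows from a discrete SCM's observational joint
sample_discrete_rows <- function(scm, n) {
  joint <- observational_table(scm)
  idx <- sample.int(nrow(joint), n, replace = TRUE, prob = joint$p)
  joint[idx, setdiff(names(joint), "p")]
}
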