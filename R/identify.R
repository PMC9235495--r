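#' Causal queries
#'
#' A causal query asks for the interventional distribution
#' `P(Y | do(X = x'))` or its expectation over a set of outcomes, given a
#' set of intervened nodes fixed to numeric values.
#'
#' @param targets named numeric vector: intervened nodes and their values.
#' @param outcomes character vector of outcome nodes, disjoint from the
#'   targets.
#' @param form `"expectation"` or `"distribution"`.
#' @return An object of class `causal_query`.
#' @examples
#' causal_query(c(X = 1), "Y", form = "distribution")
#' @export
causal_query <- function(targets, outcomes,
                         form = c("expectation", "distribution")) {
  form <- match.arg(form)
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("targets must be a named numeric vector, e.g. c(X = 1)")
  }
  if (length(intersect(names(targets), outcomes))) {
    stop("targets and outcomes must be disjoint")
  }
  structure(list(targets = targets, outcomes = as.character(outcomes),
                 form = form),
            class = "causal_query")
}

#' @export
print.causal_query <- function(x, ...) {
  fn <- if (x$form == "expectation") "E" else "P"
  cat(sprintf("%s[%s | do(%s)]\n", fn, paste(x$outcomes, collapse = ","),
              paste(names(x$targets), "=", x$targets, collapse = ", ")))
  invisible(x)
}

#' Back-door criterion
#'
#' `z` satisfies the back-door criterion relative to (`x`, `y`) when no
#' member of `z` is a descendant of `x` and `z` d-separates `x` from `y` in
#' the graph with the edges out of `x` removed — which blocks every path
#' into `x`, including paths through bidirected (latent-confounding) edges,
#' since the implied latents can never be conditioned on.
#'
#' @param admg an ADMG.
#' @param x intervened node(s).
#' @param y outcome node(s).
#' @param z candidate adjustment set (may be empty).
#' @return `TRUE` or `FALSE`.
#' @export
check_backdoor <- function(admg, x, y, z = character()) {
  check_nodes_known(c(x, y, z), observed_nodes(admg), "check_backdoor()")
  if (length(intersect(z, c(x, y)))) {
    stop("adjustment set must not contain the cause or the outcome")
  }
  if (any(z %in% setdiff(graph_descendants(admg, x), x))) return(FALSE)
  d_separated(mutilate_outgoing(admg, x), x, y, z)
}

#' Front-door criterion
#'
#' `z` satisfies the front-door criterion relative to (`x`, `y`) when (i)
#' `z` intercepts every directed path from `x` to `y`, (ii) there is no
#' unblocked back-door path from `x` to `z`, and (iii) every back-door path
#' from `z` to `y` is blocked by `x`.  The mediator is thereby shielded
#' from the confounding that invalidates direct adjustment.
#'
#' @inheritParams check_backdoor
#' @param z candidate mediator set.
#' @return `TRUE` or `FALSE`.
#' @export
check_frontdoor <- function(admg, x, y, z) {
  check_nodes_known(c(x, y, z), observed_nodes(admg), "check_frontdoor()")
  if (length(intersect(z, c(x, y)))) {
    stop("mediator set must not contain the cause or the outcome")
  }
  sub <- induced_subgraph_mg(admg, setdiff(admg$nodes, z))
  if (any(y %in% graph_descendants(sub, intersect(x, sub$nodes)))) {
    return(FALSE)  # a directed x -> y path avoids z
  }
  if (!length(z)) return(TRUE)
  if (!d_separated(mutilate_outgoing(admg, x), x, z, character())) {
    return(FALSE)
  }
  d_separated(mutilate_outgoing(admg, z), z, y, x)
}

subsets_by_size <- function(pool, max_size) {
  out <- list(character(0))
  if (!length(pool)) return(out)
  for (k in seq_len(min(max_size, length(pool)))) {
    cmb <- utils::combn(pool, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

#' Search for an admissible adjustment or mediator set
#'
#' Enumerates candidate sets by increasing size and returns the first that
#' satisfies the criterion, or `NULL` if none does.
#'
#' @inheritParams check_backdoor
#' @param max_size largest candidate set considered.
#' @return Character vector (possibly empty) or `NULL`.
#' @export
find_backdoor_set <- function(admg, x, y, max_size = 5) {
  pool <- setdiff(observed_nodes(admg), c(x, y, graph_descendants(admg, x)))
  for (z in subsets_by_size(pool, max_size)) {
    if (check_backdoor(admg, x, y, z)) return(z)
  }
  NULL
}

#' @rdname find_backdoor_set
#' @export
find_frontdoor_set <- function(admg, x, y, max_size = 3) {
  pool <- setdiff(observed_nodes(admg), c(x, y))
  for (z in subsets_by_size(pool, max_size)) {
    if (length(z) && check_frontdoor(admg, x, y, z)) return(z)
  }
  NULL
}

#' Textbook adjustment estimands
#'
#' `backdoor_estimand()` builds `sum_z P(y|x,z) P(z)`;
#' `frontdoor_estimand()` builds `sum_z P(z|x) sum_x P(y|x,z) P(x)`.
#' These are the expression trees [identify()] attaches when the
#' corresponding criterion holds; exposed for direct evaluation against
#' empirical tables.
#'
#' @param x,y cause and effect variable names (may be vectors).
#' @param z adjustment or mediator variable names.
#' @return An [estimand].
#' @export
backdoor_estimand <- function(x, y, z) {
  if (!length(z)) return(est_conditional(y, x))
  est_marginalize(z, est_product(list(est_conditional(y, c(x, z)),
                                      est_conditional(z))))
}

#' @rdname backdoor_estimand
#' @export
frontdoor_estimand <- function(x, y, z) {
  inner <- est_marginalize(x, est_product(list(est_conditional(y, c(x, z)),
                                               est_conditional(x))))
  est_marginalize(z, est_product(list(est_conditional(z, x), inner)))
}

#' The three rules of do-calculus
#'
#' Tests the graphical premise of a do-calculus rule on an ADMG.  Rule 1
#' (insertion/deletion of observations) requires `(Y indep Z | X, W)` in the
#' graph with incoming edges to `X` removed; rule 2 (action/observation
#' exchange) the same independence with, additionally, the edges out of `Z`
#' removed; rule 3 (insertion/deletion of actions) the independence with
#' incoming edges removed for `X` and for `Z(W)`, the subset of `Z` that are
#' not ancestors of any node of `W` in the `X`-mutilated graph.
#'
#' @param rule 1, 2 or 3.
#' @param admg an ADMG.
#' @param x,y,z,w disjoint node sets (`x` and `w` may be empty).
#' @return `TRUE` iff the rule's d-separation premise holds.
#' @export
apply_rule <- function(rule, admg, x, y, z, w = character()) {
  sets <- list(x, y, z, w)
  for (i in 1:3) for (j in seq(i + 1, 4)) {
    if (length(intersect(sets[[i]], sets[[j]]))) {
      stop("apply_rule() requires disjoint node sets")
    }
  }
  if (!length(z)) return(TRUE)
  g <- switch(as.character(rule),
    "1" = mutilate_incoming(admg, x),
    "2" = mutilate_outgoing(mutilate_incoming(admg, x), z),
    "3" = {
      gx <- mutilate_incoming(admg, x)
      zw <- if (length(w)) setdiff(z, graph_ancestors(gx, w)) else z
      mutilate_incoming(admg, union(x, zw))
    },
    stop("rule must be 1, 2 or 3"))
  d_separated(g, y, z, union(x, w))
}

# ---------------------------------------------------------------------------
# complete recursive identification over districts

# conditional of the running distribution expression P, restricted to the
# current variable scope; context variables of P outside the scope are kept
cond_within <- function(P, v, pred, scope) {
  keep <- union(setdiff(est_vars(P), scope), union(v, pred))
  if (P$kind == "conditional" && !length(P$given)) {
    k1 <- intersect(P$vars, keep)
    return(est_conditional(v, setdiff(k1, v)))
  }
  num <- est_marginalize(setdiff(est_vars(P), keep), P)
  den <- est_marginalize(v, num)
  est_fraction(num, den)
}

#' Recursive district-based identification (low level)
#'
#' The complete recursive identification algorithm, exposed for
#' cross-checking against the fast-path criteria.  Raises a condition of
#' class `dolvm_hedge` when the query is not identifiable.  Most callers
#' want [identify()].
#'
#' @param y outcome node set.
#' @param x intervened node set.
#' @param P running distribution expression (start with
#'   `est_conditional(observed_nodes(G))`).
#' @param G an ADMG.
#' @return An [estimand].
#' @export
id_recursive <- function(y, x, P, G) {
  V <- G$nodes
  if (!length(x)) {
    return(est_marginalize(setdiff(V, y), P))
  }
  A <- graph_ancestors(G, y)
  if (!setequal(A, V)) {
    return(id_recursive(y, intersect(x, A),
                        est_marginalize(setdiff(V, A), P),
                        induced_subgraph_mg(G, A)))
  }
  W <- setdiff(setdiff(V, x),
               graph_ancestors(mutilate_incoming(G, x), y))
  if (length(W)) {
    return(id_recursive(y, union(x, W), P, G))
  }
  Ds <- districts(G, setdiff(V, x))
  if (length(Ds) > 1) {
    parts <- lapply(Ds, function(D) id_recursive(D, setdiff(V, D), P, G))
    return(est_marginalize(setdiff(V, union(y, x)), est_product(parts)))
  }
  D <- Ds[[1]]
  DG <- districts(G, V)
  if (any(vapply(DG, function(d) setequal(d, V), TRUE))) {
    rlang::abort("query is not identifiable (hedge found)",
                 class = "dolvm_hedge", district = D)
  }
  ord <- topological_sort(G)
  pred <- function(v) ord[seq_len(match(v, ord) - 1)]
  if (any(vapply(DG, function(d) setequal(d, D), TRUE))) {
    facs <- lapply(D[order(match(D, ord))],
                   function(v) cond_within(P, v, pred(v), V))
    return(est_marginalize(setdiff(D, y), est_product(facs)))
  }
  Sp <- DG[[which(vapply(DG, function(d) all(D %in% d), TRUE))[1]]]
  Sp <- Sp[order(match(Sp, ord))]
  facs <- lapply(Sp, function(v) cond_within(P, v, pred(v), V))
  id_recursive(y, intersect(x, Sp), est_product(facs),
               induced_subgraph_mg(G, Sp))
}

#' Decide identifiability and derive a do-free estimand
#'
#' Tries, in order: the back-door criterion, the front-door criterion, and
#' the complete recursive identification algorithm over confounded
#' districts (sound and complete for interventional queries on ADMGs).  The
#' first two are fast paths that also label which textbook criterion
#' applied; the recursive algorithm decides every remaining case, so a
#' query is reported non-identifiable only when no do-calculus derivation
#' exists.
#'
#' @param admg an ADMG over observed nodes (use [latent_project()] on an
#'   explicit-latent DAG first).
#' @param query a [causal_query()]; multi-node intervention and outcome
#'   sets are supported.
#' @return An object of class `identify_result` with fields `status`
#'   (`"identifiable"` or `"not_identifiable"`), `estimand` (an
#'   [estimand], present iff identifiable), `method` (`"backdoor"`,
#'   `"frontdoor"` or `"id_algorithm"`), `witness` (the adjustment or
#'   mediator set, when applicable) and `query`.
#' @examples
#' fd <- parse_graph(c("X -> Z", "Z -> Y", "X <-> Y"))
#' identify(fd, causal_query(c(X = 1), "Y"))
#' @export
identify <- function(admg, query) {
  if (length(admg$latent)) {
    stop("identify() expects an ADMG; apply latent_project() first")
  }
  x <- names(query$targets)
  y <- query$outcomes
  check_nodes_known(c(x, y), observed_nodes(admg), "identify()")
  z <- find_backdoor_set(admg, x, y)
  if (!is.null(z)) {
    return(new_identify_result("identifiable", backdoor_estimand(x, y, z),
                               "backdoor", z, query))
  }
  z <- find_frontdoor_set(admg, x, y)
  if (!is.null(z)) {
    return(new_identify_result("identifiable", frontdoor_estimand(x, y, z),
                               "frontdoor", z, query))
  }
  est <- tryCatch(
    id_recursive(y, x, est_conditional(observed_nodes(admg)), admg),
    dolvm_hedge = function(e) e)
  if (inherits(est, "estimand")) {
    return(new_identify_result("identifiable", est, "id_algorithm", NULL,
                               query))
  }
  new_identify_result("not_identifiable", NULL, NA_character_,
                      est$district, query)
}

new_identify_result <- function(status, estimand, method, witness, query) {
  structure(list(status = status, estimand = estimand, method = method,
                 witness = witness, query = query),
            class = "identify_result")
}

#' @export
print.identify_result <- function(x, ...) {
  print(x$query)
  if (x$status == "identifiable") {
    cat("identifiable via ", x$method, sep = "")
    if (!is.null(x$witness) && length(x$witness)) {
      cat(" (witness: ", paste(x$witness, collapse = ", "), ")", sep = "")
    }
    cat("\n  ", render_estimand(x$estimand), "\n", sep = "")
  } else {
    cat("NOT identifiable")
    if (!is.null(x$witness)) {
      cat(" (hedge at district {", paste(x$witness, collapse = ", "), "})",
          sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.identify_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    method = x$method,
    witness = paste(x$witness, collapse = ","),
    targets = paste(names(x$query$targets), collapse = ","),
    outcomes = paste(x$query$outcomes, collapse = ","),
    estimand = if (is.null(x$estimand)) NA_character_ else
      render_estimand(x$estimand))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data :=
NULL
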