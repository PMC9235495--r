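#' Discrete structural causal models by exhaustive enumeration
#'
#' A small finite-support SCM toolset used as the numeric ground truth for
#' identification: the observational joint is obtained by enumerating the
#' full table and summing out latents, and interventional truth by graph
#' surgery on the conditional probability tables followed by the same
#' enumeration.  Everything is exact, so identified estimands can be
#' checked against surgery truth to machine precision.
#'
#' @param graph an explicit-latent DAG (`mixed_graph`).
#' @param cpts named list, one entry per node: a data frame with one column
#'   per parent, one column for the node itself and a `p` column holding
#'   the conditional probability of the node value given the parent values.
#' @return `discrete_scm()` returns an object of class `discrete_scm`.
#' @export
discrete_scm <- function(graph, cpts) {
  stopifnot(setequal(names(cpts), graph$nodes))
  for (v in graph$nodes) {
    pa <- graph_parents(graph, v)
    got <- setdiff(names(cpts[[v]]), "p")
    if (!setequal(got, c(v, pa))) {
      stop("cpt for ", v, " must have columns {", paste(c(v, pa),
           collapse = ", "), ", p}")
    }
  }
  structure(list(graph = graph, cpts = lapply(cpts, tibble::as_tibble)),
            class = "discrete_scm")
}

#' @rdname discrete_scm
#' @param levels number of levels per variable (values `0:(levels-1)`).
#' @details `random_discrete_scm()` draws strictly positive conditional
#'   probability tables (each row normalized from `runif(0.1, 1)` weights),
#'   so every conditioning event has positive mass.
#' @export
random_discrete_scm <- function(graph, levels = 2) {
  cpts <- list()
  for (v in graph$nodes) {
    pa <- graph_parents(graph, v)
    grid <- do.call(expand.grid, c(
      stats::setNames(rep(list(0:(levels - 1)), length(pa) + 1), c(pa, v)),
      list(KEEP.OUT.ATTRS = FALSE)))
    grid <- tibble::as_tibble(grid)
    grid$p <- stats::runif(nrow(grid), 0.1, 1)
    grid <- grid |>
      dplyr::group_by(dplyr::across(dplyr::all_of(pa))) |>
      dplyr::mutate(p = .data$p / sum(.data$p)) |>
      dplyr::ungroup()
    cpts[[v]] <- grid
  }
  discrete_scm(graph, cpts)
}

#' @rdname discrete_scm
#' @param scm a `discrete_scm`.
#' @details `scm_full_joint()` enumerates the joint over all nodes;
#'   `observational_table()` sums out the latent nodes.
#' @export
scm_full_joint <- function(scm) {
  ord <- topological_sort(scm$graph)
  out <- NULL
  for (v in ord) {
    cpt <- scm$cpts[[v]] |> dplyr::rename(.pv = "p")
    if (is.null(out)) {
      out <- cpt |> dplyr::rename(p = ".pv")
    } else {
      by <- intersect(setdiff(names(out), "p"), setdiff(names(cpt), ".pv"))
      out <- if (length(by)) {
        dplyr::inner_join(out, cpt, by = by, relationship = "many-to-many")
      } else {
        dplyr::cross_join(out, cpt)
      }
      out <- out |>
        dplyr::mutate(p = .data$p * .data$.pv) |>
        dplyr::select(-".pv")
    }
  }
  out
}

#' @rdname discrete_scm
#' @export
observational_table <- function(scm) {
  obs <- observed_nodes(scm$graph)
  scm_full_joint(scm) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(obs))) |>
    dplyr::summarise(p = sum(.data$p), .groups = "drop")
}

#' Interventional truth by graph surgery
#'
#' Replaces the conditional probability table of each intervened node by a
#' point mass at its intervention value, severs its parents, enumerates the
#' mutilated joint and returns the exact distribution of the outcomes.
#'
#' @param scm a `discrete_scm`.
#' @param do named vector of intervention values (observed nodes).
#' @param outcomes character vector of outcome nodes.
#' @return A tibble over the outcome columns with a `prob` column.
#' @export
surgery_truth <- function(scm, do, outcomes) {
  check_nodes_known(names(do), observed_nodes(scm$graph), "surgery_truth()")
  g2 <- mutilate_incoming(scm$graph, names(do))
  cpts <- scm$cpts
  for (v in names(do)) {
    support <- sort(unique(scm$cpts[[v]][[v]]))
    cpts[[v]] <- tibble::tibble(!!v := support,
                                p = as.numeric(support == do[[v]]))
  }
  mut <- discrete_scm(g2, cpts)
  scm_full_joint(mut) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(outcomes))) |>
    dplyr::summarise(prob = sum(.data$p), .groups = "drop")
}

#' Canonical explicit-latent DAG of an ADMG
#'
#' Introduces one fresh latent parent per bidirected edge, giving an
#' explicit-latent DAG whose latent projection is the input ADMG.
#'
#' @param admg an ADMG (`mixed_graph` with bidirected edges, no latent
#'   flags).
#' @return An explicit-latent `mixed_graph`.
#' @export
canonical_dag <- function(admg) {
  if (length(admg$latent)) stop("canonical_dag() expects an ADMG")
  if (!nrow(admg$bi)) return(admg)
  lat <- paste0("u_", admg$bi[, 1], "_", admg$bi[, 2])
  di <- rbind(admg$di, cbind(lat, admg$bi[, 1]), cbind(lat, admg$bi[, 2]))
  mixed_graph(c(admg$nodes, lat), directed = di, latent = lat)
}
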