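#' Mass-action reaction networks
#'
#' @param species character vector of species names.
#' @param reactions list of reactions; each is a list with `reactants` and
#'   `products` (named integer count maps, possibly empty) and a positive
#'   `rate` constant.
#' @param init named integer vector of initial molecule counts (defaults
#'   to 100 for every species, the convention of the signaling benchmark).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions,
                             init = stats::setNames(rep(100L,
                                                        length(species)),
                                                    species)) {
  if (!length(reactions)) stop("reaction network needs at least one reaction")
  for (r in reactions) {
    if (!is.numeric(r$rate) || r$rate <= 0) stop("reaction rates must be > 0")
    bad <- setdiff(c(names(r$reactants), names(r$products)), species)
    if (length(bad)) stop("unknown species in reaction: ",
                          paste(bad, collapse = ", "))
  }
  init <- init[species]
  if (any(is.na(init)) || any(init < 0) || any(init != round(init))) {
    stop("initial counts must be non-negative integers for every species")
  }
  structure(list(species = species, reactions = reactions, init = init),
            class = "reaction_network")
}

propensities <- function(net, x) {
  vapply(net$reactions, function(r) {
    a <- r$rate
    for (s in names(r$reactants)) {
      k <- r$reactants[[s]]
      # falling factorial for multi-molecular collisions
      a <- a * prod(x[[s]] - seq_len(k) + 1)
    }
    max(a, 0)
  }, 0)
}

#' Exact stochastic simulation (Gillespie SSA)
#'
#' Exponential waiting times with propensity-proportional reaction choice,
#' exact for mass-action kinetics.  Returns the full event-time trajectory
#' (or just the endpoint when `record = FALSE`).
#'
#' @param network a [reaction_network()].
#' @param t_max simulated time horizon.
#' @param seed integer seed.
#' @param init optional override of the initial counts.
#' @param record keep the full trajectory (`TRUE`) or only the final
#'   state.
#' @param max_events safety cap on the number of reaction events.
#' @return With `record = TRUE`, a tibble with `time` and one column per
#'   species; otherwise a named vector of final counts.
#' @export
gillespie <- function(network, t_max, seed, init = NULL, record = TRUE,
                      max_events = 1e6) {
  set.seed(derive_seed(seed, "ssa"))
  x <- network$init
  if (!is.null(init)) x[names(init)] <- init
  x <- as.numeric(x)
  names(x) <- network$species
  t <- 0
  rows <- if (record) vector("list", 256) else NULL
  nrow_used <- 0
  push <- function(t, x) {
    nrow_used <<- nrow_used + 1
    if (nrow_used > length(rows)) length(rows) <<- 2 * length(rows)
    rows[[nrow_used]] <<- c(time = t, x)
  }
  if (record) push(t, x)
  # precompute reaction delta vectors
  deltas <- lapply(network$reactions, function(r) {
    d <- stats::setNames(numeric(length(x)), names(x))
    for (s in names(r$reactants)) d[s] <- d[s] - r$reactants[[s]]
    for (s in names(r$products)) d[s] <- d[s] + r$products[[s]]
    d
  })
  ev <- 0
  while (t < t_max && ev < max_events) {
    a <- propensities(network, x)
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > t_max) break
    j <- sample.int(length(a), 1, prob = a)
    x <- x + deltas[[j]]
    ev <- ev + 1
    if (record) push(t, x)
  }
  if (!record) return(x)
  out <- tibble::as_tibble(do.call(rbind, rows[seq_len(nrow_used)]))
  out
}

#' Endpoint datasets from repeated stochastic simulations
#'
#' Runs `n` independent trajectories and collects the molecule counts at
#' `t_max`, one replicate per row — the observational (or, with `do`,
#' interventional) data-generating process of the signaling benchmark.
#' Intervened species are clamped: reactions changing their count are
#' disabled and the count is fixed at the intervention value (the species
#' keeps its catalytic role).
#'
#' @param network a [reaction_network()].
#' @param n number of replicates.
#' @param t_max time horizon per replicate.
#' @param seed integer seed.
#' @param init_fn optional `function(replicate_index)` returning a named
#'   vector of initial-count overrides (used to randomize the exogenous
#'   growth factors across replicates).
#' @param do optional named vector clamping species.
#' @return A tibble with one column per species, plus provenance
#'   attributes.
#' @export
sample_gillespie_dataset <- function(network, n, t_max, seed,
                                     init_fn = NULL, do = NULL) {
  net <- network
  if (!is.null(do)) {
    check_nodes_known(names(do), net$species, "sample_gillespie_dataset()")
    getc <- function(v, s) if (s %in% names(v)) v[[s]] else 0
    keep <- vapply(net$reactions, function(r) {
      sp <- union(names(r$reactants), names(r$products))
      changed <- sp[vapply(sp, function(s)
        getc(r$products, s) - getc(r$reactants, s) != 0, TRUE)]
      # drop reactions that change a clamped species' count
      !any(changed %in% names(do))
    }, TRUE)
    if (!any(keep)) stop("clamping removed every reaction")
    net$reactions <- net$reactions[keep]
    net$init[names(do)] <- do
  }
  set.seed(derive_seed(seed, "ssa_dataset"))
  seeds <- sample.int(2^31 - 2, n)
  rows <- lapply(seq_len(n), function(i) {
    init <- if (!is.null(init_fn)) init_fn(i) else NULL
    if (!is.null(do)) init <- c(init[setdiff(names(init), names(do))], do)
    gillespie(net, t_max, seed = seeds[i], init = init, record = FALSE)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "provenance") <- if (is.null(do)) "gillespie" else
    "gillespie_interventional"
  if (!is.null(do)) attr(out, "do") <- do
  out
}

#' The signaling-benchmark reaction network
#'
#' Mass-action kinetics for the growth-factor cascade: each activating
#' edge contributes a catalytic production reaction (`P -> P + C`), each
#' species a first-order decay, and the repressive Akt-Raf edge a
#' catalyzed degradation (`Akt + Raf -> Akt`).  The exogenous growth
#' factors EGF and IGF carry no reactions — they are inputs, randomized
#' across replicates.  Rates are chosen so that steady-state abundances
#' stay near the initial 100 molecules and relaxation completes well
#' within the simulated horizon; they are plain arguments, not calibrated
#' constants.
#'
#' @param k_prod catalytic production rate per parent molecule.
#' @param k_deg first-order decay rate.
#' @param k_inh rate of the Akt-catalyzed Raf degradation.
#' @return A [reaction_network()].
#' @export
signaling_network <- function(k_prod = 0.05, k_deg = 0.05,
                              k_inh = 5e-4) {
  species <- c("EGF", "IGF", "SOS", "Ras", "PI3K", "Akt", "Raf", "Mek",
               "Erk")
  acts <- list(c("EGF", "SOS"), c("IGF", "SOS"), c("EGF", "PI3K"),
               c("IGF", "PI3K"), c("SOS", "Ras"), c("Ras", "PI3K"),
               c("Ras", "Raf"), c("PI3K", "Akt"), c("Raf", "Mek"),
               c("Mek", "Erk"))
  n_parents <- table(vapply(acts, `[`, "", 2))
  rx <- lapply(acts, function(e) {
    list(reactants = stats::setNames(1L, e[1]),
         products = stats::setNames(c(1L, 1L), c(e[1], e[2])),
         rate = k_prod / n_parents[[e[2]]])
  })
  for (s in setdiff(species, c("EGF", "IGF"))) {
    rx[[length(rx) + 1]] <- list(reactants = stats::setNames(1L, s),
                                 products = stats::setNames(integer(), character()),
                                 rate = k_deg)
  }
  rx[[length(rx) + 1]] <- list(
    reactants = stats::setNames(c(1L, 1L), c("Akt", "Raf")),
    products = stats::setNames(1L, "Akt"), rate = k_inh)
  reaction_network(species, rx)
}

#' Randomized growth-factor initialization
#'
#' Uniform integer initial counts for EGF and IGF in `[lo, hi]` — the
#' replicate-to-replicate variability source of the signaling benchmark.
#'
#' @param lo,hi bounds of the uniform draw.
#' @return A `function(i)` suitable as `init_fn` of
#'   [sample_gillespie_dataset()].
#' @export
random_growth_factor_init <- function(lo = 40, hi = 160) {
  function(i) c(EGF = sample(lo:hi, 1), IGF = sample(lo:hi, 1))
}
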