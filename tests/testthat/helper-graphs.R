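# canonical benchmark ADMGs used across identification tests

bow_admg <- function() parse_graph(c("X -> Y", "X <-> Y"))

frontdoor_admg <- function() parse_graph(c("X -> Z", "Z -> Y", "X <-> Y"))

napkin_admg <- function() {
  parse_graph(c("W2 -> W1", "W1 -> X", "X -> Y",
                "W2 <-> X", "W2 <-> Y"))
}

# multi-cause feed-forward: three causes into one mediator into the effect,
# confounders tie every cause to the effect (bidirected clique via two
# shared latent regulators in the explicit form)
multicause_admg <- function() {
  parse_graph(c("A -> M", "B -> M", "C -> M", "M -> Y",
                "A <-> Y", "B <-> Y", "C <-> Y",
                "A <-> B", "A <-> C", "B <-> C"))
}

max_abs_diff_tables <- function(t1, t2, by) {
  m <- dplyr::inner_join(t1, t2, by = by, suffix = c("_a", "_b"))
  max(abs(m$prob_a - m$prob_b))
}
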