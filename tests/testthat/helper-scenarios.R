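# Scenario builders for small synthetic references (the exported
# heterotroph_scenario targets the full 82-gene complement).

## Evolve signed permutations down a tree by random reversals (Poisson
## number per edge, at least the expectation floor of 0); returns leaf
## permutations and the planted event count.
simulate_perm_evolution <- function(tree, n_blocks = 8, rate = 1, seed = 1) {
  plastrophy:::with_seed(seed, {
    n_tip <- length(tree$tip.label)
    states <- vector("list", n_tip + tree$Nnode)
    states[[n_tip + 1L]] <- seq_len(n_blocks)
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    n_events <- 0L
    for (i in seq_len(nrow(edges))) {
      par <- edges[i, 1]; ch <- edges[i, 2]
      k <- stats::rpois(1, rate)
      p <- states[[par]]
      if (k > 0) {
        for (j in seq_len(k)) {
          ij <- sort(sample.int(n_blocks, 2, replace = TRUE))
          p[ij[1]:ij[2]] <- -rev(p[ij[1]:ij[2]])
        }
      }
      n_events <- n_events + k
      states[[ch]] <- p
    }
    leaves <- states[seq_len(n_tip)]
    names(leaves) <- tree$tip.label
    list(leaves = leaves, n_events = n_events)
  })
}

heterotroph_scenario_small <- function(ref, seed, n_del = 4, n_pseudo = 5,
                                       ir_len = NULL,
                                       fragment_depth = NULL) {
  random_degradation_scenario(ref, n_deletions = n_del,
                              n_pseudogenizations = n_pseudo,
                              ir_len_target = ir_len,
                              fragment_depth = fragment_depth, seed = seed)
}
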