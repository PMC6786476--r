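## Locally collinear blocks (LCBs) across plastomes, signed-permutation
## encodings, and rearrangement distances: signed breakpoint counts and
## exact signed reversal distances (IDA* with the breakpoint-graph cycle
## bound), plus a tree-wide rearrangement total via a local-improvement
## labeling heuristic over a fixed phylogeny.

## anchor table for one genome: single-copy shared genes in positional order
anchor_table <- function(g, anchors) {
  f <- g$features
  f <- f[base_gene_name(f$name) %in% anchors, , drop = FALSE]
  f$anchor <- base_gene_name(f$name)
  f <- f[order(f$start), , drop = FALSE]
  data.frame(anchor = f$anchor, start = f$start, end = f$end,
             sign = ifelse(f$strand == "+", 1L, -1L),
             stringsAsFactors = FALSE)
}

## directed adjacency keys of a linearized signed anchor order
adjacency_keys <- function(tab) {
  n <- nrow(tab)
  if (n < 2) return(character(0))
  a <- tab$anchor; s <- tab$sign
  i <- seq_len(n - 1L); j <- i + 1L
  fwd <- paste0(a[i], ":", s[i], ">", a[j], ":", s[j])
  rev <- paste0(a[j], ":", -s[j], ">", a[i], ":", -s[i])
  c(fwd, rev)
}

## rotate (and reflect if needed) a circular anchor order into the linear
## frame that starts at anchor `a0` with positive sign
rotate_anchor_tab <- function(tab, a0) {
  n <- nrow(tab)
  i <- match(a0, tab$anchor)
  if (tab$sign[i] < 0) {
    tab <- tab[rev(seq_len(n)), , drop = FALSE]
    tab$sign <- -tab$sign
    i <- match(a0, tab$anchor)
  }
  tab[((i - 1L + seq_len(n) - 1L) %% n) + 1L, , drop = FALSE]
}

## circular genomic extent (bp) of a set of member intervals
circular_span <- function(starts, ends, n) {
  if (length(starts) == 1L) return(ends[1] - starts[1])
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  gaps <- c(s[-1] - e[-length(e)], s[1] + n - e[length(e)])
  n - max(gaps)
}

#' Build locally collinear blocks across plastomes
#'
#' Anchors are single-copy genes shared by all genomes (`anchor_mode =
#' "gene"`) or unique shared 31-mers (`anchor_mode = "kmer"`). Maximal runs
#' of anchors that are adjacent and equioriented in every genome become
#' blocks; blocks shorter than `min_block_len` (in the first genome) are
#' discarded and the remaining anchors re-chained.
#'
#' @param genomes named list of [plastome] objects (at least two), with IRs
#'   already collapsed (see [collapse_ir()]).
#' @param anchor_mode `"gene"` or `"kmer"`.
#' @param min_block_len minimum block span (bp) in the reference genome.
#' @return object of class `lcb_set`: `blocks` (data frame `genome`,
#'   `block`, `start`, `end`, `strand`), `n_blocks`, `anchors`.
#' @export
build_lcbs <- function(genomes, anchor_mode = c("gene", "kmer"),
                       min_block_len = 0L) {
  anchor_mode <- match.arg(anchor_mode)
  if (length(genomes) < 2) stop("need at least two genomes")
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  }
  if (anchor_mode == "kmer") {
    genomes <- lapply(genomes, as_kmer_anchor_genome)
  }
  shared <- Reduce(intersect, lapply(genomes, function(g) {
    b <- base_gene_name(g$features$name)
    names(which(table(b) == 1L))
  }))
  if (length(shared) == 0) stop("genomes share no single-copy anchors")
  anchors <- shared
  ngen <- vapply(genomes, genome_length, numeric(1))
  repeat {
    tabs <- lapply(genomes, anchor_table, anchors = anchors)
    ## canonical linear frame: start every genome at the first anchor of
    ## genome 1, oriented positive (rotation/reflection invariance)
    a0 <- tabs[[1]]$anchor[1]
    tabs <- lapply(tabs, rotate_anchor_tab, a0 = a0)
    adj <- Reduce(intersect, lapply(tabs, adjacency_keys))
    ref <- tabs[[1]]
    n <- nrow(ref)
    if (n > 1) {
      i <- seq_len(n - 1L)
      ref_keys <- paste0(ref$anchor[i], ":", ref$sign[i], ">",
                         ref$anchor[i + 1L], ":", ref$sign[i + 1L])
      linked <- ref_keys %in% adj
    } else linked <- logical(0)
    blocks_idx <- split_runs_linear(linked, n)
    ## block spans in reference; drop short blocks and re-chain
    spans <- vapply(blocks_idx, function(ix) {
      circular_span(ref$start[ix], ref$end[ix], ngen[1])
    }, numeric(1))
    if (all(spans >= min_block_len) || length(anchors) <= 2) break
    drop <- unlist(blocks_idx[spans < min_block_len])
    anchors <- setdiff(anchors, ref$anchor[drop])
    if (length(anchors) == 0) stop("no anchors left after min_block_len filter")
  }
  ## assign ids in reference order and locate each block in every genome
  out <- list()
  for (b in seq_along(blocks_idx)) {
    members <- ref$anchor[blocks_idx[[b]]]
    ref_first <- members[1]
    ref_sign_first <- ref$sign[match(ref_first, ref$anchor)]
    for (gname in names(genomes)) {
      tab <- tabs[[gname]]
      ix <- match(members, tab$anchor)
      strand <- if (length(members) == 1L) {
        tab$sign[ix] * ref_sign_first
      } else {
        if (all(diff(ix) == 1L)) 1L else -1L
      }
      out[[length(out) + 1L]] <- data.frame(
        genome = gname, block = b,
        start = min(tab$start[ix]), end = max(tab$end[ix]),
        strand = if (strand >= 0) "+" else "-",
        rank = min(ix), stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, out)
  structure(list(blocks = blocks, n_blocks = length(blocks_idx),
                 anchors = anchors, anchor_mode = anchor_mode),
            class = "lcb_set")
}

## maximal runs of anchors joined by consecutive TRUE links (linear frame);
## linked[i] means anchor i is adjacent to anchor i+1 in all genomes
split_runs_linear <- function(linked, n) {
  if (n == 0) return(list())
  if (n == 1) return(list(1L))
  run_id <- cumsum(c(TRUE, !linked))
  unname(split(seq_len(n), run_id))
}

#' @export
print.lcb_set <- function(x, ...) {
  cat(sprintf("lcb_set: %d blocks over %d genomes (%s anchors: %d)\n",
              x$n_blocks, length(unique(x$blocks$genome)), x$anchor_mode,
              length(x$anchors)))
  invisible(x)
}

## Build a pseudo-genome whose "features" are unique shared 31-mers, so the
## gene-anchor chaining machinery applies unchanged.
as_kmer_anchor_genome <- function(g, k = 31L) {
  n <- genome_length(g)
  doubled <- paste0(g$sequence, g$sequence)
  starts <- seq_len(n) - 1L
  kmers <- substring(doubled, starts + 1L, starts + k)
  rc <- dna_revcomp(kmers)
  canon <- pmin(kmers, rc)
  strand <- ifelse(kmers <= rc, "+", "-")
  keep <- !duplicated(canon) & !duplicated(canon, fromLast = TRUE)
  f <- data.frame(name = canon[keep], gene_class = "other",
                  strand = strand[keep], start = starts[keep],
                  end = starts[keep] + k, status = "unclassified",
                  stringsAsFactors = FALSE)
  f <- f[f$start + k <= n | TRUE, , drop = FALSE]
  f$end <- pmin(f$end, f$start + k)
  plastome(g$id, g$sequence, circular = g$circular,
           features = f[order(f$start), , drop = FALSE])
}

#' Signed permutations from an LCB set
#'
#' Each genome's block order is encoded as a signed permutation in the
#' frame of the first genome (the identity `+1..+n`). Circular orders are
#' linearized at block 1, oriented positive.
#'
#' @param lcbs an `lcb_set`.
#' @return named list of signed integer vectors.
#' @export
lcb_permutations <- function(lcbs) {
  b <- lcbs$blocks
  out <- list()
  for (g in unique(b$genome)) {
    sub <- b[b$genome == g, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    perm <- ifelse(sub$strand == "+", 1L, -1L) * sub$block
    out[[g]] <- canonicalize_circular_perm(perm)
  }
  out
}

## rotate (and possibly reflect) a circular signed permutation so that
## block 1 comes first with positive sign
canonicalize_circular_perm <- function(perm) {
  i <- which(abs(perm) == 1L)
  stopifnot(length(i) == 1L)
  n <- length(perm)
  perm <- perm[((i - 1L + seq_len(n) - 1L) %% n) + 1L]
  if (perm[1] < 0) {
    perm <- c(perm[1], rev(perm[-1]))
    perm <- -perm
  }
  perm
}

check_same_blocks <- function(a, b) {
  if (length(a) != length(b) || !setequal(abs(a), abs(b)) ||
      anyDuplicated(abs(a)) || anyDuplicated(abs(b))) {
    stop("permutations are not over the same block set")
  }
}

signed_adjacencies <- function(perm, framing = "linear") {
  n <- length(perm)
  seqn <- if (framing == "linear") c(0L, perm, n + 1L) else perm
  m <- length(seqn)
  pairs <- cbind(seqn[-m], seqn[-1])
  if (framing == "circular") pairs <- rbind(pairs, c(seqn[m], seqn[1]))
  apply(pairs, 1, function(p) {
    alt <- c(-p[2], -p[1])
    if (alt[1] < p[1] || (alt[1] == p[1] && alt[2] < p[2])) p <- alt
    paste(p, collapse = ",")
  })
}

#' Signed breakpoint distance
#'
#' Number of signed adjacencies (including orientation; an adjacency and
#' its reverse complement are identified) present in `perm_a` but not in
#' `perm_b`. Linear framing adds end caps `0` and `n+1`; circular framing
#' closes the order instead.
#'
#' @param perm_a,perm_b signed integer permutations over the same blocks.
#' @param framing `"linear"` (default) or `"circular"`.
#' @return integer breakpoint count.
#' @export
breakpoint_distance <- function(perm_a, perm_b,
                                framing = c("linear", "circular")) {
  framing <- match.arg(framing)
  check_same_blocks(perm_a, perm_b)
  a <- signed_adjacencies(perm_a, framing)
  b <- signed_adjacencies(perm_b, framing)
  sum(!(a %in% b))
}

## relabel so that perm_b becomes the identity
relabel_to_identity <- function(perm_a, perm_b) {
  n <- length(perm_b)
  pos <- integer(n); sgn <- integer(n)
  pos[abs(perm_b)] <- seq_len(n)
  sgn[abs(perm_b)] <- sign(perm_b)
  pos[abs(perm_a)] * sign(perm_a) * sgn[abs(perm_a)]
}

#' Exact signed reversal distance
#'
#' Minimum number of signed segment reversals transforming `perm_a` into
#' `perm_b` (linear framing). Exact search (iterative deepening guided by
#' the breakpoint-graph cycle bound) is used up to `exact_cap` blocks; for
#' larger instances the cycle lower bound is returned only when
#' `approximate = TRUE`.
#'
#' @param perm_a,perm_b signed permutations over the same blocks.
#' @param exact_cap maximum size for exact search (default 10).
#' @param approximate return the lower bound for large instances.
#' @return integer distance; attributes `exact` (logical) and
#'   `lower_bound`.
#' @export
reversal_distance <- function(perm_a, perm_b = seq_along(perm_a),
                              exact_cap = 10L, approximate = FALSE) {
  check_same_blocks(perm_a, perm_b)
  cp <- relabel_to_identity(perm_a, perm_b)
  lb <- .cycle_lower_bound_cpp(as.integer(cp))
  if (length(cp) <= exact_cap) {
    d <- .reversal_distance_cpp(as.integer(cp))
    return(structure(d, exact = TRUE, lower_bound = lb))
  }
  if (!approximate) {
    stop("instance larger than exact_cap; set approximate = TRUE for the ",
         "cycle lower bound")
  }
  structure(lb, exact = FALSE, lower_bound = lb)
}

#' Tree-wide rearrangement count
#'
#' Assigns a signed permutation to every internal node of a fixed rooted
#' tree by local improvement: nodes are initialized to descendant leaf
#' labels and repeatedly relabeled, first from the pool of observed leaf
#' labels and then by single-reversal perturbations of the current label,
#' whenever a move lowers the summed reversal distance to the node's
#' neighbors; sweeps repeat until no move improves. Branch distances are
#' then summed. The result is an upper bound on the true minimum
#' (heuristic, flagged in the output) and at least the maximum pairwise
#' leaf distance.
#'
#' @param tree an `ape::phylo` tree.
#' @param leaf_permutations named list of signed permutations, names
#'   matching tip labels.
#' @return list: `total`, `per_branch` (data frame `parent`, `child`,
#'   `distance`), `node_labels`, `heuristic = TRUE`.
#' @export
count_tree_rearrangements <- function(tree, leaf_permutations) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!setequal(tips, names(leaf_permutations))) {
    stop("leaf labels do not match permutation names")
  }
  n_tip <- length(tips)
  n_node <- tree$Nnode
  labels <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) labels[[i]] <- leaf_permutations[[tips[i]]]
  candidates <- unique(leaf_permutations)
  memo <- new.env(parent = emptyenv())
  dist_fn <- function(p, q) {
    key <- paste(c(p, 99L, q), collapse = ",")
    key2 <- paste(c(q, 99L, p), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (!is.null(memo[[key2]])) return(memo[[key2]])
    d <- as.integer(reversal_distance(p, q))
    memo[[key]] <- d
    d
  }
  ## neighbors from the edge list
  edges <- tree$edge
  nbrs <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  ## initialize internal labels exactly over the observed label pool
  ## (Sankoff dynamic programming with the reversal-distance cost matrix)
  root <- n_tip + 1L
  internal_post <- rev(sort(unique(edges[, 1])))
  sankoff_assign <- function(pool) {
    nlab <- length(pool)
    D <- matrix(0, nlab, nlab)
    for (i in seq_len(nlab)) for (j in seq_len(nlab)) {
      if (i < j) D[i, j] <- D[j, i] <- dist_fn(pool[[i]], pool[[j]])
    }
    leaf_lab <- vapply(seq_len(n_tip), function(i) {
      which(vapply(pool, identical, logical(1), labels[[i]]))[1]
    }, integer(1))
    cost <- matrix(Inf, n_tip + n_node, nlab)
    cost[cbind(seq_len(n_tip), leaf_lab)] <- 0
    choice <- array(NA_integer_, c(n_tip + n_node, nlab,
                                   max(table(edges[, 1]))))
    for (nd in internal_post) {
      ch <- edges[edges[, 1] == nd, 2]
      for (l in seq_len(nlab)) {
        tot <- 0
        for (ci in seq_along(ch)) {
          v <- cost[ch[ci], ] + D[l, ]
          best <- which.min(v)
          choice[nd, l, ci] <- best
          tot <- tot + v[best]
        }
        cost[nd, l] <- tot
      }
    }
    assign_down <- function(nd, l) {
      labels[[nd]] <<- pool[[l]]
      ch <- edges[edges[, 1] == nd, 2]
      for (ci in seq_along(ch)) {
        if (ch[ci] > n_tip) assign_down(ch[ci], choice[nd, l, ci])
      }
    }
    assign_down(root, which.min(cost[root, ]))
  }
  ## enrich the label pool with intermediate states along one optimal
  ## reversal path between each pair of distinct leaf labels: these are
  ## natural median candidates that pure leaf labels cannot supply
  path_states <- function(a, b) {
    out <- list()
    cur <- a
    d <- dist_fn(cur, b)
    nb <- length(a)
    while (d > 1) {
      advanced <- FALSE
      for (i in seq_len(nb)) {
        for (j in i:nb) {
          q <- cur; q[i:j] <- -rev(q[i:j])
          if (dist_fn(q, b) == d - 1L) {
            cur <- q; d <- d - 1L
            out[[length(out) + 1L]] <- q
            advanced <- TRUE
            break
          }
        }
        if (advanced) break
      }
      if (!advanced) break
    }
    out
  }
  if (length(candidates) > 1) {
    extra <- list()
    for (i in seq_along(candidates)) {
      for (j in seq_len(i - 1L)) {
        extra <- c(extra, path_states(candidates[[i]], candidates[[j]]))
      }
    }
    candidates <- unique(c(candidates, extra))
  }
  sankoff_assign(candidates)
  internal <- sort(unique(edges[, 1]))
  nblocks <- length(labels[[1]])
  one_reversal_moves <- function(p) {
    out <- list()
    for (i in seq_len(nblocks)) {
      for (j in i:nblocks) {
        q <- p
        q[i:j] <- -rev(q[i:j])
        out[[length(out) + 1L]] <- q
      }
    }
    out
  }
  neighbor_cost <- function(nd, lab) {
    nb <- nbrs[[as.character(nd)]]
    sum(vapply(nb, function(x) dist_fn(lab, labels[[x]]), numeric(1)))
  }
  total_now <- function() {
    sum(vapply(seq_len(nrow(edges)), function(i)
      dist_fn(labels[[edges[i, 1]]], labels[[edges[i, 2]]]), numeric(1)))
  }
  ## alternate single-reversal hill climbing on node labels with Sankoff
  ## re-optimization over the enlarged label pool, until neither improves
  pool <- candidates
  sweep_once <- function() {
    improved <- FALSE
    for (nd in internal) {
      cur <- neighbor_cost(nd, labels[[nd]])
      for (cand in c(pool, one_reversal_moves(labels[[nd]]))) {
        alt <- neighbor_cost(nd, cand)
        if (alt < cur) {
          labels[[nd]] <<- cand
          cur <- alt
          improved <- TRUE
        }
      }
    }
    improved
  }
  descend <- function() {
    repeat {
      if (!sweep_once()) break
    }
    ## grow the pool with the refined labels and with optimal-path states
    ## bridging each node to its neighbors, then re-optimize exactly over
    ## the enlarged pool
    repeat {
      bridge <- list()
      for (nd in internal) {
        for (x in nbrs[[as.character(nd)]]) {
          bridge <- c(bridge, path_states(labels[[nd]], labels[[x]]))
        }
      }
      pool <<- unique(c(pool, labels[internal], bridge))
      before <- total_now()
      sankoff_assign(pool)
      while (sweep_once()) NULL
      if (total_now() >= before) break
    }
    total_now()
  }
  best_total <- descend()
  best_labels <- labels[internal]
  ## restarts from uniform leaf-label initializations
  for (cand in unique(leaf_permutations)) {
    for (nd in internal) labels[[nd]] <- cand
    t2 <- descend()
    if (t2 < best_total) {
      best_total <- t2
      best_labels <- labels[internal]
    }
  }
  labels[internal] <- best_labels
  ## seeded perturbation restarts: kick converged labels by random
  ## reversals and re-descend, keeping the best labeling found
  with_seed(20230617L, {
    for (kick in 1:8) {
      for (nd in internal) {
        for (m in seq_len(sample(1:2, 1))) {
          ij <- sort(sample.int(nblocks, 2, replace = TRUE))
          p <- labels[[nd]]
          p[ij[1]:ij[2]] <- -rev(p[ij[1]:ij[2]])
          labels[[nd]] <- p
        }
      }
      t2 <- descend()
      if (t2 < best_total) {
        best_total <- t2
        best_labels <- labels[internal]
      } else {
        labels[internal] <- best_labels
      }
    }
  })
  labels[internal] <- best_labels
  per_branch <- data.frame(
    parent = edges[, 1], child = edges[, 2],
    distance = vapply(seq_len(nrow(edges)), function(i)
      dist_fn(labels[[edges[i, 1]]], labels[[edges[i, 2]]]), numeric(1)))
  list(total = sum(per_branch$distance), per_branch = per_branch,
       node_labels = labels, heuristic = TRUE)
}
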