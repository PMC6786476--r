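test_that("collapse_ir removes one copy and keeps the other's features", {
  ref <- small_reference(71)
  noir <- partition_quadripartite(ref$genome, NULL)
  expect_identical(collapse_ir(ref$genome, noir)$sequence,
                   ref$genome$sequence)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 3000), seed = 71)
  map <- partition_quadripartite(deg$genome,
                                 list(ira = deg$planted$ira,
                                      irb = deg$planted$irb))
  coll <- collapse_ir(deg$genome, map)
  L <- deg$planted$ira[2] - deg$planted$ira[1]
  expect_equal(genome_length(coll), genome_length(deg$genome) - L)
  ## the IR-duplicated copies in one repeat are gone, the others retained
  n_dup <- sum(endsWith(deg$genome$features$name, "_ir"))
  expect_gt(n_dup, 0)
  base_names <- plastrophy:::base_gene_name(coll$features$name)
  expect_false(anyDuplicated(base_names) > 0)
  expect_equal(nrow(coll$features), nrow(deg$genome$features) - n_dup)
})

test_that("LCB construction: identical genomes, planted inversion, truth boundaries", {
  ref <- small_reference(72)
  g <- ref$genome
  g2 <- g; g2$id <- "b"
  one <- build_lcbs(list(a = g, b = g2))
  expect_equal(one$n_blocks, 1)
  f <- g$features[order(g$features$start), ]
  scen <- degradation_scenario(inversions = list(c(f$name[8], f$name[12])))
  deg <- degrade_plastome(ref, scen, seed = 72)
  lc <- build_lcbs(list(ref = g, inv = deg$genome))
  expect_equal(lc$n_blocks, 3)
  pp <- lcb_permutations(lc)
  expect_identical(pp$ref, 1:3)
  expect_identical(abs(pp$inv), 1:3)
  expect_equal(sum(pp$inv < 0), 1)
  ## block boundaries near the planted inversion interval (one intergene)
  inv_iv <- deg$planted$inversions[[1]]
  blk <- lc$blocks[lc$blocks$genome == "inv" & lc$blocks$strand == "-", ]
  expect_lt(abs(blk$start - inv_iv[1]), 500)
  expect_lt(abs(inv_iv[2] - blk$end), 500)
  expect_error(build_lcbs(list(a = g)), "at least")
})

test_that("k-mer anchoring reproduces gene-anchor blocks on a planted inversion", {
  ref <- small_reference(73, n_protein = 10, n_trna = 2, n_rrna = 1)
  f <- ref$genome$features[order(ref$genome$features$start), ]
  scen <- degradation_scenario(inversions = list(c(f$name[4], f$name[6])))
  deg <- degrade_plastome(ref, scen, seed = 73)
  lc <- build_lcbs(list(ref = ref$genome, inv = deg$genome),
                   anchor_mode = "kmer", min_block_len = 300)
  pp <- lcb_permutations(lc)
  expect_equal(lc$n_blocks, 3)
  expect_equal(sum(pp$inv < 0), 1)
})

test_that("breakpoint distance counts missing signed adjacencies", {
  expect_equal(breakpoint_distance(c(1L, 2L, 3L), c(1L, 2L, 3L)), 0)
  expect_equal(breakpoint_distance(c(1L, -2L, 3L), c(1L, 2L, 3L)), 2)
  expect_error(breakpoint_distance(c(1L, 2L), c(1L, 2L, 3L)), "block set")
  ## adjacency-set oracle on random pairs
  for (i in 1:30) {
    set.seed(7300 + i)
    n <- sample(3:8, 1)
    a <- random_signed_perm(n); b <- random_signed_perm(n)
    adj <- function(p) {
      x <- c(0L, p, n + 1L)
      keys <- character(0)
      for (j in seq_len(length(x) - 1)) {
        pr <- c(x[j], x[j + 1]); al <- c(-pr[2], -pr[1])
        if (al[1] < pr[1] || (al[1] == pr[1] && al[2] < pr[2])) pr <- al
        keys <- c(keys, paste(pr, collapse = ","))
      }
      keys
    }
    expect_equal(breakpoint_distance(a, b), sum(!(adj(a) %in% adj(b))))
  }
})

test_that("reversal distance: trivia, exhaustive BFS agreement, bounds, metric", {
  expect_equal(as.integer(reversal_distance(c(1L, 2L, 3L))), 0)
  p <- c(1L, 2L, 3L, 4L); p[2:3] <- -rev(p[2:3])
  expect_equal(as.integer(reversal_distance(p)), 1)
  ## pure-R BFS oracle, all signed permutations n <= 4
  for (n in 2:4) {
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ,
                   drop = FALSE]
    signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
    for (i in seq_len(nrow(perms))) {
      for (j in seq_len(nrow(signs))) {
        pp <- as.integer(perms[i, ] * signs[j, ])
        expect_equal(as.integer(reversal_distance(pp)),
                     oracle_reversal_distance(pp))
      }
    }
  }
  ## bounds and metric properties on random instances
  for (i in 1:40) {
    set.seed(7400 + i)
    n <- sample(4:8, 1)
    a <- random_signed_perm(n); b <- random_signed_perm(n)
    cc <- random_signed_perm(n)
    dab <- as.integer(reversal_distance(a, b))
    bp <- breakpoint_distance(a, b)
    expect_gte(dab, ceiling(bp / 2))
    expect_lte(dab, bp)
    expect_equal(dab, as.integer(reversal_distance(b, a)))
    expect_lte(dab, as.integer(reversal_distance(a, cc)) +
                 as.integer(reversal_distance(cc, b)))
  }
  expect_error(reversal_distance(random_signed_perm(12)), "exact_cap")
  lb <- reversal_distance(random_signed_perm(12), approximate = TRUE)
  expect_false(attr(lb, "exact"))
})

test_that("tree rearrangement totals: trivia, two-leaf reduction, invariance", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  id <- 1:4
  same <- list(a = id, b = id, c = id, d = id)
  expect_equal(count_tree_rearrangements(tr, same)$total, 0)
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  pa <- c(1L, -3L, -2L, 4L)
  two <- count_tree_rearrangements(tr2, list(a = id, b = pa))
  expect_equal(two$total, as.integer(reversal_distance(pa, id)))
  ## leaf input order does not matter
  perms <- list(a = id, b = pa, c = c(2L, 1L, 3L, 4L) * c(1L, -1L, 1L, 1L),
                d = id)
  t1 <- count_tree_rearrangements(tr, perms)$total
  t2 <- count_tree_rearrangements(tr, perms[c(3, 1, 4, 2)])$total
  expect_equal(t1, t2)
  expect_error(count_tree_rearrangements(tr, perms[1:3]), "labels")
})

test_that("planted tree scenarios satisfy the sandwich bounds", {
  for (rep in 1:5) {
    set.seed(7500 + rep)
    tr <- ape::rtree(6)
    sim <- simulate_perm_evolution(tr, n_blocks = 8,
                                   rate = 1.2, seed = 7600 + rep)
    res <- count_tree_rearrangements(tr, sim$leaves)
    pairmax <- 0
    leaves <- sim$leaves
    for (i in seq_along(leaves)) for (j in seq_len(i - 1)) {
      pairmax <- max(pairmax, as.integer(
        reversal_distance(leaves[[i]], leaves[[j]])))
    }
    expect_lte(res$total, sim$n_events)
    expect_gte(res$total, pairmax)
  }
})
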