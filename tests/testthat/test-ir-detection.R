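test_that("random sequences yield no large inverted candidates", {
  set.seed(41)
  x <- rnd_dna(20000)
  expect_equal(nrow(find_inverted_candidates(x, min_len = 1000)), 0)
  expect_error(find_inverted_candidates(x, min_len = 20), "min_len")
})

test_that("planted inverted copies are found at exact coordinates, longest first", {
  set.seed(42)
  X <- rnd_dna(9000)
  Y <- rnd_dna(2000)
  s <- paste0(rnd_dna(3000), X, rnd_dna(2500), Y, rnd_dna(2000),
              rc(Y), rnd_dna(1500), rc(X), rnd_dna(2500))
  cands <- find_inverted_candidates(s, min_len = 1000)
  expect_gte(nrow(cands), 2)
  expect_true(all(diff(cands$length) <= 0))
  expect_gte(cands$length[1], 9000)   # chance extension possible
  expect_lte(abs(cands$start_a[1] - 3000), 2)
})

test_that("coverage profile counts read bases with circular wrap", {
  empty <- coverage_profile(
    data.frame(qname = character(), mate = integer(), pos = integer(),
               strand = character(), len = integer(), mapped = logical()),
    1000)
  expect_true(all(empty$depth == 0))
  one <- coverage_profile(
    data.frame(qname = "r", mate = 1L, pos = 0L, strand = "+", len = 150L,
               mapped = TRUE), 1000)
  expect_equal(sum(one$depth), 150)
  expect_true(all(one$depth[1:150] == 1) && all(one$depth[151:1000] == 0))
  wrap <- coverage_profile(
    data.frame(qname = "r", mate = 1L, pos = 950L, strand = "+", len = 100L,
               mapped = TRUE), 1000)
  expect_equal(sum(wrap$depth), 100)
  expect_true(all(wrap$depth[951:1000] == 1) && all(wrap$depth[1:50] == 1))
  expect_error(coverage_profile(
    data.frame(qname = "r", mate = 1L, pos = 1200L, strand = "+",
               len = 100L, mapped = TRUE), 1000), "range")
})

test_that("split-pair evidence supports all four junctions of a true IR", {
  ref <- small_reference(43)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 4000), seed = 43)
  reads <- simulate_reads(deg$genome, coverage = 80, error_rate = 0.005,
                          seed = 44)
  pl <- map_reads(reads, deg$genome)
  cand <- data.frame(start_a = deg$planted$ira[1],
                     start_b = deg$planted$irb[1],
                     length = deg$planted$ira[2] - deg$planted$ira[1])
  ev <- split_pair_evidence(pl, cand, genome_length(deg$genome))
  expect_true(all(ev$junction_support >= 5))
  expect_gt(ev$n_split_pairs, 0)
  expect_error(split_pair_evidence(pl[pl$mate == 1, ], cand,
                                   genome_length(deg$genome)), "unpaired")
})

test_that("no-IR genomes give zero split support and no call", {
  ref <- small_reference(45)
  reads <- simulate_reads(ref$genome, coverage = 40, seed = 45)
  pl <- map_reads(reads, ref$genome)
  fake <- data.frame(start_a = 1000L, start_b = 12000L, length = 2000L)
  ev <- split_pair_evidence(pl, fake, genome_length(ref$genome))
  expect_equal(ev$n_split_pairs, 0)
  det <- detect_ir(ref$genome, reads)
  expect_null(det$call)
})

test_that("call_ir enforces length and evidence thresholds", {
  expect_null(call_ir(NULL, genome_len = 1000))
  cands <- data.frame(start_a = 0L, start_b = 5000L, length = 400L,
                      mismatches = 0L)
  splits <- list(list(junction_support = c(ira_left = 50, ira_right = 50,
                                           irb_left = 50, irb_right = 50)))
  expect_null(call_ir(cands, splits = splits, genome_len = 20000,
                      min_ir_len = 1000))
  cands$length <- 2000L
  got <- call_ir(cands, splits = splits, genome_len = 20000,
                 min_ir_len = 1000)
  expect_s3_class(got, "ir_call")
  expect_equal(got$accepted_by, "split_pairs")
  splits[[1]]$junction_support["irb_left"] <- 1
  expect_null(call_ir(cands, splits = splits, genome_len = 20000))
})

test_that("collapsed assemblies show the ~2x coverage signature", {
  ref <- small_reference(46)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 4000), seed = 46)
  reads <- simulate_reads(deg$genome, coverage = 60, error_rate = 0.005,
                          seed = 47)
  map <- partition_quadripartite(deg$genome,
                                 list(ira = deg$planted$ira,
                                      irb = deg$planted$irb))
  coll <- collapse_ir(deg$genome, map)
  pl <- map_reads(reads, coll)
  prof <- coverage_profile(pl, genome_length(coll))
  ## locate the surviving IR copy in the collapsed genome by its sequence
  ira_seq <- plastrophy:::extract_circular(deg$genome$sequence,
                                           deg$planted$ira[1],
                                           deg$planted$ira[2])
  hit <- regexpr(ira_seq, paste0(coll$sequence, coll$sequence),
                 fixed = TRUE)
  if (hit < 0) {
    hit <- regexpr(rc(ira_seq), paste0(coll$sequence, coll$sequence),
                   fixed = TRUE)
  }
  expect_gt(hit, 0)
  ira_in_coll <- c(hit - 1L, hit - 1L + nchar(ira_seq))
  ratio <- coverage_ratio(prof, ira_in_coll)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("IR detection is rotation invariant", {
  ref <- small_reference(48)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 3000), seed = 48)
  n <- genome_length(deg$genome)
  shift <- 7321L
  rot <- rotate_plastome(deg$genome, shift)
  c1 <- find_inverted_candidates(deg$genome)
  c2 <- find_inverted_candidates(rot)
  expect_equal(nrow(c1), nrow(c2))
  expect_setequal(sort(c((c1$start_a - shift) %% n, (c1$start_b - shift) %% n)),
                  sort(c(c2$start_a, c2$start_b)))
  expect_equal(sort(c1$length), sort(c2$length))
})
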