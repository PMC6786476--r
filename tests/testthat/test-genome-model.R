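test_that("FASTA/GFF3 round trip preserves sequence and coordinates", {
  set.seed(11)
  g <- plastome("toy", rnd_dna(1000), features = data.frame(
    name = c("atpA", "trnH-GUG", "wrapGene"),
    strand = c("+", "-", "+"),
    start = c(10L, 400L, 990L),
    end = c(100L, 475L, 1010L),   # wrapGene crosses the origin
    status = "unclassified"))
  fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gf)
  g2 <- read_genome(fa, gf)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features$start, g$features$start)
  expect_identical(g2$features$end, g$features$end)
  expect_identical(g2$features$strand, g$features$strand)
  ## GFF3 emits 1-based inclusive
  lines <- readLines(gf)
  expect_true(any(grepl("\t11\t100\t", lines)))  # atpA at [10,100) -> 11..100
})

test_that("wrapped intervals match tail+head concatenation and doubled sequence", {
  set.seed(12)
  s <- rnd_dna(1000)
  g <- plastome("toy", s, features = data.frame(
    name = "w", strand = "+", start = 990L, end = 1010L,
    status = "unclassified"))
  got <- feature_seq(g, "w")
  expect_identical(nchar(got), 20L)
  expect_identical(got, paste0(substr(s, 991, 1000), substr(s, 1, 10)))
  expect_identical(got, substr(paste0(s, s), 991, 1010))
})

test_that("invalid feature tables are rejected", {
  s <- rnd_dna(100)
  expect_error(plastome("x", s, features = data.frame(
    name = c("a", "a"), strand = "+", start = c(0L, 10L),
    end = c(5L, 20L), status = "unclassified")), "duplicate")
  expect_error(plastome("x", s, features = data.frame(
    name = "a", strand = "+", start = 200L, end = 210L,
    status = "unclassified")), "range")
})

test_that("quadripartite partition reproduces the worked example and sums to genome length", {
  ## LSC 38,859 / SSC 27,947 / IR 9,256 each on an 85,318-bp circle
  n <- 85318L
  ira <- c(38859L, 38859L + 9256L)
  irb <- c(38859L + 9256L + 27947L, 38859L + 9256L + 27947L + 9256L)
  g <- plastome("worked", substr(strrep("ACGT", 21330), 1, n))
  map <- partition_quadripartite(g, list(ira = ira, irb = irb))
  expect_equal(unname(map$lengths["lsc"]), 38859)
  expect_equal(unname(map$lengths["ssc"]), 27947)
  expect_equal(unname(map$lengths["ira"]), 9256)
  expect_equal(sum(map$lengths), 85318)
})

test_that("degenerate and erroneous IR inputs are handled", {
  g <- plastome("x", rnd_dna(5000))
  map <- partition_quadripartite(g, NULL)
  expect_true(map$degenerate)
  expect_equal(unname(map$lengths["lsc"]), 5000)
  expect_error(
    partition_quadripartite(g, list(ira = c(0, 100), irb = c(50, 150))),
    "overlap")
})

test_that("partition recovers planted IR intervals exactly (generator truth)", {
  ref <- small_reference(31)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 4000), seed = 32)
  map <- partition_quadripartite(
    deg$genome, list(ira = deg$planted$ira, irb = deg$planted$irb))
  expect_equal(sum(map$lengths), genome_length(deg$genome))
  got <- sort(c(map$ira[1] %% genome_length(deg$genome),
                map$irb[1] %% genome_length(deg$genome)))
  expect_equal(got, sort(c(deg$planted$ira[1], deg$planted$irb[1])))
})

test_that("coding-capacity summary counts unique genes by type", {
  ## 33 + 31 + 4 intact unique genes = 68
  feats <- data.frame(
    name = c(PLASTID_PROTEIN_GENES[1:33], PLASTID_TRNA_GENES[1:31],
             PLASTID_RRNA_GENES),
    strand = "+", start = seq(0, by = 100, length.out = 68),
    end = seq(0, by = 100, length.out = 68) + 90, status = "intact")
  g <- plastome("p", rnd_dna(7000), features = feats)
  s <- summarize_coding_capacity(g)
  expect_equal(s$n_intact_unique, 68)
  expect_equal(unname(s$by_type["protein", "intact"]), 33)
  expect_equal(unname(s$by_type["trna", "intact"]), 31)
  expect_equal(unname(s$by_type["rrna", "intact"]), 4)
})

test_that("summary deduplicates IR copies, errors on unclassified, zero on empty", {
  feats <- data.frame(name = c("rpl2", "rpl2_ir", "matK"), strand = "+",
                      start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
                      status = c("intact", "intact", "pseudogene"))
  g <- plastome("p", rnd_dna(1000), features = feats)
  s <- summarize_coding_capacity(g)
  expect_equal(s$n_unique, 2)
  expect_equal(s$n_intact_unique, 1)
  g$features$status[1] <- "unclassified"
  expect_error(summarize_coding_capacity(g), "unclassified")
  e <- summarize_coding_capacity(plastome("e", rnd_dna(100)))
  expect_equal(e$n_unique, 0)
})

test_that("rotation shifts all coordinates by the same offset mod n", {
  ref <- small_reference(33)
  g <- ref$genome
  r <- rotate_plastome(g, 1234)
  n <- genome_length(g)
  expect_identical(
    sort((g$features$start - 1234) %% n),
    sort(r$features$start %% n))
  expect_identical(feature_seq(g, "atpA"), feature_seq(r, "atpA"))
})
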