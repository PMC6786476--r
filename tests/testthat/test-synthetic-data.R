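test_that("reference generator is deterministic and builds valid ORFs", {
  a <- make_reference_plastome(seed = 7)
  b <- make_reference_plastome(seed = 7)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_equal(nrow(a$genome$features), 82 + 32 + 4)
  prot <- a$genome$features$name[
    gene_type_of(a$genome$features$gene_class) == "protein"]
  for (g in sample(prot, 12)) {
    cds <- feature_seq(a$genome, g)
    expect_true(startsWith(cds, "ATG"))
    aa <- plastrophy:::translate_dna(cds)
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    expect_true(endsWith(aa, "*"))
  }
})

test_that("empty scenario leaves the reference untouched", {
  ref <- small_reference(21)
  deg <- degrade_plastome(ref, degradation_scenario(), seed = 1)
  expect_identical(deg$genome$sequence, ref$genome$sequence)
  expect_true(all(deg$truth$status == "intact"))
})

test_that("heterotroph scenario leaves 33 intact proteins of 82 (49 lost)", {
  ref <- make_reference_plastome(seed = 5)
  scen <- heterotroph_scenario(ref, seed = 5)
  deg <- degrade_plastome(ref, scen, seed = 5)
  tr <- deg$truth
  prot <- tr[gene_type_of(gene_class_of(tr$gene)) == "protein", ]
  expect_equal(nrow(prot), 82)
  expect_equal(sum(prot$status == "intact"), 33)
  expect_equal(sum(prot$status != "intact"), 49)
  trna <- tr[gene_class_of(tr$gene) == "trna", ]
  expect_equal(sum(trna$status == "absent"), 1)
  expect_equal(trna$gene[trna$status == "absent"], "trnR-CCG")
})

test_that("IR insertion grows the genome by the segment and plants a revcomp copy", {
  ref <- small_reference(22)
  len0 <- genome_length(ref$genome)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 5000), seed = 3)
  L <- deg$planted$ira[2] - deg$planted$ira[1]
  expect_equal(genome_length(deg$genome), len0 + L)
  a <- plastrophy:::extract_circular(deg$genome$sequence,
                                     deg$planted$ira[1], deg$planted$ira[2])
  b <- plastrophy:::extract_circular(deg$genome$sequence,
                                     deg$planted$irb[1], deg$planted$irb[2])
  expect_identical(a, rc(b))
  ## planted boundaries are exactly maximal: one-base extension breaks
  s <- deg$genome$sequence; n <- nchar(s)
  at <- function(p) substr(s, (p %% n) + 1, (p %% n) + 1)
  expect_false(at(deg$planted$ira[1] - 1) ==
                 chartr("ACGT", "TGCA", at(deg$planted$irb[2])))
  expect_false(at(deg$planted$ira[2]) ==
                 chartr("ACGT", "TGCA", at(deg$planted$irb[1] - 1)))
})

test_that("lesion on a deleted gene is rejected", {
  expect_error(degradation_scenario(
    deletions = "psbA", pseudogenizations = c(psbA = "premature_stop")),
    "deleted")
})

test_that("read counts, exactness and realized depth follow the model", {
  ref <- small_reference(23)
  g <- ref$genome
  L <- genome_length(g)
  expect_equal(length(simulate_reads(g, coverage = 0, seed = 1)), 0)
  expect_error(simulate_reads(g, 10, read_len = 700, insert_mean = 650))
  rs <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 2)
  expect_equal(nrow(rs$pairs), round(30 * L / (2 * 150)))
  ## with zero error every read is an exact substring of the doubled
  ## sequence or its reverse complement
  doubled <- paste0(g$sequence, g$sequence)
  idx <- sample(nrow(rs$pairs), 40)
  for (i in idx) {
    r <- rs$pairs$mate1[i]
    expect_true(grepl(r, doubled, fixed = TRUE) ||
                  grepl(rc(r), doubled, fixed = TRUE))
  }
  ## realized depth within 5% of target after mapping back
  pl <- map_reads(rs, g)
  prof <- coverage_profile(pl, L)
  expect_lt(abs(mean(prof$depth) - 30) / 30, 0.05)
})

test_that("insert fragments are confined to a window at the requested depth", {
  ref <- small_reference(24)
  prot <- ref$genome$features$name[
    gene_type_of(ref$genome$features$gene_class) == "protein"]
  lens <- ref$genome$features$end - ref$genome$features$start
  gene <- prot[which.max(lens[match(prot, ref$genome$features$name)])]
  glen <- nchar(feature_seq(ref$genome, gene))
  expect_equal(length(simulate_insert_fragments(
    ref, gene, 0.5, relative_depth = 0, main_coverage = 50, seed = 1)), 0)
  fr <- simulate_insert_fragments(ref, gene, 0.5, relative_depth = 0.3,
                                  main_coverage = 100, seed = 2)
  win <- attr(fr, "window")
  expect_equal(win[2] - win[1], max(150, floor(0.5 * glen)))
  ## map back to the CDS: footprint confined to the window, depth ~ 30
  pl <- map_reads(fr, feature_seq(ref$genome, gene), circular = FALSE,
                  seed_len = 21)
  pl <- pl[pl$mapped, ]
  expect_gte(min(pl$pos), win[1])
  expect_lte(max(pl$pos + pl$len), win[2])
  prof <- coverage_profile(pl, glen, circular = FALSE)
  realized <- mean(prof$depth[(win[1] + 1):win[2]])
  expect_lt(abs(realized - 30) / 30, 0.2)
})

test_that("trait simulation matches Brownian expectations", {
  ## zero-length tree: tips equal the root state
  tr <- ape::read.tree(text = "(a:0,b:0);")
  tt <- simulate_traits(tr, diag(2), root_state = c(3, -2), seed = 1)
  expect_equal(tt$x, c(3, 3))
  expect_equal(tt$y, c(-2, -2))
  ## tip variance ~ branch length, uncorrelated increments near 0
  tr2 <- ape::read.tree(text = "(a:2.5,b:2.5);")
  xs <- ys <- numeric(3000)
  for (i in 1:3000) {
    s <- simulate_traits(tr2, diag(2), seed = i)
    xs[i] <- s$x[1]; ys[i] <- s$y[1]
  }
  expect_lt(abs(var(xs) - 2.5) / 2.5, 0.1)
  expect_lt(abs(cor(xs, ys)), 0.03 + 0.02)  # MC band
  expect_error(simulate_traits(tr2, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("FASTQ round trip preserves pairs", {
  ref <- small_reference(25)
  rs <- simulate_reads(ref$genome, coverage = 2, seed = 9)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq_pair(rs, f1, f2)
  back <- read_fastq_pair(f1, f2)
  expect_identical(back$pairs$mate1, rs$pairs$mate1)
  expect_identical(back$pairs$mate2, rs$pairs$mate2)
})
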