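test_that("constructed repeat pairs are reported once per orientation class", {
  set.seed(61)
  X <- rnd_dna(30)
  s <- paste0(rnd_dna(300), X, rnd_dna(200), X, rnd_dna(300))
  h <- find_maximal_repeats(s, min_len = 20, max_mismatch = 0,
                            max_evalue = Inf, classes = "forward")
  expect_equal(nrow(h), 1)
  expect_gte(h$length[1], 30)
  expect_equal(h$mismatches[1], 0)
  s2 <- paste0(rnd_dna(300), X, rnd_dna(200), rc(X), rnd_dna(300))
  h2 <- find_maximal_repeats(s2, min_len = 20, max_mismatch = 0,
                             max_evalue = Inf, classes = "inverted")
  expect_equal(nrow(h2), 1)
  s3 <- paste0(rnd_dna(300), X, rnd_dna(200), str_rev(X), rnd_dna(300))
  h3 <- find_maximal_repeats(s3, min_len = 20, max_mismatch = 0,
                             max_evalue = Inf, classes = "reverse")
  expect_equal(nrow(h3), 1)
  s4 <- paste0(rnd_dna(300), X, rnd_dna(200), chartr("ACGT", "TGCA", X),
               rnd_dna(300))
  h4 <- find_maximal_repeats(s4, min_len = 20, max_mismatch = 0,
                             max_evalue = Inf, classes = "complement")
  expect_equal(nrow(h4), 1)
  expect_error(find_maximal_repeats(s, min_len = 6, max_mismatch = 3),
               "min_len")
})

test_that("maximal repeat finder matches the brute-force diagonal oracle", {
  for (s in 1:10) {
    set.seed(6100 + s)
    n <- sample(150:500, 1)
    x <- rnd_dna(n)
    ml <- sample(8:20, 1)
    k <- sample(0:3, 1)
    ml <- max(ml, 2 * (k + 1))
    for (cl in REPEAT_CLASSES) {
      imp <- find_maximal_repeats(x, min_len = ml, max_mismatch = k,
                                  max_evalue = Inf, classes = cl)
      imp <- imp[order(-imp$length, imp$start_a, imp$start_b),
                 c("start_a", "start_b", "length", "mismatches")]
      ora <- oracle_repeats(x, cl, ml, k)
      rownames(imp) <- rownames(ora) <- NULL
      expect_equal(imp, ora, ignore_attr = TRUE,
                   label = sprintf("seed %d class %s", s, cl))
    }
  }
})

test_that("e-value is a binomial tail times the pair count, monotone", {
  n <- 30000
  expect_lt(repeat_evalue(30, 0, n), repeat_evalue(25, 0, n))
  expect_lt(repeat_evalue(30, 1, n), repeat_evalue(30, 2, n))
  ## direct summation oracle for the tail term
  for (l in c(10, 15, 20)) {
    for (k in 0:3) {
      tail_direct <- sum(vapply(seq(l - k, l), function(m)
        choose(l, m) * 0.25^m * 0.75^(l - m), numeric(1)))
      expect_equal(repeat_evalue(l, k, n), 4 * n^2 * tail_direct,
                   tolerance = 1e-12)
    }
  }
})

test_that("hit lists are invariant under rotation", {
  set.seed(62)
  X <- rnd_dna(40)
  s <- paste0(rnd_dna(400), X, rnd_dna(300), rc(X), rnd_dna(200))
  n <- nchar(s)
  shift <- 555
  s2 <- plastrophy:::rotate_seq(s, shift)
  h1 <- find_maximal_repeats(s, min_len = 20, max_mismatch = 1,
                             max_evalue = Inf)
  h2 <- find_maximal_repeats(s2, min_len = 20, max_mismatch = 1,
                             max_evalue = Inf)
  expect_equal(nrow(h1), nrow(h2))
  key <- function(h, off) {
    s1 <- (h$start_a - off) %% n; s2_ <- (h$start_b - off) %% n
    sort(paste(h$class, pmin(s1, s2_), pmax(s1, s2_), h$length))
  }
  expect_identical(key(h1, shift), key(h2, 0))
})

test_that("tandem scanner matches construction and the brute-force oracle", {
  ## flanks chosen so the array cannot extend by chance
  s <- paste0("GGT", "ACACACACACAC", "TTG")
  h <- find_tandem_repeats(s)
  hit <- h[h$unit %in% c("AC", "CA"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$total, 12)
  expect_equal(hit$unit_len, 2)
  expect_equal(hit$copy_number, 6)
  ## homopolymer runs are excluded (unit length 1 outside the range)
  ## flanks chosen so no accidental dinucleotide joins the run
  s2 <- paste0("GTC", strrep("A", 12), "CTG")
  h2 <- find_tandem_repeats(s2)
  expect_equal(nrow(h2[h2$total >= 10, ]), 0)
  for (seed in 1:8) {
    set.seed(6300 + seed)
    x <- rnd_dna(sample(200:800, 1))
    imp <- find_tandem_repeats(x)[, c("start", "unit_len", "total")]
    ora <- oracle_tandem(x)
    rownames(imp) <- rownames(ora) <- NULL
    expect_equal(imp, ora, ignore_attr = TRUE, label = paste("seed", seed))
  }
})

test_that("repeat density counts hits and the covered-base union", {
  expect_equal(repeat_density(data.frame(), 30000)$count_density, 0)
  expect_error(repeat_density(data.frame(), 0), "positive")
  one <- data.frame(class = "forward", start_a = 0L, start_b = 1000L,
                    length = 30L, mismatches = 0L)
  d <- repeat_density(one, 30000)
  expect_equal(d$count_density, 1000 / 30000)
  expect_equal(d$bp_fraction, 60 / 30000)
  ## overlapping hits: union oracle by position marking
  hits <- data.frame(class = "forward",
                     start_a = c(0L, 10L), start_b = c(100L, 200L),
                     length = c(30L, 30L), mismatches = 0L)
  d2 <- repeat_density(hits, 1000)
  marked <- logical(1000)
  for (iv in list(c(0, 30), c(10, 40), c(100, 130), c(200, 230))) {
    marked[(iv[1] + 1):iv[2]] <- TRUE
  }
  expect_equal(d2$bp_fraction, mean(marked))
})

test_that("the planted large IR tops the inverted repeat census", {
  ref <- small_reference(64)
  deg <- degrade_plastome(ref, plant_ir_scenario(ref, 3000), seed = 64)
  h <- find_maximal_repeats(deg$genome, min_len = 20, max_mismatch = 3,
                            max_evalue = 1e-3, classes = "inverted")
  expect_gte(nrow(h), 1)
  expect_gte(h$length[1], deg$planted$ira[2] - deg$planted$ira[1])
  ## with zero mismatches allowed, the top hit is the planted IR exactly
  h0 <- find_maximal_repeats(deg$genome, min_len = 20, max_mismatch = 0,
                             max_evalue = 1e-3, classes = "inverted")
  expect_equal(h0$length[1], deg$planted$ira[2] - deg$planted$ira[1])
  expect_equal(sort(c(h0$start_a[1], h0$start_b[1])),
               sort(c(deg$planted$ira[1], deg$planted$irb[1])))
})
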