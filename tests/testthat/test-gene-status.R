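test_that("global alignment reports identity and single-gap lesions", {
  set.seed(51)
  s <- rnd_dna(300)
  a <- align_ortholog(s, s)
  expect_equal(a$identity, 100)
  expect_equal(a$n_gaps, 0)
  ## one deleted base -> exactly one 1-bp gap
  s2 <- paste0(substr(s, 1, 149), substr(s, 151, 300))
  a2 <- align_ortholog(s2, s)
  expect_equal(a2$n_gaps, 1)
  ## unrelated sequences align poorly (negative control)
  ids <- vapply(1:40, function(i) {
    set.seed(5000 + i)
    align_ortholog(rnd_dna(300), rnd_dna(300))$identity
  }, numeric(1))
  expect_lt(stats::median(ids), 60)
})

test_that("planted lesions drive the expected status calls", {
  ref <- small_reference(52)
  prot <- ref$genome$features$name[
    gene_type_of(ref$genome$features$gene_class) == "protein"]
  scen <- degradation_scenario(
    deletions = c(prot[1], "trnC-GCA"),
    pseudogenizations = c(
      setNames("premature_stop", prot[2]),
      setNames("frameshift_del", prot[3]),
      setNames("frameshift_ins", prot[4]),
      setNames("truncation", "trnA-UGC")))
  deg <- degrade_plastome(ref, scen, seed = 52)
  idx <- seed_index(deg$genome$sequence, 21L)
  call_of <- function(g) classify_gene(deg$genome, g, ref, index = idx)
  expect_equal(call_of(prot[1])$status, "absent")
  expect_true("no_homolog" %in% call_of(prot[1])$evidence)
  c2 <- call_of(prot[2])
  expect_equal(c2$status, "pseudogene")
  expect_true("premature_stop" %in% c2$evidence)
  c3 <- call_of(prot[3])
  expect_equal(c3$status, "pseudogene")
  expect_true("frameshift" %in% c3$evidence)
  c4 <- call_of(prot[4])
  expect_equal(c4$status, "pseudogene")
  expect_true("frameshift" %in% c4$evidence)
  ## untouched genes stay intact; tRNA rules are coverage/identity only
  expect_equal(call_of(prot[5])$status, "intact")
  expect_equal(call_of("trnC-GCA")$status, "absent")
  ct <- call_of("trnA-UGC")
  expect_equal(ct$status, "pseudogene")
  expect_true("truncated" %in% ct$evidence)
  expect_equal(call_of("rrn16")$status, "intact")
})

test_that("pseudogene calls always carry at least one lesion", {
  ref <- small_reference(53)
  scen <- heterotroph_scenario_small(ref, seed = 53)
  deg <- degrade_plastome(ref, scen, seed = 53)
  idx <- seed_index(deg$genome$sequence, 21L)
  for (g in unique(plastrophy:::base_gene_name(ref$genome$features$name))) {
    cl <- classify_gene(deg$genome, g, ref, index = idx)
    if (cl$status == "pseudogene") expect_gte(length(cl$evidence), 1)
    if (cl$status == "absent") expect_true("no_homolog" %in% cl$evidence)
  }
})

test_that("lowering the identity threshold never turns intact into absent", {
  ref <- small_reference(54)
  deg <- degrade_plastome(ref, degradation_scenario(), seed = 54)
  idx <- seed_index(deg$genome$sequence, 21L)
  strict <- classification_thresholds(absent_identity = 60)
  lax <- classification_thresholds(absent_identity = 30)
  for (g in sample(ref$genome$features$name, 8)) {
    a <- classify_gene(deg$genome, g, ref, strict, index = idx)$status
    b <- classify_gene(deg$genome, g, ref, lax, index = idx)$status
    expect_equal(a, "intact")
    expect_false(a == "intact" && b == "absent")
  }
})

test_that("absence verification distinguishes fragments from clean deletions", {
  ref <- small_reference(55)
  prot <- ref$genome$features$name[
    gene_type_of(ref$genome$features$gene_class) == "protein"]
  lens <- ref$genome$features$end - ref$genome$features$start
  big <- prot[order(-lens[match(prot, ref$genome$features$name)])][1:2]
  scen <- degradation_scenario(deletions = big)
  deg <- degrade_plastome(ref, scen, seed = 55)
  main <- simulate_reads(deg$genome, coverage = 40, seed = 56)
  frag <- simulate_insert_fragments(ref, big[1], 0.5, 0.35,
                                    main_coverage = 40, seed = 57)
  reads <- merge_read_sets(main, frag)
  v1 <- verify_absence(big[1], ref, reads, 40)
  expect_equal(v1$result, "fragment_found")
  expect_lt(v1$relative_depth, 1)
  v2 <- verify_absence(big[2], ref, reads, 40)
  expect_equal(v2$result, "confirmed_absent")
  intact_call <- structure(list(status = "intact"), class = "gene_status_call")
  expect_equal(verify_absence(prot[3], ref, reads, 40,
                              prior_call = intact_call)$result, "present")
  expect_error(verify_absence(big[1], ref, reads, 0), "positive")
})

test_that("status matrix equals generator truth and the all-intact column", {
  ref <- small_reference(58, n_protein = 12, n_trna = 3, n_rrna = 1)
  scen <- heterotroph_scenario_small(ref, seed = 58, n_del = 3, n_pseudo = 3)
  deg <- degrade_plastome(ref, scen, seed = 58)
  self <- ref$genome; self$id <- "self"
  m <- build_status_matrix(list(self = self, parasite = deg$genome), ref)
  expect_true(all(m[, "self"] == "intact"))
  truth <- setNames(deg$truth$status, deg$truth$gene)
  expect_identical(unname(m[names(truth), "parasite"]), unname(truth))
})
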