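## Pipeline orchestration: one configuration object drives simulate ->
## detect-ir -> partition -> gene-status -> repeats -> synteny -> traits,
## each stage writing its outputs before the next starts, with a run
## manifest recording seeds and parameters. Stages are plain functions and
## individually invocable; run_pipeline() is exactly their composition.

#' Build a pipeline configuration
#'
#' Defaults reproduce the standard analysis parameters: repeat census at
#' minimum length 20, Hamming distance 3, e-value 1e-3; tandem scan at
#' minimum 10 bp, units 2-50; IR calling at minimum 1000 bp with 5
#' supporting pairs per junction; gene classification thresholds as in
#' [classification_thresholds()].
#'
#' @param out_dir output directory.
#' @param seed top-level seed; every stage derives a named substream.
#' @param simulate `NULL`, or a list of overrides for the synthetic
#'   scenario (fields `coverage`, `error_rate`, `ir_len_target`,
#'   `n_protein`, `n_trna`, `n_rrna`, `intergenic_len`).
#' @param genome_fasta,genome_features paths to an assembled genome (used
#'   when `simulate` is `NULL`).
#' @param reference_fasta,reference_features paths to the reference genome.
#' @param tree path to a Newick tree (optional; required for the traits
#'   stage on real data).
#' @param traits path to a TSV trait table (optional).
#' @param thresholds classification thresholds.
#' @param min_ir_len,min_pairs,cov_ratio_window IR-calling parameters.
#' @param repeat_min_len,repeat_max_mismatch,repeat_max_evalue repeat
#'   census parameters.
#' @param tandem_min_total,tandem_unit_range tandem scan parameters.
#' @param min_block_len LCB minimum block length.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("plastrophy_run_"),
                            seed = 1L,
                            simulate = list(),
                            genome_fasta = NULL, genome_features = NULL,
                            reference_fasta = NULL,
                            reference_features = NULL,
                            tree = NULL, traits = NULL,
                            thresholds = classification_thresholds(),
                            min_ir_len = 1000L, min_pairs = 5L,
                            cov_ratio_window = c(1.7, 2.3),
                            repeat_min_len = 20L, repeat_max_mismatch = 3L,
                            repeat_max_evalue = 1e-3,
                            tandem_min_total = 10L,
                            tandem_unit_range = c(2L, 50L),
                            min_block_len = 0L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = simulate, genome_fasta = genome_fasta,
              genome_features = genome_features,
              reference_fasta = reference_fasta,
              reference_features = reference_features,
              tree = tree, traits = traits, thresholds = thresholds,
              min_ir_len = min_ir_len, min_pairs = min_pairs,
              cov_ratio_window = cov_ratio_window,
              repeat_min_len = repeat_min_len,
              repeat_max_mismatch = repeat_max_mismatch,
              repeat_max_evalue = repeat_max_evalue,
              tandem_min_total = tandem_min_total,
              tandem_unit_range = tandem_unit_range,
              min_block_len = min_block_len)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$genome_fasta)) {
    stop("configuration error: either a simulate block or genome_fasta ",
         "must be provided")
  }
  if (!is.null(cfg$traits) && is.null(cfg$tree)) {
    stop("configuration error: traits requested but no tree given")
  }
  for (p in c("genome_fasta", "genome_features", "reference_fasta",
              "reference_features", "tree", "traits")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("configuration error: missing file for ", p, ": ", cfg[[p]])
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; fields as in [pipeline_config()].
#' @param overrides named list of fields that win over the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), detect-ir, partition, gene-status,
#' repeats, synteny and traits in order, writing every stage's outputs
#' under `config$out_dir` before the next stage starts. Any stage error
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with per-stage results and the path of the
#'   consolidated JSON report.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    log_stage(name, "starting")
    tryCatch(expr, error = function(e) {
      err <- list(stage = name, message = conditionMessage(e))
      jsonlite::write_json(err, file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- simulate ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    res$simulate <- stage("simulate", {
      sim <- config$simulate
      sdir <- file.path(config$out_dir, "simulate")
      dir.create(sdir, showWarnings = FALSE)
      ref <- make_reference_plastome(
        n_protein = sim$n_protein %||% 82L,
        n_trna = sim$n_trna %||% 32L, n_rrna = sim$n_rrna %||% 4L,
        intergenic_len = sim$intergenic_len %||% 300,
        seed = child_seed(config$seed, "reference"))
      full_complement <- (sim$n_protein %||% 82L) == 82L &&
        (sim$n_trna %||% 32L) == 32L
      scen <- if (full_complement) {
        heterotroph_scenario(ref,
                             ir_len_target = sim$ir_len_target %||% 9256,
                             seed = child_seed(config$seed, "scenario"))
      } else {
        np <- sim$n_protein %||% 82L
        random_degradation_scenario(
          ref, n_deletions = max(1L, np %/% 4),
          n_pseudogenizations = max(1L, np %/% 4),
          ir_len_target = sim$ir_len_target %||% 9256,
          fragment_depth = 0.3,
          seed = child_seed(config$seed, "scenario"))
      }
      deg <- degrade_plastome(ref, scen,
                              seed = child_seed(config$seed, "degrade"),
                              id = "degraded")
      cov <- sim$coverage %||% 100
      reads <- simulate_reads(deg$genome, coverage = cov,
                              error_rate = sim$error_rate %||% 0.002,
                              seed = child_seed(config$seed, "reads"))
      frag_sets <- lapply(seq_len(nrow(scen$insert_fragments %||%
                                         data.frame())), function(i) {
        fr <- scen$insert_fragments[i, ]
        simulate_insert_fragments(ref, fr$gene, fr$fraction,
                                  fr$relative_depth, main_coverage = cov,
                                  error_rate = sim$error_rate %||% 0.002,
                                  seed = child_seed(config$seed,
                                                    paste0("frag", i)))
      })
      all_reads <- do.call(merge_read_sets, c(list(reads), frag_sets))
      write_genome(ref$genome, file.path(sdir, "reference.fasta"),
                   file.path(sdir, "reference.gff3"))
      write_genome(deg$genome, file.path(sdir, "degraded.fasta"),
                   file.path(sdir, "degraded.gff3"))
      write_fastq_pair(all_reads, file.path(sdir, "reads_1.fastq"),
                       file.path(sdir, "reads_2.fastq"))
      write_status_table(deg$truth, file.path(sdir, "truth.tsv"))
      list(reference = ref, degraded = deg, scenario = scen,
           reads = all_reads, coverage = cov)
    })
    genome <- res$simulate$degraded$genome
    reference <- res$simulate$reference$genome
    reads <- res$simulate$reads
    coverage_x <- res$simulate$coverage
  } else {
    genome <- stage("load", read_genome(config$genome_fasta,
                                        config$genome_features))
    reference <- if (!is.null(config$reference_fasta)) {
      read_genome(config$reference_fasta, config$reference_features)
    } else NULL
    reads <- NULL
    coverage_x <- NA_real_
  }

  ## ---- detect-ir ---------------------------------------------------------
  res$ir <- stage("detect-ir", {
    det <- detect_ir(genome, reads, min_ir_len = config$min_ir_len,
                     min_pairs = config$min_pairs,
                     cov_ratio_window = config$cov_ratio_window)
    out <- if (is.null(det$call)) list(ir_found = FALSE) else
      list(ir_found = TRUE, ira = det$call$ira, irb = det$call$irb,
           length = det$call$length, accepted_by = det$call$accepted_by,
           junction_support = as.list(det$call$junction_support %||% NULL),
           coverage_ratio = det$call$coverage_ratio)
    jsonlite::write_json(out, file.path(config$out_dir, "ir_call.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(det$call)) {
      write_bed(data.frame(start = c(det$call$ira[1], det$call$irb[1]),
                           end = c(det$call$ira[2], det$call$irb[2]),
                           name = c("IRa", "IRb")),
                genome$id, file.path(config$out_dir, "ir.bed"))
    }
    det
  })

  ## ---- partition ---------------------------------------------------------
  res$partition <- stage("partition", {
    map <- partition_quadripartite(genome, res$ir$call)
    jsonlite::write_json(
      list(degenerate = map$degenerate, lengths = as.list(map$lengths),
           genome_length = map$genome_length),
      file.path(config$out_dir, "quadripartite.json"),
      auto_unbox = TRUE, digits = NA)
    map
  })

  ## ---- gene-status -------------------------------------------------------
  if (!is.null(reference)) {
    res$gene_status <- stage("gene-status", {
      genes <- unique(base_gene_name(reference$features$name))
      idx <- seed_index(genome$sequence, 21L, genome$circular)
      calls <- lapply(genes, function(g)
        classify_gene(genome, g, reference, config$thresholds, index = idx))
      names(calls) <- genes
      tab <- data.frame(
        gene = genes,
        status = vapply(calls, `[[`, character(1), "status"),
        evidence = vapply(calls, function(x)
          paste(x$evidence, collapse = ";"), character(1)),
        identity = vapply(calls, `[[`, numeric(1), "identity"),
        covered = vapply(calls, `[[`, numeric(1), "covered"),
        stringsAsFactors = FALSE)
      write_status_table(tab, file.path(config$out_dir, "gene_status.tsv"))
      verifications <- list()
      if (!is.null(reads)) {
        absent <- genes[tab$status == "absent"]
        verifications <- lapply(absent, function(g)
          verify_absence(g, reference, reads, coverage_x,
                         prior_call = calls[[g]]))
        names(verifications) <- absent
        jsonlite::write_json(verifications,
                             file.path(config$out_dir, "absence_checks.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      ## summary on the target annotated with the calls
      annotated <- genome
      keep <- match(base_gene_name(annotated$features$name), tab$gene)
      annotated$features$status <- ifelse(is.na(keep), "unclassified",
                                          tab$status[keep])
      list(calls = calls, table = tab, verifications = verifications,
           annotated = annotated)
    })
  }

  ## ---- repeats -----------------------------------------------------------
  res$repeats <- stage("repeats", {
    hits <- find_maximal_repeats(genome, min_len = config$repeat_min_len,
                                 max_mismatch = config$repeat_max_mismatch,
                                 max_evalue = config$repeat_max_evalue)
    tand <- find_tandem_repeats(genome, min_total = config$tandem_min_total,
                                unit_range = config$tandem_unit_range)
    dens <- repeat_density(hits, genome_length(genome))
    utils::write.table(hits, file.path(config$out_dir, "repeats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tand, file.path(config$out_dir, "tandem_repeats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(dens, file.path(config$out_dir,
                                         "repeat_density.json"),
                         auto_unbox = TRUE, digits = NA)
    list(dispersed = hits, tandem = tand, density = dens)
  })

  ## ---- synteny -----------------------------------------------------------
  if (!is.null(reference)) {
    res$synteny <- stage("synteny", {
      collapsed <- collapse_ir(genome, res$partition)
      lcbs <- build_lcbs(list(reference = reference, target = collapsed),
                         anchor_mode = "gene",
                         min_block_len = config$min_block_len)
      perms <- lcb_permutations(lcbs)
      bp <- breakpoint_distance(perms[[2]], perms[[1]])
      rev <- reversal_distance(perms[[2]], perms[[1]],
                               exact_cap = 10L, approximate = TRUE)
      utils::write.table(lcbs$blocks, file.path(config$out_dir, "lcbs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(n_blocks = lcbs$n_blocks, breakpoint_distance = bp,
             reversal_distance = as.integer(rev),
             reversal_exact = isTRUE(attr(rev, "exact"))),
        file.path(config$out_dir, "synteny.json"), auto_unbox = TRUE,
        digits = NA)
      list(lcbs = lcbs, permutations = perms, breakpoints = bp,
           reversals = rev)
    })
  }

  ## ---- traits ------------------------------------------------------------
  if (!is.null(config$tree) && !is.null(config$traits)) {
    res$traits <- stage("traits", {
      tree <- ape::read.tree(config$tree)
      traits <- read_trait_table(config$traits)
      lrt <- lrt_correlation(tree, traits)
      jsonlite::write_json(
        list(LR = lrt$LR, LR_corrected = lrt$LR_corrected, df = lrt$df,
             p = lrt$p, correlation = lrt$correlation,
             caveat = lrt$caveat),
        file.path(config$out_dir, "trait_lrt.json"), auto_unbox = TRUE,
        digits = NA)
      lrt
    })
  } else if (!is.null(res$simulate)) {
    ## demo mode: seeded 16-taxon tree with independent + correlated pairs
    res$traits <- stage("traits", {
      tr <- with_seed(child_seed(config$seed, "tree"),
                      ape::rcoal(16, tip.label = sprintf("t%02d", 1:16)))
      sim_ind <- simulate_traits(tr, diag(2),
                                 seed = child_seed(config$seed, "traits0"))
      sim_cor <- simulate_traits(tr, matrix(c(1, .9, .9, 1), 2),
                                 seed = child_seed(config$seed, "traits9"))
      lrts <- list(independent = lrt_correlation(tr, sim_ind),
                   correlated = lrt_correlation(tr, sim_cor))
      jsonlite::write_json(
        lapply(lrts, function(l) list(LR = l$LR, p = l$p,
                                      correlation = l$correlation)),
        file.path(config$out_dir, "trait_lrt.json"), auto_unbox = TRUE,
        digits = NA)
      lrts
    })
  }

  ## ---- report ------------------------------------------------------------
  report <- stage("report", {
    manifest <- list(
      package = "plastrophy",
      version = as.character(utils::packageVersion("plastrophy")),
      seed = config$seed,
      parameters = config[setdiff(names(config),
                                  c("thresholds", "simulate"))],
      thresholds = config$thresholds,
      stages_run = names(res))
    path <- file.path(config$out_dir, "report.json")
    summary <- list(
      manifest = manifest,
      ir = if (!is.null(res$ir$call)) list(length = res$ir$call$length)
           else list(length = 0),
      quadripartite = as.list(res$partition$lengths),
      gene_status = if (!is.null(res$gene_status))
        as.list(table(res$gene_status$table$status)) else NULL,
      repeats = list(n_dispersed = nrow(res$repeats$dispersed),
                     n_tandem = nrow(res$repeats$tandem),
                     density = res$repeats$density),
      synteny = if (!is.null(res$synteny))
        list(n_blocks = res$synteny$lcbs$n_blocks,
             breakpoints = res$synteny$breakpoints,
             reversals = as.integer(res$synteny$reversals)) else NULL)
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
    path
  })
  res$report <- report
  log_stage("report", "written to ", report)
  invisible(res)
}
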