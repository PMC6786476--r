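## Synthetic plastome generation: a photosynthetic reference with a standard
## gene complement, and a degraded derivative with planted deletions,
## pseudogenizations, inversions, a planted large IR, and a truth ledger.

STOP_CODONS <- c("TAA", "TAG", "TGA")

non_stop_codons <- function() {
  cods <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                collapse = "")
  setdiff(cods, STOP_CODONS)
}

#' Generate a photosynthetic reference plastome
#'
#' Builds an IR-less circular plastome with the canonical gene complement
#' (82 protein, 32 tRNA, 4 rRNA by default; real plastid gene symbols are
#' used, drawn from the bundled inventory). Protein genes are valid ORFs:
#' ATG start, stop-free interior drawn from the 61 sense codons, TAA stop.
#' Gene order and strands are shuffled; genes are separated by random
#' intergenic spacers. Deterministic given `seed`.
#'
#' @param n_protein,n_trna,n_rrna gene counts per molecule type.
#' @param intergenic_len mean spacer length (bp); spacers are uniform on
#'   `[0.5, 1.5] * intergenic_len`.
#' @param protein_len_range range of protein gene lengths (bp, rounded to
#'   codons).
#' @param seed integer seed.
#' @return list with elements `genome` (a [plastome]) and `truth`
#'   (data frame `gene`, `status`, `lesion`).
#' @export
make_reference_plastome <- function(n_protein = 82, n_trna = 32, n_rrna = 4,
                                    intergenic_len = 300,
                                    protein_len_range = c(300, 1800),
                                    seed = 1) {
  stopifnot(n_protein >= 0, n_trna >= 0, n_rrna >= 0,
            n_protein <= length(PLASTID_PROTEIN_GENES),
            n_trna <= length(PLASTID_TRNA_GENES),
            n_rrna <= length(PLASTID_RRNA_GENES))
  with_seed(seed, {
    names_all <- c(PLASTID_PROTEIN_GENES[seq_len(n_protein)],
                   PLASTID_TRNA_GENES[seq_len(n_trna)],
                   PLASTID_RRNA_GENES[seq_len(n_rrna)])
    types <- c(rep("protein", n_protein), rep("trna", n_trna),
               rep("rrna", n_rrna))
    ord <- sample(seq_along(names_all))
    names_all <- names_all[ord]; types <- types[ord]
    sense <- non_stop_codons()
    make_gene_seq <- function(type, name) {
      if (type == "protein") {
        len <- sample(seq(protein_len_range[1], protein_len_range[2], by = 3), 1)
        n_cod <- len %/% 3
        paste0("ATG", paste(sample(sense, n_cod - 2L, replace = TRUE),
                            collapse = ""), "TAA")
      } else if (type == "trna") {
        random_dna(sample(70:90, 1))
      } else {
        len <- switch(name, rrn16 = 1490, rrn23 = 2810, rrn5 = 120,
                      `rrn4.5` = 100, sample(100:3000, 1))
        random_dna(len)
      }
    }
    pieces <- character(0)
    feats <- vector("list", length(names_all))
    pos <- 0L
    for (i in seq_along(names_all)) {
      spacer <- random_dna(sample(
        seq(max(20L, round(0.5 * intergenic_len)),
            round(1.5 * intergenic_len)), 1))
      gseq <- make_gene_seq(types[i], names_all[i])
      strand <- sample(c("+", "-"), 1)
      gs <- if (strand == "-") dna_revcomp(gseq) else gseq
      pieces <- c(pieces, spacer, gs)
      start <- pos + nchar(spacer)
      feats[[i]] <- data.frame(name = names_all[i],
                               gene_class = gene_class_of(names_all[i]),
                               strand = strand, start = start,
                               end = start + nchar(gs),
                               status = "unclassified",
                               stringsAsFactors = FALSE)
      pos <- start + nchar(gs)
    }
    pieces <- c(pieces, random_dna(sample(
      seq(max(20L, round(0.5 * intergenic_len)),
          round(1.5 * intergenic_len)), 1)))
    features <- do.call(rbind, feats)
    g <- plastome("reference", paste(pieces, collapse = ""),
                  circular = TRUE, features = features)
    truth <- data.frame(gene = features$name, status = "intact",
                        lesion = NA_character_, stringsAsFactors = FALSE)
    list(genome = g, truth = truth)
  })
}

#' Describe a degradation scenario
#'
#' @param deletions gene names to excise (gene plus half of each flanking
#'   spacer).
#' @param pseudogenizations named character vector `gene -> lesion`, lesion
#'   one of `premature_stop`, `frameshift_del`, `frameshift_ins` (protein
#'   genes) or `truncation` (any gene type).
#' @param ir_insert `NULL` or list(`first_gene`, `last_gene`, `after_gene`):
#'   the segment from `first_gene` through `last_gene` (with half-spacer
#'   margins) is copied in inverted orientation into the spacer following
#'   `after_gene`, creating a large IR.
#' @param inversions list of `c(first_gene, last_gene)` segments to invert
#'   in place.
#' @param insert_fragments data frame `gene`, `fraction`, `relative_depth`
#'   describing extra-plastomic gene fragments to plant in the read pool.
#' @return object of class `degradation_scenario`.
#' @export
degradation_scenario <- function(deletions = character(),
                                 pseudogenizations = character(),
                                 ir_insert = NULL,
                                 inversions = list(),
                                 insert_fragments = NULL) {
  ok_lesions <- c("premature_stop", "frameshift_del", "frameshift_ins",
                  "truncation")
  if (length(pseudogenizations) > 0) {
    stopifnot(!is.null(names(pseudogenizations)),
              all(pseudogenizations %in% ok_lesions))
  }
  both <- intersect(deletions, names(pseudogenizations))
  if (length(both) > 0) {
    stop("lesion requested on deleted gene(s): ", paste(both, collapse = ", "))
  }
  structure(list(deletions = deletions,
                 pseudogenizations = pseudogenizations,
                 ir_insert = ir_insert, inversions = inversions,
                 insert_fragments = insert_fragments),
            class = "degradation_scenario")
}

## ---- sequence splice helpers (linear feature tables, no wrapped features) --

splice_delete <- function(g, a, b) {
  n <- genome_length(g)
  stopifnot(a >= 0, b > a, b <= n)
  f <- g$features
  if (nrow(f) > 0) {
    len <- f$end - f$start
    inside <- f$start >= a & f$end <= b
    straddle <- !inside & f$start < b & f$end > a
    if (any(straddle)) stop("deletion interval cuts a feature")
    f <- f[!inside, , drop = FALSE]
    len <- len[!inside]
    shift <- f$start >= b
    f$start[shift] <- f$start[shift] - (b - a)
    f$end <- f$start + len
  }
  seq <- paste0(substr(g$sequence, 1, a), substr(g$sequence, b + 1, n))
  plastome(g$id, seq, circular = g$circular, features = f)
}

splice_insert <- function(g, pos, insert_seq, new_features = NULL) {
  n <- genome_length(g)
  stopifnot(pos >= 0, pos <= n)
  L <- nchar(insert_seq)
  f <- g$features
  if (nrow(f) > 0) {
    shift <- f$start >= pos
    f$start[shift] <- f$start[shift] + L
    f$end[shift] <- f$end[shift] + L
  }
  if (!is.null(new_features) && nrow(new_features) > 0) {
    f <- rbind(f, new_features)
  }
  f <- f[order(f$start), , drop = FALSE]
  seq <- paste0(substr(g$sequence, 1, pos), insert_seq,
                substr(g$sequence, pos + 1, n))
  plastome(g$id, seq, circular = g$circular, features = f)
}

## Replace the bases of [a, b) with `repl` (same or different length).
splice_replace <- function(g, a, b, repl) {
  n <- genome_length(g)
  delta <- nchar(repl) - (b - a)
  f <- g$features
  if (nrow(f) > 0 && delta != 0L) {
    container <- f$start <= a & f$end >= b
    after <- f$start >= b
    f$start[after] <- f$start[after] + delta
    f$end[after | container] <- f$end[after | container] + delta
    cut <- !container & !after & f$end > a & f$start < b
    if (any(cut)) stop("replacement cuts a feature boundary")
  }
  seq <- paste0(substr(g$sequence, 1, a), repl, substr(g$sequence, b + 1, n))
  g$sequence <- seq
  g$features <- f
  validate_plastome(g)
  g
}

feature_row <- function(g, name) {
  i <- match(name, g$features$name)
  if (is.na(i)) stop("gene not found: ", name)
  i
}

## Half-open spacer gap midpoints around feature i (features sorted by start).
gap_bounds <- function(g, i) {
  f <- g$features[order(g$features$start), , drop = FALSE]
  k <- which(f$name == g$features$name[i])
  n <- genome_length(g)
  prev_end <- if (k == 1) f$end[nrow(f)] - n else f$end[k - 1]
  next_start <- if (k == nrow(f)) f$start[1] + n else f$start[k + 1]
  left_mid <- floor((prev_end + f$start[k]) / 2)
  right_mid <- ceiling((f$end[k] + next_start) / 2)
  c(left = max(0L, left_mid), right = min(n, right_mid))
}

## ---- lesions -------------------------------------------------------------

apply_pseudogenization <- function(g, gene, lesion) {
  i <- feature_row(g, gene)
  f <- g$features[i, ]
  gtype <- gene_type_of(f$gene_class)
  if (lesion != "truncation" && gtype != "protein") {
    stop("frame lesions only apply to protein genes: ", gene)
  }
  if (lesion == "truncation") {
    len <- f$end - f$start
    cut <- max(1L, floor(0.3 * len))
    ## remove the terminal 30% of the coding strand
    if (f$strand == "+") {
      g <- splice_replace(g, f$end - cut, f$end, "")
    } else {
      g <- splice_replace(g, f$start, f$start + cut, "")
    }
    i <- feature_row(g, gene)
    g$features$end[i] <- g$features$start[i] + (len - cut)
    return(validate_plastome(g))
  }
  cds <- feature_seq(g, gene)
  n_cod <- nchar(cds) %/% 3
  if (lesion == "premature_stop") {
    ## in-frame stop at a random internal codon, early enough that the
    ## predicted protein is unambiguously truncated (< 85% of full length)
    j <- sample(seq(max(3L, floor(0.10 * n_cod)),
                    max(4L, floor(0.80 * n_cod))), 1)
    substr(cds, 3 * (j - 1) + 1, 3 * j) <- "TAA"
    new_cds <- cds
  } else {
    p <- sample(seq(max(10L, floor(0.10 * nchar(cds))),
                    floor(0.50 * nchar(cds))), 1)
    if (lesion == "frameshift_del") {
      new_cds <- paste0(substr(cds, 1, p - 1), substr(cds, p + 1, nchar(cds)))
    } else {
      new_cds <- paste0(substr(cds, 1, p), sample(DNA_BASES, 1),
                        substr(cds, p + 1, nchar(cds)))
    }
  }
  repl <- if (f$strand == "-") dna_revcomp(new_cds) else new_cds
  g <- splice_replace(g, f$start, f$end, repl)
  g
}

apply_deletion <- function(g, gene) {
  i <- feature_row(g, gene)
  gb <- gap_bounds(g, i)
  a <- gb["left"]; b <- gb["right"]
  if (a > g$features$start[i]) a <- g$features$start[i]
  if (b < g$features$end[i]) b <- g$features$end[i]
  splice_delete(g, a, b)
}

apply_inversion <- function(g, first_gene, last_gene) {
  i <- feature_row(g, first_gene); j <- feature_row(g, last_gene)
  a <- gap_bounds(g, i)["left"]; b <- gap_bounds(g, j)["right"]
  stopifnot(a < b)
  seg <- substr(g$sequence, a + 1, b)
  f <- g$features
  inside <- f$start >= a & f$end <= b
  if (any(f$start < b & f$end > a & !inside)) {
    stop("inversion boundary cuts a feature")
  }
  new_start <- a + (b - f$end[inside])
  f$end[inside] <- a + (b - f$start[inside])
  f$start[inside] <- new_start
  f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
  g$sequence <- paste0(substr(g$sequence, 1, a), dna_revcomp(seg),
                       substr(g$sequence, b + 1, genome_length(g)))
  g$features <- f[order(f$start), , drop = FALSE]
  validate_plastome(g)
  list(genome = g, interval = c(a, b))
}

## Insert an inverted copy of the segment [first_gene .. last_gene] into the
## spacer after `after_gene`; duplicated features get the `_ir` suffix.
## Junction bases are adjusted so the resulting inverted-repeat pair is
## exactly maximal at the planted boundaries.
do_ir_insert <- function(g, first_gene, last_gene, after_gene) {
  i <- feature_row(g, first_gene); j <- feature_row(g, last_gene)
  s <- gap_bounds(g, i)["left"]; e <- gap_bounds(g, j)["right"]
  stopifnot(s < e)
  k <- feature_row(g, after_gene)
  gbk <- gap_bounds(g, k)
  p <- unname((g$features$end[k] + gbk["right"]) %/% 2)
  if (p <= g$features$end[k]) p <- g$features$end[k] + 1L
  if (p > s && p < e) stop("IR insertion point falls inside the source segment")
  seg <- substr(g$sequence, s + 1, e)
  ins <- dna_revcomp(seg)
  L <- nchar(ins)
  f <- g$features
  inside <- f$start >= s & f$end <= e
  dup <- f[inside, , drop = FALSE]
  ## mirror coordinates into the inserted copy
  new_start <- p + (e - dup$end)
  dup$end <- p + (e - dup$start)
  dup$start <- new_start
  dup$strand <- ifelse(dup$strand == "+", "-", "+")
  dup$name <- paste0(dup$name, "_ir")
  g2 <- splice_insert(g, p, ins, dup)
  ## coordinates after insertion
  if (p <= s) { s2 <- s + L; e2 <- e + L } else { s2 <- s; e2 <- e }
  b1 <- c(p, p + L)     # inserted copy
  b2 <- c(s2, e2)       # source copy
  ## break accidental extension at all four junctions
  n <- genome_length(g2)
  seqc <- strsplit(g2$sequence, "")[[1]]
  fix <- function(pos_mut, must_differ_from) {
    if (seqc[pos_mut] == must_differ_from) {
      seqc[pos_mut] <<- sample(setdiff(DNA_BASES, must_differ_from), 1)
    }
  }
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  at1 <- function(pos0) ((pos0 %% n) + 1L)   # 0-based -> 1-based, circular
  ## pair = (x = earlier interval, y = later interval), A[x] = revcomp(A[y])
  xs <- if (b1[1] < b2[1]) b1 else b2
  ys <- if (b1[1] < b2[1]) b2 else b1
  ## left of x pairs with right of y, and right of x with left of y
  fix(at1(ys[2]), comp1(seqc[at1(xs[1] - 1L)]))
  fix(at1(ys[1] - 1L), comp1(seqc[at1(xs[2])]))
  g2$sequence <- paste(seqc, collapse = "")
  validate_plastome(g2)
  list(genome = g2, ira = xs, irb = ys)
}

#' Degrade a reference plastome according to a scenario
#'
#' Applies pseudogenizing lesions, gene deletions, segmental inversions and
#' an optional inverted-duplication (IR gain) to the reference, and records
#' the intended status of every reference gene in a truth table.
#'
#' @param reference result of [make_reference_plastome()] or a [plastome].
#' @param scenario a [degradation_scenario].
#' @param seed integer seed (lesion positions are random).
#' @param id label for the degraded genome.
#' @return list with `genome` (degraded [plastome]), `truth` (data frame
#'   `gene`, `status`, `lesion`), and `planted` (list with `ira`, `irb`,
#'   `inversions` coordinates in the degraded genome).
#' @export
degrade_plastome <- function(reference, scenario, seed = 1,
                             id = "degraded") {
  g <- if (inherits(reference, "plastome")) reference else reference$genome
  stopifnot(inherits(scenario, "degradation_scenario"))
  all_targets <- c(scenario$deletions, names(scenario$pseudogenizations),
                   unlist(scenario$inversions),
                   unlist(scenario$ir_insert),
                   as.character(scenario$insert_fragments$gene))
  missing <- setdiff(all_targets, g$features$name)
  if (length(missing) > 0) {
    stop("scenario targets absent from reference: ",
         paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    out <- g
    out$id <- id
    for (gene in names(scenario$pseudogenizations)) {
      out <- apply_pseudogenization(out, gene, scenario$pseudogenizations[[gene]])
    }
    for (gene in scenario$deletions) out <- apply_deletion(out, gene)
    inv_ivs <- list()
    for (iv in scenario$inversions) {
      r <- apply_inversion(out, iv[1], iv[2])
      out <- r$genome
      inv_ivs[[length(inv_ivs) + 1L]] <- r$interval
    }
    planted <- list(ira = NULL, irb = NULL, inversions = inv_ivs)
    if (!is.null(scenario$ir_insert)) {
      r <- do_ir_insert(out, scenario$ir_insert$first_gene,
                        scenario$ir_insert$last_gene,
                        scenario$ir_insert$after_gene)
      out <- r$genome
      planted$ira <- unname(r$ira)
      planted$irb <- unname(r$irb)
    }
    truth <- data.frame(gene = g$features$name, status = "intact",
                        lesion = NA_character_, stringsAsFactors = FALSE)
    truth$status[truth$gene %in% scenario$deletions] <- "absent"
    pg <- names(scenario$pseudogenizations)
    truth$status[truth$gene %in% pg] <- "pseudogene"
    truth$lesion[match(pg, truth$gene)] <- unname(scenario$pseudogenizations)
    list(genome = out, truth = truth, planted = planted)
  })
}

#' Default heterotroph-like degradation scenario
#'
#' Emulates the lesion spectrum of a parasitic-gymnosperm plastome against
#' an 82/32/4 reference: 28 protein genes plus one tRNA deleted, 21
#' photosynthesis-related proteins pseudogenized (33 intact proteins, 31
#' tRNAs and 4 rRNAs remain), one segmental inversion, a planted large IR
#' assembled from a run of retained genes, and low-depth insert fragments of
#' eight deleted genes.
#'
#' @param reference result of [make_reference_plastome()].
#' @param ir_len_target approximate length (bp) of the planted IR.
#' @param seed integer seed used for lesion-type assignment.
#' @return a [degradation_scenario].
#' @export
heterotroph_scenario <- function(reference, ir_len_target = 9256, seed = 1) {
  g <- if (inherits(reference, "plastome")) reference else reference$genome
  lesions <- c("premature_stop", "frameshift_del", "frameshift_ins")
  pseudo <- with_seed(seed, setNames(
    sample(lesions, length(HETEROTROPH_PSEUDOGENES), replace = TRUE),
    HETEROTROPH_PSEUDOGENES))
  pseudo[c("chlB", "chlL", "chlN")] <- "premature_stop"
  deletions <- c(HETEROTROPH_DELETED_PROTEINS, "trnR-CCG")
  ## pick the IR source: a contiguous run of retained genes whose span in
  ## the post-deletion genome is close to the target length
  f <- g$features[order(g$features$start), , drop = FALSE]
  retained <- f[!(f$name %in% c(deletions)), , drop = FALSE]
  lens <- retained$end - retained$start + 250   # approx post-deletion spacing
  run <- best_run_for_length(lens, ir_len_target)
  src <- retained$name[run]
  after_candidates <- setdiff(retained$name, src)
  ## insert roughly opposite the source on the circle
  after_gene <- after_candidates[which.max(
    pmin((retained$start[match(after_candidates, retained$name)] -
            retained$start[run[1]]) %% genome_length(g),
         (retained$start[run[1]] -
            retained$start[match(after_candidates, retained$name)]) %%
           genome_length(g)))]
  ## one inversion over a short run of retained genes outside IR source
  inv_pool <- setdiff(after_candidates, after_gene)
  inv_pos <- match(inv_pool, retained$name)
  inv <- NULL
  for (s in order(inv_pos)) {
    idx <- inv_pos[s]
    if (idx + 2 <= nrow(retained) &&
        all(retained$name[idx:(idx + 2)] %in% inv_pool)) {
      inv <- c(retained$name[idx], retained$name[idx + 2]); break
    }
  }
  degradation_scenario(
    deletions = deletions,
    pseudogenizations = pseudo,
    ir_insert = list(first_gene = src[1], last_gene = src[length(src)],
                     after_gene = after_gene),
    inversions = if (is.null(inv)) list() else list(inv),
    insert_fragments = data.frame(
      gene = HETEROTROPH_INSERT_FRAGMENT_GENES,
      fraction = 0.5, relative_depth = 0.3, stringsAsFactors = FALSE)
  )
}

#' Random degradation scenario for an arbitrary reference
#'
#' Draws deletion and pseudogenization targets from the reference's protein
#' genes (lesion types sampled uniformly), optionally plants a large IR
#' from a run of untouched genes, and optionally plants an insert fragment
#' for the longest deleted gene.
#'
#' @param reference result of [make_reference_plastome()].
#' @param n_deletions,n_pseudogenizations lesion counts.
#' @param ir_len_target approximate IR length (bp) or `NULL` for no IR.
#' @param fragment_depth relative depth of a planted insert fragment of
#'   one deleted gene (`NULL` for none).
#' @param seed integer seed.
#' @return a [degradation_scenario].
#' @export
random_degradation_scenario <- function(reference, n_deletions = 4,
                                        n_pseudogenizations = 6,
                                        ir_len_target = NULL,
                                        fragment_depth = NULL, seed = 1) {
  g <- if (inherits(reference, "plastome")) reference else reference$genome
  f <- g$features[order(g$features$start), , drop = FALSE]
  prot <- f$name[gene_type_of(f$gene_class) == "protein"]
  stopifnot(n_deletions + n_pseudogenizations <= length(prot))
  with_seed(seed, {
    pick <- sample(prot, n_deletions + n_pseudogenizations)
    dels <- pick[seq_len(n_deletions)]
    pse <- pick[n_deletions + seq_len(n_pseudogenizations)]
    lesions <- sample(c("premature_stop", "frameshift_del", "frameshift_ins"),
                      length(pse), TRUE)
    ir <- NULL
    if (!is.null(ir_len_target)) {
      ir <- plant_ir_scenario(reference, ir_len_target)$ir_insert
      src_i <- match(c(ir$first_gene, ir$last_gene), f$name)
      src_genes <- f$name[src_i[1]:src_i[2]]
      dels <- setdiff(dels, src_genes)
      pse <- setdiff(pse, src_genes)
      lesions <- lesions[seq_along(pse)]
      if (ir$after_gene %in% dels) dels <- setdiff(dels, ir$after_gene)
    }
    frag <- NULL
    if (!is.null(fragment_depth) && length(dels) > 0) {
      lens <- f$end[match(dels, f$name)] - f$start[match(dels, f$name)]
      frag <- data.frame(gene = dels[which.max(lens)], fraction = 0.5,
                         relative_depth = fragment_depth,
                         stringsAsFactors = FALSE)
    }
    degradation_scenario(deletions = dels,
                         pseudogenizations = setNames(lesions, pse),
                         ir_insert = ir, insert_fragments = frag)
  })
}

#' Scenario that only plants a large IR
#'
#' Picks a contiguous run of genes whose span approximates `ir_len_target`
#' and duplicates it in inverted orientation on the opposite side of the
#' circle, leaving all genes intact.
#'
#' @param reference result of [make_reference_plastome()].
#' @param ir_len_target approximate IR length (bp).
#' @param seed unused (selection is deterministic); kept for interface
#'   symmetry with the other scenario builders.
#' @return a [degradation_scenario].
#' @export
plant_ir_scenario <- function(reference, ir_len_target = 9256, seed = 1) {
  g <- if (inherits(reference, "plastome")) reference else reference$genome
  f <- g$features[order(g$features$start), , drop = FALSE]
  lens <- f$end - f$start + 250
  run <- best_run_for_length(lens, ir_len_target)
  src <- f$name[run]
  others <- setdiff(f$name, src)
  n <- genome_length(g)
  after_gene <- others[which.max(pmin(
    (f$start[match(others, f$name)] - f$start[run[1]]) %% n,
    (f$start[run[1]] - f$start[match(others, f$name)]) %% n))]
  degradation_scenario(ir_insert = list(first_gene = src[1],
                                        last_gene = src[length(src)],
                                        after_gene = after_gene))
}

## Contiguous run of entries of `lens` whose sum is closest to `target`.
best_run_for_length <- function(lens, target) {
  best <- c(1L, 1L); best_err <- Inf
  i <- 1L; j <- 0L; s <- 0
  n <- length(lens)
  while (i <= n) {
    while (j < n && s < target) { j <- j + 1L; s <- s + lens[j] }
    if (abs(s - target) < best_err && j >= i) {
      best <- c(i, j); best_err <- abs(s - target)
    }
    s <- s - lens[i]; i <- i + 1L
    if (j < i - 1L) { j <- i - 1L; s <- 0 }
  }
  seq(best[1], best[2])
}
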