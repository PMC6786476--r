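## Gene-status classification against an autotrophic reference: each
## reference gene is located in the target plastome by exact-seed anchoring
## plus local affine alignment, then classified as intact, pseudogene
## (premature stop / frameshift / truncation) or absent. Absences can be
## verified against the raw read pool, where low-depth fragments betray
## copies residing in other genomic compartments.

#' Classification thresholds
#'
#' The qualitative rules (truncated reading frame, premature stop,
#' frameshift) are operationalized with these defaults: a homolog must
#' cover 90% of the reference CDS to count as intact; an in-frame stop
#' before 90% of the reference protein length is premature; a region is a
#' homolog at all only at >= 60% identity over >= 30% of the CDS; tRNA and
#' rRNA genes (no reading frame) need >= 80% identity.
#'
#' @param covered_intact minimum covered fraction of the reference CDS for
#'   an intact call.
#' @param stop_frac internal stops before this fraction of the reference
#'   protein length are premature.
#' @param absent_identity minimum percent identity for homolog detection.
#' @param absent_cover minimum covered fraction for homolog detection.
#' @param rna_identity minimum percent identity for intact tRNA/rRNA.
#' @return list of thresholds.
#' @export
classification_thresholds <- function(covered_intact = 0.9, stop_frac = 0.9,
                                      absent_identity = 60,
                                      absent_cover = 0.3,
                                      rna_identity = 80) {
  list(covered_intact = covered_intact, stop_frac = stop_frac,
       absent_identity = absent_identity, absent_cover = absent_cover,
       rna_identity = rna_identity)
}

.sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3,
                                                     baseOnly = TRUE)
    }
    m
  }
})

#' Global pairwise alignment of a target region to a reference CDS
#'
#' Needleman-Wunsch with affine gaps (match +2, mismatch -3, gap open -5,
#' gap extend -2).
#'
#' @param target_region,reference_cds DNA strings.
#' @return list with `score`, `identity` (percent), `n_gaps` (gap opening
#'   count), `alignment` (the Biostrings alignment object).
#' @export
align_ortholog <- function(target_region, reference_cds) {
  stopifnot(nchar(target_region) > 0, nchar(reference_cds) > 0)
  mat <- .sub_matrix()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(target_region),
    subject = Biostrings::DNAString(reference_cds),
    type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln),
       n_gaps = gap_open_count(aln),
       alignment = aln)
}

gap_open_count <- function(aln) {
  ins <- Biostrings::nindel(aln)@insertion
  del <- Biostrings::nindel(aln)@deletion
  sum(ins[, "Length"]) + sum(del[, "Length"])
}

## locate the best seed cluster of a reference CDS in a target genome;
## returns NULL (no homolog anchor) or list(strand, window = c(start,end))
locate_gene_region <- function(target_seq, ref_cds, seed_len = 21L,
                               stride = 10L, circular = TRUE,
                               index = NULL) {
  n <- nchar(target_seq)
  L <- nchar(ref_cds)
  if (L < seed_len) return(NULL)
  if (is.null(index)) index <- seed_index(target_seq, seed_len, circular)
  stopifnot(index$k == seed_len)
  offs <- unique(c(seq(0L, L - seed_len, by = stride), L - seed_len))
  seeds <- substring(ref_cds, offs + 1L, offs + seed_len)
  ok <- !grepl("N", seeds, fixed = TRUE)
  if (!any(ok)) return(NULL)
  seeds <- seeds[ok]; offs <- offs[ok]
  hits_f <- .kmer_index_lookup_cpp(index$ptr, seeds)
  hits_r <- .kmer_index_lookup_cpp(index$ptr, dna_revcomp(seeds))
  best <- NULL
  for (strand in c("+", "-")) {
    st <- if (strand == "+") hits_f else hits_r
    hit <- which(lengths(st) > 0)
    if (length(hit) > 0) {
      ## implied locus starts (0-based, mod n)
      locus <- unlist(lapply(hit, function(i) {
        starts <- st[[i]]
        if (strand == "+") (starts - offs[i]) %% n
        else (starts + seed_len + offs[i] - L) %% n  # via revcomp geometry
      }))
      ## cluster by rounding to L/2 bins on the circle
      bin <- floor((locus %% n) / max(1, L / 2))
      tab <- sort(table(bin), decreasing = TRUE)
      top_bin <- as.integer(names(tab)[1])
      members <- locus[bin == top_bin |
                         abs(bin - top_bin) == 1]
      cand <- list(strand = strand, n_hits = length(members),
                   locus = round(stats::median(members)))
      if (is.null(best) || cand$n_hits > best$n_hits) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  margin <- max(150L, L %/% 4)
  start <- (best$locus - margin) %% n
  width <- min(n, L + 2L * margin)
  list(strand = best$strand, window = c(start, start + width))
}

## local alignment of reference CDS against a window; returns coverage,
## identity and frame metrics
aligned_metrics <- function(ref_cds, window_seq) {
  mat <- .sub_matrix()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref_cds),
    subject = Biostrings::DNAString(window_seq),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  pr <- Biostrings::pattern(aln)
  rs <- Biostrings::start(pr); re <- Biostrings::end(pr)
  covered <- (re - rs + 1) / nchar(ref_cds)
  ins <- Biostrings::nindel(aln)@insertion   # gaps in pattern (ref)
  del <- Biostrings::nindel(aln)@deletion    # gaps in subject (target)
  net_indel <- sum(ins[, "WidthSum"]) - sum(del[, "WidthSum"])
  tgt <- gsub("-", "", as.character(Biostrings::alignedSubject(aln)))
  list(alignment = aln, identity = Biostrings::pid(aln),
       covered = covered, ref_start = rs, ref_end = re,
       net_indel = net_indel, target_seq = tgt)
}

#' Classify one gene in a target plastome
#'
#' Locates the reference CDS in the target (exact 21-mer anchoring, both
#' strands, densest cluster wins) and applies the lesion rules: intact
#' requires a homolog covering >= 90% of the CDS with no premature internal
#' stop and a net indel of 0 mod 3 (frame restored); a located homolog with
#' any lesion (premature stop, frameshift, truncation) is a pseudogene;
#' no homologous region at >= 60% identity over >= 30% of the CDS is
#' absent. tRNA/rRNA genes use covered fraction >= 90% and identity >= 80%
#' (no reading-frame rules).
#'
#' @param target a [plastome] to interrogate.
#' @param gene gene name carried by the reference.
#' @param reference a [plastome] (or `make_reference_plastome()` result)
#'   with intact genes.
#' @param thresholds see [classification_thresholds()].
#' @param index optional prebuilt [seed_index()] of the target (k = 21);
#'   build it once when classifying many genes.
#' @return list of class `gene_status_call`: `gene`, `status`, `evidence`
#'   (character vector), `identity`, `covered`, `strand`.
#' @export
classify_gene <- function(target, gene, reference,
                          thresholds = classification_thresholds(),
                          index = NULL) {
  ref <- if (inherits(reference, "plastome")) reference else reference$genome
  ref_cds <- feature_seq(ref, gene)
  gclass <- gene_class_of(gene)
  gtype <- gene_type_of(gclass)
  if (gtype == "protein") {
    prot <- translate_dna(ref_cds)
    if (!startsWith(ref_cds, "ATG") ||
        grepl("\\*", substr(prot, 1, nchar(prot) - 1))) {
      stop("reference ORF invalid for gene ", gene)
    }
  }
  th <- thresholds
  call <- function(status, evidence = character(), identity = NA_real_,
                   covered = NA_real_, strand = NA_character_) {
    structure(list(gene = gene, status = status, evidence = evidence,
                   identity = identity, covered = covered, strand = strand),
              class = "gene_status_call")
  }
  loc <- locate_gene_region(target$sequence, ref_cds,
                            circular = target$circular, index = index)
  if (is.null(loc)) return(call("absent", "no_homolog"))
  win <- extract_circular(target$sequence, loc$window[1] %% genome_length(target),
                          pmin(loc$window[2], loc$window[1] +
                                 genome_length(target)))
  if (loc$strand == "-") win <- dna_revcomp(win)
  met <- aligned_metrics(ref_cds, win)
  if (met$identity < th$absent_identity || met$covered < th$absent_cover) {
    return(call("absent", "no_homolog", met$identity, met$covered,
                loc$strand))
  }
  if (gtype != "protein") {
    ok <- met$covered >= th$covered_intact && met$identity >= th$rna_identity
    if (ok) return(call("intact", character(), met$identity, met$covered,
                        loc$strand))
    return(call("pseudogene", "truncated", met$identity, met$covered,
                loc$strand))
  }
  evidence <- character()
  if (met$covered < th$covered_intact) evidence <- c(evidence, "truncated")
  if (met$net_indel %% 3 != 0) evidence <- c(evidence, "frameshift")
  ## translate the target locus in the reference frame from the aligned start
  phase <- (3 - ((met$ref_start - 1) %% 3)) %% 3
  tseq <- substr(met$target_seq, phase + 1, nchar(met$target_seq))
  prot <- translate_dna(tseq)
  aa_ref <- nchar(ref_cds) / 3 - 1          # reference protein length
  stops <- gregexpr("*", prot, fixed = TRUE)[[1]]
  stops <- stops[stops > 0]
  ## the reference terminal stop corresponds to the last codon; internal
  ## stops count only before the premature-stop fraction of the protein
  internal <- stops[(stops + (met$ref_start - 1 + phase) / 3) <
                      th$stop_frac * aa_ref]
  if (length(internal) > 0) evidence <- c(evidence, "premature_stop")
  if (length(evidence) == 0) {
    return(call("intact", character(), met$identity, met$covered, loc$strand))
  }
  call("pseudogene", unique(evidence), met$identity, met$covered, loc$strand)
}

#' @export
print.gene_status_call <- function(x, ...) {
  cat(sprintf("%s: %s%s (identity %.1f%%, covered %.2f)\n", x$gene, x$status,
              if (length(x$evidence)) paste0(" [", paste(x$evidence,
                                                         collapse = ","), "]")
              else "", x$identity, x$covered))
  invisible(x)
}

#' Verify a gene absence against the read pool
#'
#' Maps the read set to the reference CDS (21-mer seeds); any covered span
#' indicates a retained fragment, whose depth relative to the main plastome
#' coverage is reported. Relative depth below 1 flags a likely
#' extra-plastomic (nuclear/mitochondrial) insert, the low-k-mer-coverage
#' signal of fragmented gene copies in other genomic compartments.
#'
#' @param gene gene name.
#' @param reference reference [plastome] or generator result.
#' @param reads a `read_set` (the target's full read pool).
#' @param main_coverage mean plastome depth (must be positive).
#' @param prior_call optional `gene_status_call`; a non-absent prior call
#'   returns `present` immediately.
#' @return list with `result` (`confirmed_absent`, `fragment_found`, or
#'   `present`), and for fragments `span` (covered interval on the CDS) and
#'   `relative_depth`.
#' @export
verify_absence <- function(gene, reference, reads, main_coverage,
                           prior_call = NULL) {
  if (main_coverage <= 0) stop("main_coverage must be positive")
  if (!is.null(prior_call) && prior_call$status != "absent") {
    return(list(result = "present"))
  }
  ref <- if (inherits(reference, "plastome")) reference else reference$genome
  cds <- feature_seq(ref, gene)
  pl <- map_reads(reads, cds, circular = FALSE, seed_len = 21L)
  pl <- pl[isTRUE_vec(pl$mapped), , drop = FALSE]
  pl <- pl[pl$pos + pl$len <= nchar(cds), , drop = FALSE]
  if (nrow(pl) == 0) return(list(result = "confirmed_absent"))
  prof <- coverage_profile(pl, nchar(cds), circular = FALSE)
  covered <- which(prof$depth > 0)
  span <- c(min(covered) - 1L, max(covered))
  rel <- mean(prof$depth[covered]) / main_coverage
  list(result = "fragment_found", span = span, relative_depth = rel,
       n_reads = nrow(pl))
}

#' Gene-by-taxon status matrix
#'
#' Classifies every reference gene in every target plastome.
#'
#' @param targets named list of [plastome] objects.
#' @param reference reference [plastome] or generator result.
#' @param thresholds see [classification_thresholds()].
#' @return character matrix (genes x taxa) with values intact / pseudogene /
#'   absent.
#' @export
build_status_matrix <- function(targets, reference,
                                thresholds = classification_thresholds()) {
  ref <- if (inherits(reference, "plastome")) reference else reference$genome
  genes <- base_gene_name(ref$features$name)
  genes <- unique(genes)
  taxa <- names(targets) %||% paste0("taxon", seq_along(targets))
  m <- matrix(NA_character_, nrow = length(genes), ncol = length(targets),
              dimnames = list(genes, taxa))
  for (j in seq_along(targets)) {
    idx <- seed_index(targets[[j]]$sequence, 21L, targets[[j]]$circular)
    for (g in genes) {
      m[g, j] <- classify_gene(targets[[j]], g, ref, thresholds,
                               index = idx)$status
    }
  }
  m
}
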