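## Central genome container: a circular (usually) plastid genome with a flat
## feature table. Internal coordinates are 0-based half-open; a feature with
## end > genome length wraps across the origin.

GENE_CLASSES <- c("photosystem", "cytochrome_b6f", "atp_synthase", "ndh",
                  "rubisco", "chl", "rpo", "ribosomal_protein", "trna",
                  "rrna", "other")

GENE_STATUSES <- c("intact", "pseudogene", "absent", "unclassified")

## Prefix rules mapping gene symbols to functional classes; bundled as a
## plain-text table in inst/extdata/gene_classes.tsv and overridable there.
default_gene_class_table <- function() {
  data.frame(
    prefix = c("psa", "psb", "pet", "atp", "ndh", "rbc", "chl", "rpo",
               "rpl", "rps", "trn", "rrn"),
    gene_class = c("photosystem", "photosystem", "cytochrome_b6f",
                   "atp_synthase", "ndh", "rubisco", "chl", "rpo",
                   "ribosomal_protein", "ribosomal_protein", "trna", "rrna"),
    stringsAsFactors = FALSE
  )
}

#' Look up the functional class of plastid gene symbols
#'
#' Classification is by gene-symbol prefix (psa/psb/pet/atp/ndh/rbc/chl/rpo/
#' rpl/rps/trn/rrn); symbols matching no prefix are classed `other`.
#'
#' @param names character vector of gene symbols (copy suffixes such as
#'   `_ir` are ignored).
#' @param table optional custom prefix table with columns `prefix`,
#'   `gene_class`.
#' @return character vector of gene classes.
#' @export
gene_class_of <- function(names, table = NULL) {
  tab <- table %||% .plastrophy_class_table()
  base <- sub("_.*$", "", names)
  out <- rep("other", length(names))
  for (i in seq_len(nrow(tab))) {
    hit <- startsWith(base, tab$prefix[i])
    out[hit] <- tab$gene_class[i]
  }
  out
}

.class_table_cache <- new.env(parent = emptyenv())

.plastrophy_class_table <- function() {
  if (!is.null(.class_table_cache$tab)) return(.class_table_cache$tab)
  path <- system.file("extdata", "gene_classes.tsv", package = "plastrophy")
  tab <- if (nzchar(path) && file.exists(path)) {
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    default_gene_class_table()
  }
  .class_table_cache$tab <- tab
  tab
}

## Molecule type (protein / trna / rrna) implied by the gene class.
gene_type_of <- function(gene_class) {
  ifelse(gene_class == "trna", "trna",
         ifelse(gene_class == "rrna", "rrna", "protein"))
}

empty_features <- function() {
  data.frame(name = character(), gene_class = character(),
             strand = character(), start = integer(), end = integer(),
             status = character(), stringsAsFactors = FALSE)
}

#' Construct a plastome object
#'
#' @param id genome label.
#' @param sequence DNA string over A/C/G/T/N.
#' @param circular logical; plastomes are circular by default.
#' @param features data frame with columns `name`, `gene_class`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open; `end` may exceed the
#'   genome length by less than one full turn to wrap the origin), and
#'   optionally `status`.
#' @return an object of class `plastome`.
#' @export
plastome <- function(id, sequence, circular = TRUE, features = empty_features()) {
  sequence <- toupper(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) > 0 && is.null(features$status)) features$status <- "unclassified"
  if (nrow(features) == 0) features <- empty_features()
  if (nrow(features) > 0 && is.null(features$gene_class)) {
    features$gene_class <- gene_class_of(features$name)
  }
  obj <- structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         features = features),
    class = "plastome"
  )
  validate_plastome(obj)
  obj
}

validate_plastome <- function(x) {
  n <- genome_length(x)
  f <- x$features
  if (nrow(f) == 0) return(invisible(x))
  if (anyDuplicated(f$name)) {
    dup <- unique(f$name[duplicated(f$name)])
    stop("duplicate feature names (add copy suffixes for IR duplicates): ",
         paste(dup, collapse = ", "))
  }
  if (any(f$start < 0 | f$start >= n)) stop("feature start out of range")
  if (any(f$end <= f$start)) stop("feature end must exceed start")
  if (any(f$end - f$start > n)) stop("feature longer than genome")
  if (!x$circular && any(f$end > n)) stop("wrapped feature on a linear genome")
  if (!all(f$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(f$status %in% GENE_STATUSES)) stop("invalid feature status")
  invisible(x)
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome '%s': %s bp (%s), %d features\n", x$id,
              format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  if (nrow(x$features) > 0) {
    st <- table(factor(x$features$status, levels = GENE_STATUSES))
    cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
genome_length <- function(x) UseMethod("genome_length")

#' @export
genome_length.plastome <- function(x) nchar(x$sequence)

#' Extract a feature's nucleotide sequence (strand-aware)
#' @param x a plastome.
#' @param name feature name.
#' @return DNA string of the feature on its coding strand.
#' @export
feature_seq <- function(x, name) {
  i <- match(name, x$features$name)
  if (is.na(i)) stop("no such feature: ", name)
  s <- extract_circular(x$sequence, x$features$start[i], x$features$end[i])
  if (x$features$strand[i] == "-") dna_revcomp(s) else s
}

## Translate a DNA string (standard code); returns the amino-acid string
## with '*' for stops and 'X' for ambiguous codons; trailing partial codon
## dropped. Table lookup keeps this fast on thousands of calls.
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

translate_dna <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .codon_table()[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Rotate a plastome to a new origin
#'
#' Shifts the circular coordinate system so that `origin` becomes position 0;
#' all feature coordinates move by the same offset modulo genome length.
#'
#' @param x a plastome.
#' @param origin 0-based position that becomes the new origin.
#' @return a rotated plastome.
#' @export
rotate_plastome <- function(x, origin) {
  stopifnot(x$circular)
  n <- genome_length(x)
  origin <- origin %% n
  y <- x
  y$sequence <- rotate_seq(x$sequence, origin)
  if (nrow(x$features) > 0) {
    st <- (x$features$start - origin) %% n
    y$features$start <- st
    y$features$end <- st + (x$features$end - x$features$start)
  }
  validate_plastome(y)
  y
}
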