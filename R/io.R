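## Standard-format I/O. Sequences travel as FASTA (Biostrings), features as a
## GFF3 subset (type=gene lines with Name=/status= attributes) or a simple
## 1-based inclusive TSV. Internally everything is 0-based half-open.

#' Read a plastome from FASTA plus a feature file
#'
#' @param path_fasta single-record FASTA file.
#' @param path_features GFF3 file (1-based inclusive `gene` lines with a
#'   `Name=` attribute) or a TSV with columns name, start, end and optional
#'   strand, status (also 1-based inclusive). `NULL` for no features.
#' @param circular logical, default TRUE.
#' @return a [plastome].
#' @export
read_genome <- function(path_fasta, path_features = NULL, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path_fasta)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record, found ", length(seqs))
  }
  id <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])
  features <- empty_features()
  if (!is.null(path_features)) {
    features <- if (grepl("\\.gff3?$", path_features, ignore.case = TRUE)) {
      read_features_gff3(path_features)
    } else {
      read_features_tsv(path_features)
    }
  }
  n <- nchar(sequence)
  if (nrow(features) > 0 && any(features$start < 0 | features$start >= n |
                                features$end - features$start > n)) {
    stop("feature interval out of range for genome of length ", n)
  }
  plastome(id, sequence, circular = circular, features = features)
}

read_features_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 9
  if (any(bad)) stop("malformed GFF3 line(s): ", which(bad)[1])
  m <- do.call(rbind, parts)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(empty_features())
  attr_field <- function(attrs, key) {
    hit <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(hit, function(h) if (length(h) == 2) h[2] else NA_character_,
           character(1))
  }
  name <- attr_field(m[, 9], "Name")
  if (anyNA(name)) name[is.na(name)] <- attr_field(m[is.na(name), 9], "ID")
  if (anyNA(name)) stop("GFF3 gene line without Name= or ID= attribute")
  status <- attr_field(m[, 9], "status")
  status[is.na(status)] <- "unclassified"
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  if (anyNA(start1) || anyNA(end1)) stop("non-numeric GFF3 coordinates")
  data.frame(name = name, gene_class = gene_class_of(name),
             strand = m[, 7], start = start1 - 1L, end = end1,
             status = status, stringsAsFactors = FALSE)
}

read_features_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("feature TSV needs columns: ", paste(need, collapse = ", "))
  }
  data.frame(name = tab$name, gene_class = gene_class_of(tab$name),
             strand = tab$strand %||% rep("+", nrow(tab)),
             start = as.integer(tab$start) - 1L, end = as.integer(tab$end),
             status = tab$status %||% rep("unclassified", nrow(tab)),
             stringsAsFactors = FALSE)
}

#' Write a plastome to FASTA (+ optional GFF3)
#'
#' Inverse of [read_genome()]: coordinates are emitted 1-based inclusive; a
#' feature wrapping the circular origin keeps `end > length` so that the
#' round trip is exact.
#'
#' @param x a [plastome].
#' @param path_fasta output FASTA path.
#' @param path_features optional output GFF3 path.
#' @return invisibly, `x`.
#' @export
write_genome <- function(x, path_fasta, path_features = NULL) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$id
  Biostrings::writeXStringSet(seqs, path_fasta, width = 70L)
  if (!is.null(path_features)) {
    f <- x$features
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", x$id, genome_length(x)))
    if (nrow(f) > 0) {
      lines <- c(lines, sprintf(
        "%s\tplastrophy\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;status=%s",
        x$id, f$start + 1L, f$end, f$strand, f$name, f$name, f$status))
    }
    writeLines(lines, path_features)
  }
  invisible(x)
}

#' Write / read a gene-status table (TSV)
#'
#' @param calls data frame of gene-status calls (see [classify_gene()]).
#' @param path file path.
#' @return `read_status_table` returns the data frame.
#' @export
write_status_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' @rdname write_status_table
#' @export
read_status_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a paired read set to two FASTQ files
#'
#' Mates carry `/1` and `/2` name suffixes; quality strings are constant
#' (`I`), as downstream analyses never use base qualities.
#'
#' @param reads a `read_set` from [simulate_reads()].
#' @param path1,path2 output FASTQ paths for mate 1 and mate 2.
#' @return invisibly, `reads`.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  wr <- function(seqs, names, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  ids <- reads$pairs$qname
  wr(reads$pairs$mate1, paste0(ids, "/1"), path1)
  wr(reads$pairs$mate2, paste0(ids, "/2"), path2)
  invisible(reads)
}

#' Read a paired read set from two FASTQ files
#' @param path1,path2 FASTQ paths for mate 1 and mate 2 (same order).
#' @return a `read_set` object.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  stopifnot(length(r1) == length(r2))
  qn <- sub("/1$", "", sub("\\s.*$", "", names(r1)))
  new_read_set(data.frame(qname = qn, mate1 = as.character(r1),
                          mate2 = as.character(r2),
                          stringsAsFactors = FALSE),
               read_len = if (length(r1)) Biostrings::width(r1)[1] else 0L,
               insert_mean = NA_real_, insert_sd = NA_real_,
               error_rate = NA_real_, seed = NA_integer_)
}

#' Write intervals as BED
#' @param intervals data frame with columns `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param chrom chromosome/sequence name.
#' @param path output path.
#' @export
write_bed <- function(intervals, chrom, path) {
  df <- data.frame(chrom = chrom, start = intervals$start, end = intervals$end,
                   name = intervals$name %||% ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}
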