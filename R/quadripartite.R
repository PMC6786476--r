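## Quadripartite architecture: the pair of large inverted repeats (IRa/IRb)
## and the two single-copy regions (LSC/SSC) that partition a circular
## plastome. Intervals are 0-based half-open; `end` may exceed the genome
## length to wrap the origin.

interval_len <- function(iv) if (is.null(iv)) 0L else (iv[2] - iv[1])

## Normalize an interval on a circle of size n: start in [0, n).
norm_interval <- function(iv, n) {
  s <- iv[1] %% n
  c(s, s + (iv[2] - iv[1]))
}

## Does circular position p (0-based) fall inside interval iv on circle n?
pos_in_interval <- function(p, iv, n) {
  if (is.null(iv)) return(FALSE)
  rel <- (p - iv[1]) %% n
  rel < (iv[2] - iv[1])
}

intervals_overlap_circular <- function(a, b, n) {
  pos_in_interval(a[1] %% n, b, n) || pos_in_interval(b[1] %% n, a, n)
}

#' Partition a circular plastome into LSC / SSC / IRa / IRb
#'
#' Given the two IR intervals (from [call_ir()] or planted truth), labels the
#' longer single-copy gap LSC and the shorter SSC. With no IR, returns a
#' degenerate map with a single region spanning the genome. On a tie the
#' region containing more protein-coding features is labelled LSC.
#'
#' @param x a [plastome].
#' @param ir_call `NULL`, or a list with elements `ira` and `irb`, each
#'   `c(start, end)` (0-based half-open, circular wrap allowed).
#' @return an object of class `quadripartite_map` with elements `lsc`,
#'   `ssc`, `ira`, `irb` (intervals or `NULL`) and `lengths`.
#' @export
partition_quadripartite <- function(x, ir_call = NULL) {
  n <- genome_length(x)
  if (is.null(ir_call) || is.null(ir_call$ira)) {
    map <- structure(list(lsc = c(0L, n), ssc = NULL, ira = NULL, irb = NULL,
                          genome_length = n, degenerate = TRUE),
                     class = "quadripartite_map")
    return(add_map_lengths(map))
  }
  ira <- norm_interval(ir_call$ira, n)
  irb <- norm_interval(ir_call$irb, n)
  if (interval_len(ira) != interval_len(irb)) {
    stop("IR copies differ in length")
  }
  if (intervals_overlap_circular(ira, irb, n)) {
    stop("overlapping IR intervals")
  }
  ## single-copy gaps: from end of one IR to start of the other, circularly
  gap1 <- c(ira[2] %% n, NA); gap1[2] <- gap1[1] + ((irb[1] - ira[2]) %% n)
  gap2 <- c(irb[2] %% n, NA); gap2[2] <- gap2[1] + ((ira[1] - irb[2]) %% n)
  l1 <- interval_len(gap1); l2 <- interval_len(gap2)
  if (l1 + l2 + 2L * interval_len(ira) != n) {
    stop("IR intervals do not partition the genome")
  }
  pick_first_as_lsc <- if (l1 != l2) l1 > l2 else {
    count_protein <- function(gap) {
      f <- x$features
      if (nrow(f) == 0) return(0L)
      mid <- (f$start + (f$end - f$start) %/% 2) %% n
      sum(gene_type_of(f$gene_class) == "protein" &
            vapply(mid, pos_in_interval, logical(1), iv = gap, n = n))
    }
    count_protein(gap1) >= count_protein(gap2)
  }
  lsc <- if (pick_first_as_lsc) gap1 else gap2
  ssc <- if (pick_first_as_lsc) gap2 else gap1
  ## orient so that ira is the copy following the LSC
  if ((lsc[2] %% n) == (irb[1] %% n)) { tmp <- ira; ira <- irb; irb <- tmp }
  map <- structure(list(lsc = lsc, ssc = ssc, ira = ira, irb = irb,
                        genome_length = n, degenerate = FALSE),
                   class = "quadripartite_map")
  add_map_lengths(map)
}

add_map_lengths <- function(map) {
  map$lengths <- c(lsc = interval_len(map$lsc), ssc = interval_len(map$ssc),
                   ira = interval_len(map$ira), irb = interval_len(map$irb))
  stopifnot(sum(map$lengths) == map$genome_length)
  map
}

#' @export
print.quadripartite_map <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("quadripartite map (degenerate, no IR): single region of %d bp\n",
                x$genome_length))
  } else {
    cat(sprintf("quadripartite map: LSC %s / SSC %s / IR %s bp each (total %s)\n",
                format(x$lengths["lsc"], big.mark = ","),
                format(x$lengths["ssc"], big.mark = ","),
                format(x$lengths["ira"], big.mark = ","),
                format(x$genome_length, big.mark = ",")))
  }
  invisible(x)
}

## Strip IR-copy suffixes to get the unique gene symbol.
base_gene_name <- function(name) sub("_(ir|copy[0-9]+)$", "", name)

#' Summarize coding capacity by gene type and class
#'
#' Counts unique genes (IR-duplicated copies deduplicated; a unique gene
#' takes the best status among its copies, intact > pseudogene > absent)
#' cross-tabulated by status, by molecule type (protein/tRNA/rRNA) and by
#' functional gene class.
#'
#' @param x a [plastome] whose features are all classified.
#' @return list with `by_type` and `by_class` contingency tables, `n_unique`
#'   and `n_intact_unique`.
#' @export
summarize_coding_capacity <- function(x) {
  f <- x$features
  if (nrow(f) == 0) {
    empty <- table(factor(character(), levels = c("protein", "trna", "rrna")),
                   factor(character(), levels = setdiff(GENE_STATUSES, "unclassified")))
    return(list(by_type = empty, by_class = NULL, n_unique = 0L,
                n_intact_unique = 0L))
  }
  if (any(f$status == "unclassified")) {
    stop("unclassified features present; classify genes first")
  }
  base <- base_gene_name(f$name)
  rank <- match(f$status, c("intact", "pseudogene", "absent"))
  best <- tapply(rank, base, min)
  status <- c("intact", "pseudogene", "absent")[best]
  gclass <- gene_class_of(names(best))
  gtype <- gene_type_of(gclass)
  lv <- c("intact", "pseudogene", "absent")
  by_type <- table(factor(gtype, levels = c("protein", "trna", "rrna")),
                   factor(status, levels = lv))
  by_class <- table(factor(gclass, levels = GENE_CLASSES),
                    factor(status, levels = lv))
  list(by_type = by_type, by_class = by_class,
       n_unique = length(best),
       n_intact_unique = sum(status == "intact"))
}

#' Collapse one IR copy of a plastome
#'
#' Excises the IRb interval (sequence and the features it contains), keeping
#' the IRa copies, as rearrangement analyses require single-copy genomes.
#' Without an IR the genome is returned unchanged.
#'
#' @param x a [plastome].
#' @param map a `quadripartite_map` for `x`.
#' @return a [plastome] of length `length(x) - len(IR)`.
#' @export
collapse_ir <- function(x, map) {
  if (map$degenerate) return(x)
  n <- genome_length(x)
  y <- rotate_plastome(x, map$irb[1] %% n)
  L <- interval_len(map$irb)
  keep_seq <- substr(y$sequence, L + 1L, n)
  f <- y$features
  if (nrow(f) > 0) {
    inside <- f$start < L & f$end <= L
    straddle <- (f$start < L & f$end > L) | (f$end > n)
    if (any(straddle)) {
      warning("dropping ", sum(straddle), " feature(s) straddling the IR boundary")
    }
    f <- f[!(inside | straddle), , drop = FALSE]
    f$start <- f$start - L
    f$end <- f$end - L
  }
  plastome(x$id, keep_seq, circular = x$circular, features = f)
}
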