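# Independent brute-force oracles used throughout the suite. Each oracle
# re-derives the quantity from first principles (diagonal scans, exhaustive
# search, dense linear algebra) and never calls the code path it checks.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

str_rev <- function(s) intToUtf8(rev(utf8ToInt(s)))

## ---- repeat oracle -------------------------------------------------------

## All maximal <=k-mismatch windows between circular x and its transform,
## by scanning every diagonal's circular match vector and cutting at every
## (k+1)-st mismatch. Returns canonical pairs after the same reporting
## filters the package applies (self-identical dropped, unordered pairs
## deduplicated, overlap > 50% of the shorter suppressed).
oracle_repeats <- function(seq, class, min_len, k) {
  n <- nchar(seq)
  tr <- switch(class,
               forward = seq,
               reverse = str_rev(seq),
               complement = chartr("ACGT", "TGCA", seq),
               inverted = rc(seq))
  a <- strsplit(seq, "")[[1]]
  t <- strsplit(tr, "")[[1]]
  res <- list()
  for (d in 0:(n - 1)) {
    m <- a == t[((seq_len(n) - 1 + d) %% n) + 1]
    if (all(m)) {
      if (n >= min_len) res[[length(res) + 1L]] <- c(d, 0L, n, 0L)
      next
    }
    falses <- which(!m) - 1L            # 0-based mismatch positions
    nf <- length(falses)
    if (nf <= k) next                   # degenerate near-full-circle: skip
    ## maximal windows lie between falses[j] and the (k+1)-th following
    ## mismatch (circular index), containing the k mismatches in between
    for (j in seq_len(nf)) {
      jn <- ((j - 1L + k + 1L) %% nf) + 1L
      f1 <- falses[j]
      f2 <- falses[jn]
      len <- ((f2 - f1 - 1L) %% n)
      if (len == 0L) next
      start <- (f1 + 1L) %% n
      idx <- (start + 0:(len - 1L)) %% n
      mism <- sum(!m[idx + 1L])
      if (len >= min_len && mism <= k) {
        res[[length(res) + 1L]] <- c(d, start, len, mism)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer(), mismatches = integer()))
  }
  w <- unique(do.call(rbind, res))
  d <- w[, 1]; start <- w[, 2]; len <- w[, 3]; mism <- w[, 4]
  start_t <- (start + d) %% n
  start_b <- if (class %in% c("forward", "complement")) start_t else
    (n - start_t - len) %% n
  df <- data.frame(start_a = start, start_b = start_b, length = len,
                   mismatches = mism)
  df <- df[df$start_a != df$start_b, , drop = FALSE]
  s1 <- pmin(df$start_a, df$start_b); s2 <- pmax(df$start_a, df$start_b)
  df$start_a <- s1; df$start_b <- s2
  df <- df[!duplicated(df[, c("start_a", "start_b", "length")]), ,
           drop = FALSE]
  if (nrow(df) > 0) {
    ov <- mapply(plastrophy:::arc_intersect_len, df$start_a, df$length,
                 df$start_b, df$length, MoreArgs = list(n = n))
    df <- df[ov <= 0.5 * df$length, , drop = FALSE]
  }
  df[order(-df$length, df$start_a, df$start_b), , drop = FALSE]
}

## ---- tandem oracle -------------------------------------------------------

oracle_tandem <- function(seq, min_total = 10, unit_range = c(2, 50)) {
  n <- nchar(seq)
  a <- strsplit(seq, "")[[1]]
  primitive <- function(start0, u) {
    unit <- a[((start0 + 0:(u - 1)) %% n) + 1]
    for (dd in seq_len(u %/% 2)) {
      if (u %% dd == 0 &&
          all(unit == unit[((0:(u - 1)) %% dd) + 1])) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (u in unit_range[1]:min(unit_range[2], n %/% 2)) {
    t <- a == a[((seq_len(n) - 1 + u) %% n) + 1]
    if (all(t)) {
      if (n %% u == 0 && n >= min_total && n / u >= 2 && primitive(0, u)) {
        out[[length(out) + 1L]] <- c(0L, u, n)
      }
      next
    }
    ## circular runs of TRUE
    f <- which(!t) - 1L
    for (j in seq_along(f)) {
      nxt <- f[(j %% length(f)) + 1L]
      run <- ((nxt - f[j] - 1L) %% n)
      if (run == 0) next
      run_start <- (f[j] + 1L) %% n
      total <- run + u
      if (total >= min_total && run >= u && primitive(run_start, u)) {
        out[[length(out) + 1L]] <- c(run_start, u, total)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), unit_len = integer(),
                      total = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "unit_len", "total")
  df[order(df$start, df$unit_len), , drop = FALSE]
}

## ---- signed reversal BFS oracle (pure R, n <= 5) ------------------------

apply_rev_r <- function(p, i, j) {
  p[i:j] <- -rev(p[i:j])
  p
}

## full distance table from the identity by uninformed BFS; keys are
## comma-joined permutations
oracle_reversal_table <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    idp <- seq_len(n)
    dist <- new.env(parent = emptyenv())
    assign(paste(idp, collapse = ","), 0L, envir = dist)
    frontier <- list(idp)
    d <- 0L
    while (length(frontier) > 0) {
      nxt <- list()
      for (p in frontier) {
        for (i in seq_len(n)) for (j in i:n) {
          q <- apply_rev_r(p, i, j)
          kq <- paste(q, collapse = ",")
          if (is.null(dist[[kq]])) {
            dist[[kq]] <- d + 1L
            nxt[[length(nxt) + 1L]] <- q
          }
        }
      }
      d <- d + 1L
      frontier <- nxt
    }
    cache[[key]] <<- dist
    dist
  }
})

oracle_reversal_distance <- function(perm) {
  tab <- oracle_reversal_table(length(perm))
  tab[[paste(perm, collapse = ",")]]
}

## ---- dense BM likelihood oracle ------------------------------------------

oracle_bm_loglik <- function(tree, traits, mu, R) {
  C <- ape::vcv.phylo(tree)
  i <- match(rownames(C), traits$tip)
  y <- c(traits$x[i], traits$y[i])
  S <- kronecker(R, C)
  m <- rep(mu, each = nrow(C))
  as.numeric(-length(y) / 2 * log(2 * pi) -
               0.5 * determinant(S)$modulus -
               0.5 * t(y - m) %*% solve(S) %*% (y - m))
}

## ---- MRCA-depth covariance oracle ----------------------------------------

oracle_tree_covariance <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      anc <- if (i == j) i else ape::getMRCA(tree, c(i, j))
      C[i, j] <- depth[anc]
    }
  }
  C
}

## ---- misc helpers --------------------------------------------------------

random_signed_perm <- function(n) {
  sample(c(-1L, 1L), n, TRUE) * sample.int(n)
}

small_reference <- function(seed, n_protein = 20, n_trna = 6, n_rrna = 2,
                            intergenic_len = 200) {
  make_reference_plastome(n_protein = n_protein, n_trna = n_trna,
                          n_rrna = n_rrna, intergenic_len = intergenic_len,
                          seed = seed)
}
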