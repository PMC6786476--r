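## Correlated-trait evolution under Brownian motion (random walk) on a
## fixed phylogeny. Two traits X, Y evolve with rate matrix
## R = [[sx2, sxy], [sxy, sy2]]; tip values are multivariate normal with
## covariance R (x) C, where C is the matrix of shared root-to-tip path
## lengths. The free model estimates sxy; the null fixes sxy = 0; their
## likelihood ratio tests for correlated evolution.

#' Shared-path-length (Brownian motion) covariance of a tree
#'
#' `C[i, j]` is the depth of the most recent common ancestor of tips i and
#' j; `C[i, i]` is the root-to-tip depth of tip i.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric positive semidefinite matrix with tip-labelled rows.
#' @export
tree_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::vcv.phylo(tree)
}

check_rate_matrix <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == 2, ncol(R) == 2)
  if (abs(R[1, 2] - R[2, 1]) > 1e-12) stop("rate matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("rate matrix is not positive semidefinite")
  }
  invisible(R)
}

matrix_sqrt_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R)) %*% t(e$vectors)
}

#' Simulate two correlated Brownian traits on a tree
#'
#' Traverses the tree from the root, adding bivariate normal increments
#' with covariance `rate_matrix * branch_length` along each branch
#' (independent of the covariance-matrix route used by the likelihood
#' code).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param rate_matrix symmetric PSD 2x2 rate matrix.
#' @param root_state numeric length-2 root value.
#' @param seed integer seed.
#' @return data frame `tip`, `x`, `y`.
#' @export
simulate_traits <- function(tree, rate_matrix, root_state = c(0, 0),
                            seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  check_rate_matrix(rate_matrix)
  M <- matrix_sqrt_psd(rate_matrix)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  vals <- matrix(NA_real_, nrow = n_tip + tree$Nnode, ncol = 2)
  vals[root, ] <- root_state
  edges <- tree$edge
  ord <- order(edges[, 1])   # parents before children in cladewise numbering
  with_seed(seed, {
    for (i in ord) {
      par <- edges[i, 1]; ch <- edges[i, 2]
      bl <- tree$edge.length[i]
      z <- stats::rnorm(2)
      vals[ch, ] <- vals[par, ] + sqrt(bl) * as.numeric(M %*% z)
    }
  })
  data.frame(tip = tree$tip.label, x = vals[seq_len(n_tip), 1],
             y = vals[seq_len(n_tip), 2], stringsAsFactors = FALSE)
}

traits_matrix <- function(tree, traits) {
  if (is.data.frame(traits)) {
    stopifnot(all(c("tip", "x", "y") %in% names(traits)))
    i <- match(tree$tip.label, traits$tip)
    if (anyNA(i)) stop("traits missing for tips: ",
                       paste(setdiff(tree$tip.label, traits$tip),
                             collapse = ", "))
    cbind(x = traits$x[i], y = traits$y[i])
  } else {
    m <- as.matrix(traits)
    m[tree$tip.label, , drop = FALSE]
  }
}

## floor zero-length terminal branches so C stays nonsingular
floor_terminal_branches <- function(tree, frac = 1e-8) {
  n_tip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= n_tip
  h <- max(ape::node.depth.edgelength(tree))
  zero <- term & tree$edge.length <= 0
  if (any(zero)) tree$edge.length[zero] <- frac * h
  tree
}

#' Log-likelihood of bivariate Brownian traits
#'
#' Evaluates the log density of the stacked tip vector (X, Y) under the
#' multivariate normal with mean `(mu_x 1, mu_y 1)` and covariance
#' `R (x) C`, computed through per-trait whitening by the Cholesky factor
#' of C (never by building the dense 2n x 2n covariance).
#'
#' @param tree an `ape::phylo`.
#' @param traits data frame `tip`, `x`, `y` or tip-named 2-column matrix.
#' @param params list with `mu` (length 2), `R` (2x2 rate matrix).
#' @param correlated logical; when `FALSE` the off-diagonal of `R` is
#'   forced to zero.
#' @return log-likelihood (numeric scalar).
#' @export
bm_loglik <- function(tree, traits, params, correlated = TRUE) {
  Y <- traits_matrix(tree, traits)
  n <- nrow(Y)
  R <- params$R
  if (!correlated) { R[1, 2] <- 0; R[2, 1] <- 0 }
  check_rate_matrix(R)
  C <- tree_covariance(tree)
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular tree covariance: ", conditionMessage(e)))
  detR <- R[1, 1] * R[2, 2] - R[1, 2]^2
  if (detR <= 0 || R[1, 1] <= 0 || R[2, 2] <= 0) {
    stop("singular rate matrix in likelihood evaluation")
  }
  E <- Y - rep(1, n) %o% params$mu
  Z <- backsolve(ch, E, transpose = TRUE)   # C^{-1} = Z'Z relation
  S <- crossprod(Z)                          # E' C^{-1} E
  Rinv <- solve(R)
  quad <- sum(Rinv * S)
  logdetC <- 2 * sum(log(diag(ch)))
  -n * log(2 * pi) - n / 2 * log(detR) - logdetC - quad / 2
}

#' Fit the bivariate Brownian model (free or independent)
#'
#' Maximum likelihood: root means by generalized least squares given C and
#' the rate matrix by the whitened cross-products (the closed-form ML
#' estimator); the independent model zeroes the covariance rate.
#'
#' @param tree an `ape::phylo` (zero-length terminal branches are floored
#'   at `1e-8` of tree height).
#' @param traits data frame `tip`, `x`, `y` or tip-named matrix.
#' @param correlated fit the free model (`TRUE`) or the independent null.
#' @return object of class `bm_fit` with components `mu`, `R`,
#'   `correlation`, `logLik`, `n`, `correlated`, `converged`.
#' @export
fit_bm <- function(tree, traits, correlated = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tree <- floor_terminal_branches(tree)
  Y <- traits_matrix(tree, traits)
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 tips")
  C <- tree_covariance(tree)
  ch <- chol(C)
  W <- backsolve(ch, cbind(1, Y), transpose = TRUE)  # whitened [1, X, Y]
  one <- W[, 1]; Z <- W[, 2:3, drop = FALSE]
  denom <- sum(one^2)
  mu <- colSums(Z * one) / denom
  E <- Z - one %o% mu
  S <- crossprod(E) / n
  if (any(diag(S) <= 0)) {
    stop("degenerate trait (zero evolutionary variance); cannot fit")
  }
  if (!correlated) { S[1, 2] <- 0; S[2, 1] <- 0 }
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  ## keep the likelihood finite for perfectly collinear traits
  r2 <- min(r^2, 1 - 1e-12)
  detS <- S[1, 1] * S[2, 2] * (1 - r2)
  logdetC <- 2 * sum(log(diag(ch)))
  ll <- -n * log(2 * pi) - n / 2 * log(detS) - logdetC - n
  structure(list(mu = stats::setNames(mu, c("x", "y")), R = S,
                 correlation = r, logLik = ll, n = n,
                 correlated = correlated, converged = TRUE,
                 tree = tree),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("Bivariate Brownian-motion fit (%s model), %d tips\n",
              if (x$correlated) "free" else "independent", x$n))
  cat(sprintf("  root means: mu_x = %.4g, mu_y = %.4g\n", x$mu[1], x$mu[2]))
  cat(sprintf("  rates: sx2 = %.4g, sy2 = %.4g, sxy = %.4g (r = %.3f)\n",
              x$R[1, 1], x$R[2, 2], x$R[1, 2], x$correlation))
  cat(sprintf("  logLik = %.4f\n", x$logLik))
  invisible(x)
}

#' @export
coef.bm_fit <- function(object, ...) {
  c(mu_x = unname(object$mu[1]), mu_y = unname(object$mu[2]),
    sx2 = object$R[1, 1], sy2 = object$R[2, 2], sxy = object$R[1, 2])
}

#' @export
logLik.bm_fit <- function(object, ...) {
  structure(object$logLik, df = if (object$correlated) 5 else 4,
            nobs = 2 * object$n, class = "logLik")
}

#' Likelihood ratio test for correlated trait evolution
#'
#' Compares the free bivariate Brownian model against the independent
#' null. The raw statistic is `LR = 2 (lnL_free - lnL_null)`; the reported
#' p-value uses a Bartlett-type small-sample correction (the statistic is
#' rescaled so its null expectation equals 1, using the exact null
#' distribution of the whitened-residual correlation) against chi-square
#' with 1 degree of freedom. Binary 0/1 traits are accepted and analyzed
#' under the continuous random-walk model; a caveat field records this.
#'
#' @param tree an `ape::phylo`.
#' @param traits data frame `tip`, `x`, `y` or tip-named matrix.
#' @return object of class `bm_lrt`: `LR`, `LR_corrected`, `df`, `p`,
#'   `correlation`, `fit_free`, `fit_null`, `caveat`.
#' @export
lrt_correlation <- function(tree, traits) {
  free <- fit_bm(tree, traits, correlated = TRUE)
  null <- fit_bm(tree, traits, correlated = FALSE)
  LR <- 2 * (free$logLik - null$logLik)
  LR <- max(LR, 0)
  n <- free$n
  nu <- n - 1                      # residual dimension after the GLS mean
  bartlett <- n * (digamma(nu / 2) - digamma((nu - 1) / 2))
  LRc <- LR / bartlett
  p <- stats::pchisq(LRc, df = 1, lower.tail = FALSE)
  Y <- traits_matrix(tree, traits)
  binary <- apply(Y, 2, function(v) all(v %in% c(0, 1)))
  caveat <- if (any(binary)) {
    paste0("trait(s) ", paste(c("x", "y")[binary], collapse = ", "),
           " are binary 0/1 but analyzed under the continuous ",
           "random-walk model")
  } else NA_character_
  structure(list(LR = LR, LR_corrected = LRc, df = 1L, p = p,
                 correlation = free$correlation, fit_free = free,
                 fit_null = null, caveat = caveat),
            class = "bm_lrt")
}

#' @export
print.bm_lrt <- function(x, ...) {
  cat(sprintf("LRT for correlated Brownian evolution: r = %.3f\n",
              x$correlation))
  cat(sprintf("  LR = %.4f (Bartlett-corrected %.4f), df = %d, p = %.4g\n",
              x$LR, x$LR_corrected, x$df, x$p))
  if (!is.na(x$caveat)) cat("  note:", x$caveat, "\n")
  invisible(x)
}

#' Read / write the TSV trait table
#' @param path TSV with columns `tip`, `x`, `y` (or `tip`, `trait`,
#'   `value` long format).
#' @return data frame `tip`, `x`, `y`.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (all(c("trait", "value") %in% names(tab))) {
    wide <- stats::reshape(tab, idvar = "tip", timevar = "trait",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    tab <- wide
  }
  stopifnot(all(c("tip", "x", "y") %in% names(tab)) ||
              ncol(tab) >= 3)
  if (!all(c("x", "y") %in% names(tab))) {
    names(tab)[2:3] <- c("x", "y")
  }
  tab
}
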