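test_that("tree covariance matches closed forms and the MRCA-depth oracle", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(unname(tree_covariance(star)), diag(4))
  two <- ape::read.tree(text = "(a:1.5,b:0.7);")
  expect_equal(unname(tree_covariance(two)),
               matrix(c(1.5, 0, 0, 0.7), 2))
  for (i in 1:5) {
    set.seed(8100 + i)
    tr <- ape::rtree(6)
    C <- tree_covariance(tr)
    O <- oracle_tree_covariance(tr)
    expect_equal(C[rownames(O), colnames(O)], O, tolerance = 1e-12)
  }
  bad <- ape::rtree(4)
  bad$edge.length[1] <- -0.1
  expect_error(tree_covariance(bad), "negative")
})

test_that("bm_loglik equals closed forms and the dense Kronecker oracle", {
  ## n = 2 independent traits: sum of univariate normal log densities
  two <- ape::read.tree(text = "(a:1.2,b:0.8);")
  tt <- data.frame(tip = c("a", "b"), x = c(0.3, -0.6), y = c(1.1, 0.2))
  mu <- c(0.1, 0.4); R <- diag(c(0.9, 1.4))
  ll <- bm_loglik(two, tt, list(mu = mu, R = R), correlated = FALSE)
  byhand <- sum(dnorm(tt$x, mu[1], sqrt(0.9 * c(1.2, 0.8)), log = TRUE)) +
    sum(dnorm(tt$y, mu[2], sqrt(1.4 * c(1.2, 0.8)), log = TRUE))
  expect_equal(ll, byhand, tolerance = 1e-10)
  ## sxy = 0: free and null forms coincide
  set.seed(82)
  tr <- ape::rtree(6)
  tt2 <- simulate_traits(tr, diag(2), seed = 82)
  p <- list(mu = c(0, 0), R = diag(2))
  expect_equal(bm_loglik(tr, tt2, p, correlated = TRUE),
               bm_loglik(tr, tt2, p, correlated = FALSE))
  ## dense oracle on random instances
  for (i in 1:10) {
    set.seed(8200 + i)
    tr <- ape::rtree(sample(3:8, 1))
    r <- runif(1, -0.8, 0.8)
    R <- matrix(c(1.2, r, r, 0.7), 2)
    tt3 <- simulate_traits(tr, R, seed = i)
    mu3 <- rnorm(2)
    expect_equal(bm_loglik(tr, tt3, list(mu = mu3, R = R)),
                 oracle_bm_loglik(tr, tt3, mu3, R), tolerance = 1e-8)
  }
})

test_that("closed-form ML fit: degeneracies and nesting", {
  set.seed(83)
  tr <- ape::rtree(12)
  tt <- simulate_traits(tr, diag(2), seed = 83)
  free <- fit_bm(tr, tt, correlated = TRUE)
  null <- fit_bm(tr, tt, correlated = FALSE)
  expect_gte(free$logLik, null$logLik)
  expect_lte(abs(free$R[1, 2]), sqrt(free$R[1, 1] * free$R[2, 2]))
  ## identical traits: correlation estimate pegged at 1
  tt$y <- tt$x
  ff <- fit_bm(tr, tt)
  expect_gte(ff$correlation, 0.999)
  lr <- lrt_correlation(tr, tt)
  expect_lt(lr$p, 1e-6)
  ## the fitted logLik maximizes bm_loglik over a parameter grid probe
  tt2 <- simulate_traits(tr, matrix(c(1, .5, .5, 1), 2), seed = 84)
  fit <- fit_bm(tr, tt2)
  ll_at <- function(f) bm_loglik(tr, tt2, list(mu = f$mu, R = f$R))
  expect_equal(ll_at(fit), fit$logLik, tolerance = 1e-8)
  for (eps in c(0.05, -0.07)) {
    Rp <- fit$R; Rp[1, 1] <- Rp[1, 1] * (1 + eps)
    expect_lte(bm_loglik(tr, tt2, list(mu = fit$mu, R = Rp)), fit$logLik)
  }
})

test_that("LRT is calibrated on a star tree against the ordinary correlation test", {
  ## equal-branch star tree: phylogenetic and ordinary bivariate-normal
  ## analyses coincide; the raw LR must match -n log(1 - r^2) with the
  ## ordinary (ML) correlation of the centered data
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1,g:1,h:1);")
  set.seed(85)
  tt <- simulate_traits(star, matrix(c(1, .4, .4, 1), 2), seed = 85)
  lr <- lrt_correlation(star, tt)
  x <- tt$x - mean(tt$x); y <- tt$y - mean(tt$y)
  r2 <- (sum(x * y) / sqrt(sum(x^2) * sum(y^2)))^2
  expect_equal(lr$LR, -8 * log(1 - r2), tolerance = 1e-6)
  expect_equal(lr$correlation, sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
               tolerance = 1e-10)
})

test_that("parameter recovery: rate estimates nearly unbiased at n = 64", {
  ests <- numeric(120)
  tr <- plastrophy:::with_seed(86, ape::rcoal(64))
  for (i in seq_along(ests)) {
    tt <- simulate_traits(tr, diag(2), seed = 8600 + i)
    ests[i] <- fit_bm(tr, tt)$R[1, 1]
  }
  expect_lt(abs(mean(ests) - 1), 0.1)
})

test_that("the closed-form fit matches an independent ML implementation", {
  tr <- plastrophy:::with_seed(5, ape::rcoal(12))
  tt <- simulate_traits(tr, matrix(c(1, .5, .5, 1), 2), seed = 6)
  X <- cbind(x = tt$x, y = tt$y)
  rownames(X) <- tt$tip
  ev <- phytools::evol.vcv(tr, X)
  f <- fit_bm(tr, tt)
  expect_equal(unname(ev$R), unname(f$R), tolerance = 1e-6)
  expect_equal(ev$logL1, f$logLik, tolerance = 1e-6)
})

test_that("binary traits are accepted with a caveat", {
  set.seed(87)
  tr <- ape::rcoal(10)
  tt <- simulate_traits(tr, diag(2), seed = 87)
  tt$y <- as.numeric(tt$y > median(tt$y))
  lr <- lrt_correlation(tr, tt)
  expect_false(is.na(lr$caveat))
  expect_true(lr$p > 0 && lr$p <= 1)
})
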