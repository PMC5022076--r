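# synthetic genes x samples matrix with k independent Laplace sources
# (the classic ICA benchmark); noiseless by default so the data have
# exact rank k
planted_sources <- function(n_genes, n_samples, k, noise = 0, seed = 1) {
  set.seed(seed)
  loads <- matrix(rexp(n_genes * k) - rexp(n_genes * k), n_genes, k)
  act <- matrix(rnorm(k * n_samples), k, n_samples)
  X <- loads %*% act
  if (noise > 0) X <- X + matrix(rnorm(n_genes * n_samples, sd = noise),
                                 n_genes, n_samples)
  rownames(X) <- sprintf("g%04d", seq_len(n_genes))
  list(X = X, loads = loads)
}

test_that("ensembles are deterministic in the seed", {
  ps <- planted_sources(80, 12, 2, seed = 3)
  e1 <- run_ica_ensemble(ps$X, 2, n_iter = 5, seed = 9)
  e2 <- run_ica_ensemble(ps$X, 2, n_iter = 5, seed = 9)
  expect_identical(e1$loads, e2$loads)
  e3 <- run_ica_ensemble(ps$X, 2, n_iter = 5, seed = 10)
  expect_false(identical(e1$loads, e3$loads))
  expect_error(run_ica_ensemble(ps$X, 12), "n_components")
})

test_that("on exact rank-2 data every run spans the same load subspace", {
  ps <- planted_sources(100, 10, 2, seed = 5)
  ens <- run_ica_ensemble(ps$X, 2, n_iter = 8, seed = 2)
  expect_gte(mean(ens$converged), 0.95)
  base <- svd(scale(ps$X, scale = FALSE), nu = 2)$u
  for (L in ens$loads) {
    # residual of projecting run loads onto the data's rank-2 column space
    resid <- L - base %*% (t(base) %*% L)
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("alignment matches the exhaustive 2-component assignment", {
  set.seed(11)
  truth <- matrix(rnorm(60 * 2), 60, 2)
  runs <- list(truth,
               truth[, 2:1] * rep(c(-1, 1), each = 60),  # swapped, flipped
               truth + rnorm(120, sd = 0.01))
  runs <- lapply(runs, function(m) {
    rownames(m) <- sprintf("g%02d", 1:60); m
  })
  ens <- structure(list(loads = runs, converged = rep(TRUE, 3),
                        n_components = 2L),
                   class = "ica_ensemble")
  cons <- align_components(ens)
  expect_gt(min(cons$rbar), 0.999)
  # exhaustive check: of the 2 possible matchings for run 2, the swap has
  # the larger total |correlation|, and alignment must pick it
  cc <- abs(cor(runs[[1]], runs[[2]]))
  expect_gt(cc[1, 2] + cc[2, 1], cc[1, 1] + cc[2, 2])
  # consensus is invariant (up to sign) to which run is the reference
  ens_rev <- structure(list(loads = rev(runs), converged = rep(TRUE, 3),
                            n_components = 2L),
                       class = "ica_ensemble")
  cons_rev <- align_components(ens_rev)
  ccc <- abs(cor(cons$consensus, cons_rev$consensus))
  expect_gt(max(ccc[1, ]), 0.999)
  expect_gt(max(ccc[2, ]), 0.999)
})

test_that("identical runs give rbar 1; independent runs give rbar near 0", {
  set.seed(13)
  L <- matrix(rnorm(50 * 2), 50, 2,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  ens_same <- structure(list(loads = rep(list(L), 5),
                             converged = rep(TRUE, 5), n_components = 2L),
                        class = "ica_ensemble")
  expect_equal(unname(align_components(ens_same)$rbar), c(1, 1),
               tolerance = 1e-12)
  rand_runs <- lapply(1:10, function(i) {
    m <- matrix(rnorm(100), 50, 2)
    rownames(m) <- sprintf("g%02d", 1:50); m
  })
  ens_rand <- structure(list(loads = rand_runs,
                             converged = rep(TRUE, 10), n_components = 2L),
                        class = "ica_ensemble")
  expect_lt(max(align_components(ens_rand)$rbar), 0.3)
})

test_that("component-count selection keys on reproducibility and rank", {
  ps <- planted_sources(400, 14, 3, seed = 7)
  res <- select_component_count(ps$X, counts = 2:5, r_cut = 0.999,
                                n_iter = 10, seed = 3)
  # rank-3 noiseless data: counts above 3 cannot whiten and cannot pass
  tab <- res$rbar_table
  expect_gt(min(tab$rbar[tab$n_components == 3]), 0.999)
  expect_equal(max(tab$rbar[tab$n_components > 3]), 0)
  expect_equal(res$n_star, 3)
  # vacuous threshold takes the largest feasible count
  res0 <- select_component_count(ps$X, counts = 2:3, r_cut = 0,
                                 n_iter = 6, seed = 3)
  expect_equal(res0$n_star, 3)
  # pure noise: no count above 2 reproduces at r > 0.999
  set.seed(1)
  noise <- matrix(rnorm(300 * 21), 300, 21,
                  dimnames = list(sprintf("g%04d", 1:300), NULL))
  res_n <- select_component_count(noise, counts = 3:6, r_cut = 0.999,
                                  n_iter = 15, seed = 5)
  expect_true(is.na(res_n$n_star))
})

test_that("lowering r_cut never decreases the selected count", {
  ps <- planted_sources(200, 12, 2, noise = 0.2, seed = 19)
  for (s in 1:3) {
    res_hi <- select_component_count(ps$X, counts = 2:4, r_cut = 0.999,
                                     n_iter = 8, seed = s)
    res_lo <- select_component_count(ps$X, counts = 2:4, r_cut = 0.5,
                                     n_iter = 8, seed = s)
    n_hi <- ifelse(is.na(res_hi$n_star), 0L, res_hi$n_star)
    n_lo <- ifelse(is.na(res_lo$n_star), 0L, res_lo$n_star)
    expect_gte(n_lo, n_hi)
  }
})

test_that("significant loads apply the |z| > 3 rule", {
  set.seed(23)
  z <- matrix(rnorm(10000), ncol = 1,
              dimnames = list(sprintf("g%05d", 1:10000), "C1"))
  hits <- significant_loads(z, z_cut = 3)
  frac <- nrow(hits) / 10000
  expected <- 2 * pnorm(-3)
  se3 <- 3 * sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), se3 + 1e-9)
  expect_setequal(hits$gene, rownames(z)[abs(z[, 1]) > 3])
  # planted strong loads are all flagged; all-zero loads give none
  set.seed(24)
  z2 <- matrix(c(rep(6, 50), rnorm(450)), ncol = 1,
               dimnames = list(sprintf("g%03d", 1:500), "C1"))
  hits2 <- significant_loads(z2)
  expect_true(all(sprintf("g%03d", 1:50) %in% hits2$gene))
  expect_true(all(hits2$direction[match(sprintf("g%03d", 1:50),
                                        hits2$gene)] == "positive"))
  z0 <- matrix(0, 20, 1, dimnames = list(sprintf("g%02d", 1:20), "C1"))
  expect_equal(nrow(significant_loads(z0)), 0)
})

test_that("planted source counts are recovered across seeds", {
  hits <- vapply(1:12, function(i) {
    k <- 2 + (i - 1) %% 4                 # k cycles through 2..5
    ps <- planted_sources(1000, 21, k, seed = 500 + i)
    res <- select_component_count(ps$X, counts = 2:6, r_cut = 0.999,
                                  n_iter = 10, seed = i)
    identical(as.integer(res$n_star), as.integer(k))
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})
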