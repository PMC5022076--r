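test_that("dtw_distance handles the basic contracts", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  # 3x3 table, every cell cost 1, optimal path is the 3-step diagonal
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)), 3)
  expect_error(dtw_distance(1, c(1, 2)), "length")
  expect_error(dtw_distance(c(1, NA, 2), c(1, 2, 3)), "missing")
})

test_that("dtw_distance is symmetric and matches brute-force enumeration", {
  set.seed(7)
  for (i in 1:60) {
    la <- sample(2:4, 1); lb <- sample(2:4, 1)
    a <- round(rnorm(la), 2); b <- round(rnorm(lb), 2)
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_distance(b, a))
    expect_equal(d, brute_dtw(a, b))
  }
})

test_that("vectorized DTW against a reference equals the scalar version", {
  set.seed(8)
  trajs <- matrix(rnorm(40 * 7), 40, 7,
                  dimnames = list(sprintf("g%02d", 1:40), NULL))
  ref <- rep(0, 7)
  fast <- neurodyn:::dtw_to_reference(trajs, ref)
  slow <- apply(trajs, 1, dtw_distance, b = ref)
  expect_equal(fast, slow)
})

test_that("noise calibration recovers a near-zero intercept and tau = 2 u0", {
  nm <- calibrate_noise_null(7, n_noise = 150,
                             noise_levels = seq(0.05, 0.3, by = 0.05),
                             seed = 4)
  expect_lt(abs(nm$intercept), 3 * nm$se_intercept)
  expect_gt(nm$slope, 0)
  expect_equal(nm$tau, 2 * nm$u0)
  expect_equal(nm$u0, nm$intercept + 1.96 * nm$se_intercept)
  # near-zero noise levels drive the intercept to zero
  tiny <- calibrate_noise_null(7, n_noise = 50,
                               noise_levels = c(1e-4, 2e-4, 3e-4),
                               seed = 5)
  expect_lt(abs(tiny$intercept), 3 * tiny$se_intercept + 1e-6)
  expect_error(calibrate_noise_null(7, noise_levels = c(-0.1, 0.1, 0.2)),
               "non-negative")
  expect_error(calibrate_noise_null(7, noise_levels = c(0.1, 0.1, 0.1)),
               "distinct")
})

test_that("tau does not decrease when the calibration noise grows", {
  base <- calibrate_noise_null(7, n_noise = 100,
                               noise_levels = seq(0.05, 0.3, 0.05),
                               seed = 9)
  bigger <- calibrate_noise_null(7, n_noise = 100,
                                 noise_levels = 2 * seq(0.05, 0.3, 0.05),
                                 seed = 9)
  expect_gte(bigger$tau, base$tau)
})

test_that("dynamic flags separate planted from flat genes", {
  s <- simulate_timecourse(sim_config(n_genes = 300, noise_sd = 0,
                                      replicate_sd = 0, n_modules = 0,
                                      seed = 17))
  x <- s$experiment
  x$signal <- log2(x$signal); x$log2 <- TRUE
  gx <- collapse_probes(x, s$truth$probe_map)
  expressed <- expressed_set(gx)
  nm <- calibrate_noise_null(7, n_noise = 100, seed = 2)
  res <- select_dynamic_genes(gx, nm, genes = expressed)
  truth <- s$truth$genes
  flat <- truth$gene[truth$class == "flat_expressed"]
  dyn <- truth$gene[truth$class %in% c("monotone_up", "monotone_down",
                                       "transient")]
  tab <- res$table
  expect_equal(tab$dtw_dist[match(flat, tab$gene)], rep(0, length(flat)))
  expect_false(any(tab$dynamic[match(flat, tab$gene)]))
  expect_true(all(tab$dynamic[match(dyn, tab$gene)]))
  # dynamic calls are a subset of the expressed universe
  expect_true(all(tab$gene %in% expressed))
})

test_that("planted monotone genes are detected at signal-to-noise 5", {
  s <- simulate_timecourse(sim_config(n_genes = 400, noise_sd = 0.1,
                                      effect_size = 0.5, n_modules = 0,
                                      seed = 23))
  x <- s$experiment
  x$signal <- log2(x$signal); x$log2 <- TRUE
  gx <- collapse_probes(x, s$truth$probe_map)
  nm <- calibrate_noise_null(7, n_noise = 100, seed = 3)
  res <- select_dynamic_genes(gx, nm, genes = expressed_set(gx))
  up <- s$truth$genes$gene[s$truth$genes$class == "monotone_up"]
  sens <- mean(res$table$dynamic[match(up, res$table$gene)])
  expect_gte(sens, 0.95)
})

test_that("low-noise null genes stay mostly below the threshold", {
  # flat genes whose trajectory noise sits below the calibration grid
  s <- simulate_timecourse(sim_config(
    n_genes = 400, n_modules = 0,
    class_fractions = c(flat_expressed = 1, not_expressed = 0,
                        monotone_up = 0, monotone_down = 0,
                        transient = 0),
    seed = 29))
  x <- s$experiment
  x$signal <- log2(x$signal); x$log2 <- TRUE
  gx <- collapse_probes(x, s$truth$probe_map)
  nm <- calibrate_noise_null(7, n_noise = 200, seed = 6)
  res <- select_dynamic_genes(gx, nm, genes = expressed_set(gx))
  expect_lte(mean(res$table$dynamic), 0.05)
})

test_that("trajectory clustering finds planted archetypes", {
  ramp <- seq(0, 1, length.out = 7)
  # two well-separated shapes, exact duplicates -> k* = 2, ARI = 1
  trajs <- rbind(matrix(rep(2 * ramp, 30), 30, byrow = TRUE),
                 matrix(rep(-2 * ramp, 30), 30, byrow = TRUE))
  rownames(trajs) <- sprintf("g%03d", 1:60)
  res <- structure(
    list(table = tibble::tibble(gene = rownames(trajs),
                                dtw_dist = 1, dynamic = TRUE),
         trajectories = trajs,
         noise_model = calibrate_noise_null(7, n_noise = 30, seed = 1)),
    class = "dtw_result")
  out <- cluster_trajectories(res, k_max = 6, n_init = 10, seed = 2)
  expect_equal(out$k, 2L)
  truth <- rep(1:2, each = 30)
  expect_equal(adjusted_rand(out$clusters$cluster, truth), 1)
  # cluster 1 must be the positive responder (ordering rule)
  expect_gt(out$cluster_means[1, 7], 0)
})

test_that("identical trajectories collapse to a single cluster", {
  trajs <- matrix(rep(seq(0, 2, length.out = 7), 20), 20, byrow = TRUE)
  rownames(trajs) <- sprintf("g%03d", 1:20)
  res <- structure(
    list(table = tibble::tibble(gene = rownames(trajs), dtw_dist = 1,
                                dynamic = TRUE),
         trajectories = trajs,
         noise_model = calibrate_noise_null(7, n_noise = 30, seed = 1)),
    class = "dtw_result")
  out <- cluster_trajectories(res, k_max = 6, n_init = 5, seed = 4)
  expect_equal(out$k, 1L)
  expect_error(cluster_trajectories(res, k_max = 25, n_init = 5, seed = 1),
               "k_max")
})

test_that("five planted shapes are recovered with matching directions", {
  # three positive responders of graded strength, two negative ones
  s <- seq(0, 1, length.out = 7)
  bump <- function(c0, w = 0.18) {
    b <- exp(-(s - c0)^2 / (2 * w^2)); b - b[1]
  }
  shapes <- rbind(4 * s,
                  1.6 * bump(0.4) + 0.6 * s,
                  1.5 * sqrt(s),
                  -4 * s,
                  -1.5 * bump(0.55) - 0.8 * s)
  set.seed(6)
  trajs <- shapes[rep(1:5, each = 25), ] +
    matrix(rnorm(125 * 7, sd = 0.02), 125, 7)
  rownames(trajs) <- sprintf("g%03d", 1:125)
  res <- structure(
    list(table = tibble::tibble(gene = rownames(trajs), dtw_dist = 1,
                                dynamic = TRUE),
         trajectories = trajs,
         noise_model = calibrate_noise_null(7, n_noise = 30, seed = 1)),
    class = "dtw_result")
  out <- cluster_trajectories(res, k_max = 10, n_init = 25, seed = 8)
  expect_equal(out$k, 5L)
  truth <- rep(1:5, each = 25)
  expect_equal(adjusted_rand(out$clusters$cluster, truth), 1)
  # signs of the mean final fold change match the planted directions
  final <- out$cluster_means[, 7]
  expect_equal(sum(final > 0), 3)
  expect_equal(sum(final < 0), 2)
})

test_that("tidy and glance expose distances, flags and clusters", {
  nm <- calibrate_noise_null(7, n_noise = 30, seed = 1)
  trajs <- rbind(g1 = rep(0, 7), g2 = seq(0, 2, length.out = 7))
  x <- make_tc(trajs[, rep(1:7, each = 1)], divs = c(0, 1, 3, 5, 7, 9, 11),
               n_rep = 1)
  res <- select_dynamic_genes(x, nm)
  td <- tidy(res)
  expect_named(td, c("gene", "dtw_dist", "dynamic"))
  g <- glance(res)
  expect_equal(g$n_genes, 2L)
  expect_equal(g$tau, nm$tau)
})
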