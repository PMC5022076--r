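test_that("signed adjacency follows the correlation formula", {
  up <- seq_len(8)
  m <- rbind(g1 = up, g2 = up * 2 + 1,        # cor +1
             g3 = -up,                        # cor -1 with g1
             g4 = c(2, 1, 4, 3, 6, 5, 8, 7))  # positive, imperfect
  a <- signed_adjacency(m, beta = 12)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0)
  expect_equal(diag(a), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(a >= 0 & a <= 1))
  # cor = 0 at beta = 12 gives 0.5^12
  cc <- (0.5 + 0.5 * cor(m["g1", ], m["g4", ]))^12
  expect_equal(a["g1", "g4"], cc)
  m_bad <- rbind(m, g5 = rep(3, 8))
  expect_error(signed_adjacency(m_bad, beta = 12), "g5")
})

test_that("TOM reproduces the hand-computed 3-gene example and its bounds", {
  a <- matrix(0.5, 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  diag(a) <- 1
  tom <- topological_overlap(a)
  # k_i = 1; TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  expect_equal(tom["g1", "g2"], 0.5)
  expect_equal(diag(tom), rep(1, 3), ignore_attr = TRUE)
  # identical unweighted neighborhoods with a_ij = 1 give maximal overlap
  b <- matrix(c(1, 1, 1, 0,
                1, 1, 1, 0,
                1, 1, 1, 0,
                0, 0, 0, 1), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  expect_equal(topological_overlap(b)[1, 2], 1)
  # bounds on random signed adjacencies
  set.seed(4)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 15), n, 15)
    adj <- signed_adjacency(x, beta = sample(c(2, 6, 12), 1))
    tm <- topological_overlap(adj)
    expect_true(all(tm >= -1e-12 & tm <= 1 + 1e-12))
    expect_equal(tm, t(tm))
  }
})

test_that("module detection recovers planted orthogonal modules", {
  set.seed(9)
  t7 <- seq_len(10)
  lat1 <- sin(t7); lat2 <- cos(2 * t7)      # near-orthogonal curves
  m <- rbind(t(sapply(1:20, function(i) runif(1, 0.5, 1.5) * lat1)),
             t(sapply(1:20, function(i) runif(1, 0.5, 1.5) * lat2)))
  rownames(m) <- sprintf("g%02d", 1:40)
  a <- signed_adjacency(m, beta = 12)
  tom <- topological_overlap(a)
  mods <- detect_modules(tom, min_size = 10, cut_height = 0.9)
  expect_equal(dplyr::n_distinct(mods$module), 2)
  expect_equal(adjusted_rand(mods$module, rep(1:2, each = 20)), 1)
  # labels follow the size-ordered color convention
  expect_setequal(unique(mods$module), c("turquoise", "blue"))
})

test_that("degenerate module structures behave as declared", {
  # all genes identical: a single all-encompassing module
  m <- matrix(rep(seq_len(8), each = 12), 12, 8) +
    matrix(rnorm(96, sd = 1e-4), 12, 8)
  rownames(m) <- sprintf("g%02d", 1:12)
  tom <- topological_overlap(signed_adjacency(m, beta = 6))
  mods <- detect_modules(tom, min_size = 5, cut_height = 0.99)
  expect_equal(unique(mods$module), "turquoise")
  # min_size above every branch: everything grey
  mods_grey <- detect_modules(tom, min_size = 50, cut_height = 0.99)
  expect_equal(unique(mods_grey$module), "grey")
})

test_that("module labels and connectivity are invariant to gene order", {
  set.seed(21)
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  a <- signed_adjacency(m, beta = 6)
  tom <- topological_overlap(a)
  perm <- sample(30)
  a_p <- signed_adjacency(m[perm, ], beta = 6)
  expect_equal(a_p, a[perm, perm])
  tom_p <- topological_overlap(a_p)
  expect_equal(tom_p, tom[perm, perm], tolerance = 1e-12)
  k <- rowSums(a) - 1
  expect_equal((rowSums(a_p) - 1)[rownames(m)], k)
})

test_that("eigengenes summarize modules and recover planted trajectories", {
  s <- simulate_timecourse(sim_config(n_genes = 500, n_modules = 2,
                                      module_size = 30, noise_sd = 0.05,
                                      seed = 31))
  x <- s$experiment
  x$signal <- log2(x$signal); x$log2 <- TRUE
  gx <- collapse_probes(x, s$truth$probe_map)
  modules <- dplyr::filter(s$truth$genes, module != "unassigned") %>%
    dplyr::transmute(gene, module)
  eg <- module_eigengene(gx, modules)
  expect_equal(colnames(eg$eigengenes), c("module_1", "module_2"))
  divs <- as.character(s$truth$divs)
  for (mod in colnames(eg$trajectories)) {
    planted <- s$truth$latent[divs, mod]
    expect_gte(abs(cor(eg$trajectories[, mod], planted)), 0.95)
  }
  # identical genes: eigengene equals the standardized shared profile
  prof <- sin(seq_len(21))
  m_id <- matrix(rep(prof, each = 10), 10, 21,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  x_id <- make_tc(m_id, divs = c(0, 1, 3, 5, 7, 9, 11), n_rep = 3)
  eg_id <- module_eigengene(x_id, tibble::tibble(
    gene = rownames(m_id), module = "m1"))
  expect_gt(cor(eg_id$eigengenes[, "m1"], prof), 0.999)
  expect_equal(eg_id$variance_explained[["m1"]], 1, tolerance = 1e-9)
})

test_that("eigengene maximizes explained variance among unit vectors", {
  set.seed(5)
  m <- matrix(rnorm(15 * 21), 15, 21,
              dimnames = list(sprintf("g%02d", 1:15), NULL))
  x <- make_tc(m, divs = c(0, 1, 3, 5, 7, 9, 11), n_rep = 3)
  eg <- module_eigengene(x, tibble::tibble(gene = rownames(m),
                                           module = "m1"))
  std <- t(scale(t(m)))
  var_e <- var(as.vector(std %*% eg$eigengenes[, 1]))
  for (i in 1:20) {
    v <- rnorm(21); v <- v / sqrt(sum(v^2))
    expect_lte(var(as.vector(std %*% v)), var_e + 1e-9)
  }
})

test_that("hub metrics reproduce path and star closed forms", {
  pg <- two_tier_graph_expression("path", seed = 2)
  expect_true(pg$separated)
  adj <- signed_adjacency(pg$m, beta = 2)
  hub <- hub_metrics(pg$m, adj, spearman_cut = pg$cut, hub_quantile = 1 / 3)
  expect_equal(hub$table$degree, c(1, 2, 1))
  expect_equal(hub$table$betweenness, c(0, 1, 0))
  expect_equal(hub$hubs$degree, "g2")

  st <- two_tier_graph_expression("star", n_leaves = 4, seed = 3)
  expect_true(st$separated)
  adj_s <- signed_adjacency(st$m, beta = 2)
  hub_s <- hub_metrics(st$m, adj_s, spearman_cut = st$cut,
                       hub_quantile = 0.2)
  expect_equal(hub_s$table$degree[1], 4)
  expect_equal(hub_s$table$betweenness[1], 6)  # all C(4,2) leaf pairs
  expect_equal(hub_s$table$betweenness[-1], rep(0, 4))
  expect_equal(hub_s$hubs$betweenness, "center")
})

test_that("betweenness and degree match brute-force enumeration", {
  set.seed(12)
  for (i in 1:20) {
    m <- matrix(rnorm(8 * 25), 8, 25,
                dimnames = list(paste0("g", 1:8), NULL))
    adj <- signed_adjacency(m, beta = 2)
    cut <- runif(1, 0.1, 0.5)
    hub <- hub_metrics(m, adj, spearman_cut = cut)
    edge <- cor(t(m), method = "spearman") > cut
    diag(edge) <- FALSE
    expect_equal(hub$table$degree, unname(rowSums(edge)))
    expect_equal(hub$table$betweenness, brute_betweenness(edge),
                 tolerance = 1e-10)
    # structural bounds
    n <- 8
    expect_true(all(hub$table$degree <= n - 1))
    expect_true(all(hub$table$connectivity <= n - 1 + 1e-12))
    expect_true(all(hub$table$betweenness <= (n - 1) * (n - 2) / 2))
  }
})

test_that("hub sets use the ceiling rule with gene-ID tie-breaks", {
  prof <- sin(seq_len(15))
  m <- matrix(rep(prof, each = 11), 11, 15,
              dimnames = list(sprintf("g%02d", 1:11), NULL))
  adj <- matrix(1, 11, 11, dimnames = list(rownames(m), rownames(m)))
  hub <- hub_metrics(m, adj, spearman_cut = 0.9, hub_quantile = 0.10)
  # all metrics tied: ceiling(0.1 * 11) = 2 smallest gene IDs
  expect_equal(hub$hubs$connectivity, c("g01", "g02"))
  expect_equal(hub$hubs$degree, c("g01", "g02"))
})

test_that("soft-threshold picking returns grid singletons and flags fallbacks", {
  set.seed(8)
  m <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  expect_warning(one <- pick_soft_threshold(m, grid = 6), "best-fitting")
  expect_equal(one$beta, 6)
  expect_named(one$fit_table, c("beta", "r_squared", "slope", "mean_k"))
})
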