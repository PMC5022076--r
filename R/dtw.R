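# Dynamic time warping against a noise-calibrated null, and k-means
# trajectory clustering with an automated elbow rule.

#' Dynamic time warping distance between two series
#'
#' Classic dynamic-programming DTW: local cost `|a_i - b_j|`, symmetric
#' step pattern (match / insert / delete, each step adding the local cost
#' once), both endpoints aligned. Returns the unnormalized accumulated cost
#' of the optimal warping path.
#'
#' @param a,b numeric series of length >= 2, no missing values.
#' @return Non-negative accumulated cost; 0 iff a perfectly aligned match
#'   exists (e.g. `a == b`).
#' @export
dtw_distance <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("series must have length >= 2")
  if (anyNA(a) || anyNA(b)) stop("series must not contain missing values")
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n, m)
  cost <- abs(outer(a, b, `-`))
  D[1, 1] <- cost[1, 1]
  for (i in 2:n) D[i, 1] <- D[i - 1, 1] + cost[i, 1]
  for (j in 2:m) D[1, j] <- D[1, j - 1] + cost[1, j]
  for (i in 2:n) {
    for (j in 2:m) {
      D[i, j] <- cost[i, j] + min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
    }
  }
  D[n, m]
}

# DTW of every row of `trajs` against a common reference, vectorized over
# rows (the DP table is evaluated cell-wise across all genes at once)
dtw_to_reference <- function(trajs, ref) {
  n <- ncol(trajs); m <- length(ref)
  ng <- nrow(trajs)
  cost <- lapply(seq_len(m), function(j) abs(trajs - ref[j]))  # per ref idx
  D <- vector("list", m)
  col1 <- matrix(0, ng, n)
  col1[, 1] <- cost[[1]][, 1]
  for (i in 2:n) col1[, i] <- col1[, i - 1] + cost[[1]][, i]
  D[[1]] <- col1
  for (j in 2:m) {
    Dj <- matrix(0, ng, n)
    Dj[, 1] <- D[[j - 1]][, 1] + cost[[j]][, 1]
    for (i in 2:n) {
      Dj[, i] <- cost[[j]][, i] +
        pmin(D[[j - 1]][, i], Dj[, i - 1], D[[j - 1]][, i - 1])
    }
    D[[j]] <- Dj
  }
  stats::setNames(D[[m]][, n], rownames(trajs))
}

#' Calibrate the DTW noise null
#'
#' Builds a noise matrix: for each noise SD, `n_noise` flat (all-zero)
#' log2-FC trajectories perturbed by Gaussian noise, each scored by its DTW
#' distance to the zero reference. An ordinary least squares fit of
#' distance on noise SD gives the noise model; the dynamic-gene threshold
#' is twice the upper 95% confidence boundary of the intercept,
#' `tau = 2 * (b0 + 1.96 * SE(b0))`.
#'
#' @param n_timepoints trajectory length (or a [timecourse()] from which it
#'   is taken).
#' @param n_noise trajectories per noise level.
#' @param noise_levels vector of >= 3 distinct non-negative noise SDs
#'   (log2 scale).
#' @param seed integer seed.
#' @return An object of class `dtw_noise_model`: list with `slope`,
#'   `intercept`, `u0`, `tau`, the fitted `lm` and the simulated `table`.
#' @export
calibrate_noise_null <- function(n_timepoints, n_noise = 200,
                                 noise_levels = seq(0.05, 0.3, by = 0.05),
                                 seed = 1L) {
  if (inherits(n_timepoints, "timecourse")) {
    n_timepoints <- dplyr::n_distinct(n_timepoints$samples$div)
  }
  if (any(noise_levels < 0)) stop("noise levels must be non-negative")
  if (length(unique(noise_levels[noise_levels > 0])) < 3) {
    stop("need at least 3 distinct positive noise levels")
  }
  local_seed(seed, {
    tab <- purrr::map_dfr(noise_levels, function(sd) {
      trajs <- matrix(stats::rnorm(n_noise * n_timepoints, 0, sd),
                      n_noise, n_timepoints)
      tibble::tibble(noise_sd = sd,
                     dtw_dist = dtw_to_reference(trajs,
                                                 rep(0, n_timepoints)))
    })
    fit <- stats::lm(dtw_dist ~ noise_sd, data = tab)
    b0 <- unname(stats::coef(fit)[1])
    se_b0 <- sqrt(stats::vcov(fit)[1, 1])
    u0 <- b0 + 1.96 * se_b0
    structure(
      list(slope = unname(stats::coef(fit)[2]), intercept = b0,
           se_intercept = se_b0, u0 = u0, tau = 2 * u0,
           fit = fit, table = tab),
      class = "dtw_noise_model"
    )
  })
}

#' @export
print.dtw_noise_model <- function(x, ...) {
  cat(sprintf(
    "<dtw_noise_model> distance = %.4g + %.4g * sd; u0 = %.4g; tau = %.4g\n",
    x$intercept, x$slope, x$u0, x$tau))
  invisible(x)
}

#' Flag dynamically regulated genes by DTW distance
#'
#' Each gene's trajectory is its replicate-mean log2 fold change versus the
#' baseline time point; its DTW distance to the flat zero trajectory is
#' compared against the calibrated threshold `tau`.
#'
#' @param x a log2-scale gene-level [timecourse()].
#' @param noise_model a [calibrate_noise_null()] fit.
#' @param genes optional restriction to the expressed universe.
#' @param baseline baseline time point.
#' @return An object of class `dtw_result`: list with `table` (tibble
#'   `gene`, `dtw_dist`, `dynamic`), `trajectories` (gene x time matrix of
#'   log2 FC), `noise_model`, and (after [cluster_trajectories()])
#'   clustering fields.
#' @export
select_dynamic_genes <- function(x, noise_model, genes = NULL,
                                 baseline = 0) {
  stopifnot(inherits(x, "timecourse"), inherits(noise_model,
                                                "dtw_noise_model"))
  trajs <- log2fc_trajectories(x, baseline = baseline)
  if (!is.null(genes)) trajs <- trajs[rownames(trajs) %in% genes, ,
                                      drop = FALSE]
  d <- dtw_to_reference(trajs, rep(0, ncol(trajs)))
  structure(
    list(table = tibble::tibble(gene = rownames(trajs), dtw_dist = unname(d),
                                dynamic = unname(d) > noise_model$tau),
         trajectories = trajs, noise_model = noise_model),
    class = "dtw_result"
  )
}

#' Cluster dynamic-gene trajectories by k-means with an elbow rule
#'
#' Runs k-means (Euclidean distance on the raw log2-FC trajectories, no
#' scaling) for `k = 1..k_max`, best of `n_init` random starts each, and
#' picks `k*` as the k maximizing the second difference of the scree
#' curve on the log scale (the point of strongest relative flattening).
#' Raw-scale curvature would always elect the first dominant split -
#' typically up- versus down-regulated - whenever cluster separation is
#' hierarchical; the log scale locates the elbow the visual criterion
#' identifies. Cluster labels are reordered by descending mean final
#' log2 FC (cluster 1 = strongest positive responder).
#'
#' @param x a `dtw_result` from [select_dynamic_genes()].
#' @param k_max maximum number of clusters tried.
#' @param n_init random starts per k.
#' @param seed integer seed.
#' @return `x` with added fields: `k`, `clusters` (tibble `gene`,
#'   `cluster`), `cluster_means` (k x time matrix), `wss` (scree curve).
#' @export
cluster_trajectories <- function(x, k_max = 12, n_init = 50, seed = 1L) {
  stopifnot(inherits(x, "dtw_result"))
  dyn <- x$table$gene[x$table$dynamic]
  if (length(dyn) < k_max + 1) {
    stop("need more than k_max (", k_max, ") dynamic genes, got ",
         length(dyn))
  }
  trajs <- x$trajectories[dyn, , drop = FALSE]
  n_unique <- nrow(unique(trajs))
  local_seed(seed, {
    wss <- vapply(seq_len(k_max), function(k) {
      if (k == 1) return(sum(scale(trajs, scale = FALSE)^2))
      if (k >= n_unique) return(0)
      stats::kmeans(trajs, centers = k, nstart = n_init,
                    iter.max = 50)$tot.withinss
    }, numeric(1))
    k_star <- if (wss[1] < 1e-12 || k_max < 3) 1L else {
      lw <- log(pmax(wss, wss[1] * 1e-12))
      d2 <- lw[1:(k_max - 2)] - 2 * lw[2:(k_max - 1)] + lw[3:k_max]
      which.max(d2) + 1L
    }
    fit <- if (k_star == 1) {
      list(cluster = rep(1L, nrow(trajs)),
           centers = matrix(colMeans(trajs), 1))
    } else {
      stats::kmeans(trajs, centers = k_star, nstart = n_init, iter.max = 50)
    }
    # order clusters by descending mean final log2 FC
    final_fc <- fit$centers[, ncol(trajs)]
    relabel <- match(fit$cluster, order(final_fc, decreasing = TRUE))
    x$k <- k_star
    x$clusters <- tibble::tibble(gene = rownames(trajs), cluster = relabel)
    centers <- fit$centers[order(final_fc, decreasing = TRUE), ,
                           drop = FALSE]
    rownames(centers) <- seq_len(nrow(centers))
    x$cluster_means <- centers
    x$wss <- wss
    x
  })
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> %d gene(s), %d dynamic (tau = %.4g)%s\n",
              nrow(x$table), sum(x$table$dynamic), x$noise_model$tau,
              if (is.null(x$k)) "" else paste0("; k* = ", x$k)))
  invisible(x)
}

#' @rdname select_dynamic_genes
#' @param ... unused.
#' @export
tidy.dtw_result <- function(x, ...) {
  out <- x$table
  if (!is.null(x$clusters)) {
    out <- dplyr::left_join(out, x$clusters, by = "gene")
  }
  out
}

#' @rdname select_dynamic_genes
#' @export
glance.dtw_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_dynamic = sum(x$table$dynamic),
    tau = x$noise_model$tau,
    noise_intercept = x$noise_model$intercept,
    noise_slope = x$noise_model$slope,
    k = if (is.null(x$k)) NA_integer_ else x$k
  )
}
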