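# Reproducibility-selected independent component analysis.
#
# FastICA (logcosh contrast, symmetric decorrelation) is run many times
# from random rotations; components are matched across runs by optimal
# assignment on absolute load correlations, a consensus load is taken as
# the first principal component of each aligned run-load stack, and only
# component counts whose consensus is near-perfectly reproduced across
# runs (mean load correlation above `r_cut`) are retained.

# one FastICA fit on pre-whitened data Z (n x k, unit covariance) with
# the logcosh contrast. "parallel" updates all components jointly with
# symmetric decorrelation; "deflation" extracts them one at a time with
# Gram-Schmidt against the components already found. Returns
# list(w = k x k unmixing matrix, rows = components, converged).
fastica_core <- function(Z, w_init, tol = 1e-4, max_iter = 200,
                         method = c("parallel", "deflation")) {
  method <- match.arg(method)
  k <- ncol(Z); n <- nrow(Z)
  if (method == "parallel") {
    orth <- function(W) {
      s <- svd(W)
      s$u %*% t(s$v)
    }
    W <- orth(w_init)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      S <- Z %*% t(W)
      G <- tanh(S)
      gp <- colMeans(1 - G^2)
      W_new <- orth(crossprod(G, Z) / n - diag(gp, k) %*% W)
      delta <- max(abs(1 - abs(diag(W_new %*% t(W)))))
      W <- W_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    return(list(w = W, converged = converged))
  }
  W <- matrix(0, k, k)
  ok <- TRUE
  for (ci in seq_len(k)) {
    w <- w_init[ci, ]
    if (ci > 1) {
      prev <- W[seq_len(ci - 1), , drop = FALSE]
      w <- w - drop(t(prev) %*% (prev %*% w))
    }
    w <- w / sqrt(sum(w^2))
    comp_ok <- FALSE
    for (it in seq_len(max_iter)) {
      s <- drop(Z %*% w)
      g <- tanh(s)
      w_new <- drop(crossprod(Z, g)) / n - mean(1 - g^2) * w
      if (ci > 1) {
        prev <- W[seq_len(ci - 1), , drop = FALSE]
        w_new <- w_new - drop(t(prev) %*% (prev %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) break
      w_new <- w_new / nrm
      done <- abs(1 - abs(sum(w_new * w))) < tol
      w <- w_new
      if (done) {
        comp_ok <- TRUE
        break
      }
    }
    W[ci, ] <- w
    ok <- ok && comp_ok
  }
  list(w = W, converged = ok)
}

# PCA whitening of a genes x samples matrix to k dimensions: returns the
# genes x k whitened scores (unit variance, orthogonal)
whiten_genes <- function(X, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  s <- svd(Xc, nu = k, nv = k)
  if (s$d[k] < 1e-12 * s$d[1]) {
    stop("matrix rank is below n_components = ", k)
  }
  sqrt(nrow(X) - 1) * s$u[, seq_len(k), drop = FALSE]
}

#' Run an ensemble of randomly initialized ICA fits
#'
#' The genes x samples matrix is column-centered and PCA-whitened to
#' `n_components` dimensions; FastICA is then run `n_iter` times from
#' independent random rotations (one deterministic stream derived from
#' `seed`). Non-converged runs are kept in the output but flagged, and
#' excluded from consensus building.
#'
#' @param X numeric matrix, genes x samples (log2 scale).
#' @param n_components number of components; must be below
#'   `min(dim(X))`.
#' @param n_iter ensemble size (the reference analysis uses 250).
#' @param seed integer seed.
#' @return An object of class `ica_ensemble`: list with `loads` (list of
#'   genes x k matrices), `converged` (logical), `n_components`.
#' @export
run_ica_ensemble <- function(X, n_components, n_iter = 250, seed = 1L,
                             method = "parallel") {
  X <- as.matrix(X)
  if (n_components >= min(dim(X)) || n_components < 2) {
    stop("n_components must be in [2, min(dim(X)) - 1]")
  }
  Z <- whiten_genes(X, n_components)
  local_seed(seed, {
    runs <- purrr::map(seq_len(n_iter), function(i) {
      w0 <- matrix(stats::rnorm(n_components^2), n_components)
      fit <- fastica_core(Z, w0, method = method)
      loads <- Z %*% t(fit$w)
      rownames(loads) <- rownames(X)
      list(loads = loads, converged = fit$converged)
    })
    structure(
      list(loads = purrr::map(runs, "loads"),
           converged = purrr::map_lgl(runs, "converged"),
           n_components = n_components),
      class = "ica_ensemble"
    )
  })
}

#' Align ensemble components and build consensus loads
#'
#' Components of every run are matched one-to-one to a reference run
#' (the first converged one) by maximizing total absolute load
#' correlation (optimal linear sum assignment), and sign-flipped to
#' correlate positively. The consensus load of a component is the first
#' principal component of its aligned run-load stack, rescaled to
#' z-scores; reproducibility `rbar` is the mean correlation of run loads
#' with the consensus, over every run of the ensemble. Runs that did not
#' converge within the iteration cap are flagged and counted but still
#' enter `rbar`: a component whose estimation stalls at scattered
#' positions is genuinely irreproducible, and that instability is the
#' signal the downstream count selection relies on.
#'
#' @param ensemble an `ica_ensemble`.
#' @return List with `consensus` (genes x k z-scored loads), `rbar`
#'   (per-component mean correlation), `n_runs_used`.
#' @export
align_components <- function(ensemble) {
  stopifnot(inherits(ensemble, "ica_ensemble"))
  loads <- ensemble$loads
  if (length(loads) < 2) stop("need at least 2 runs")
  k <- ensemble$n_components
  ref <- if (any(ensemble$converged)) {
    loads[[which(ensemble$converged)[1]]]
  } else {
    loads[[1]]
  }
  aligned <- purrr::map(loads, function(L) {
    cc <- suppressWarnings(stats::cor(ref, L))
    cc[!is.finite(cc)] <- 0
    perm <- as.integer(clue::solve_LSAP(abs(cc), maximum = TRUE))
    out <- L[, perm, drop = FALSE]
    signs <- sign(cc[cbind(seq_len(k), perm)])
    signs[signs == 0] <- 1
    sweep(out, 2, signs, `*`)
  })
  consensus <- matrix(0, nrow(ref), k, dimnames = list(rownames(ref), NULL))
  rbar <- numeric(k)
  for (c_i in seq_len(k)) {
    stack <- vapply(aligned, function(L) L[, c_i], numeric(nrow(ref)))
    if (all(apply(stack, 2, stats::sd) < 1e-300)) {
      rbar[c_i] <- 0
      next
    }
    pc1 <- svd(scale(stack, center = TRUE, scale = FALSE), nu = 1, nv = 1)$u[, 1]
    if (stats::cor(pc1, rowMeans(stack)) < 0) pc1 <- -pc1
    consensus[, c_i] <- (pc1 - mean(pc1)) / stats::sd(pc1)
    run_cor <- suppressWarnings(
      apply(stack, 2, stats::cor, y = consensus[, c_i]))
    run_cor[!is.finite(run_cor)] <- 0
    rbar[c_i] <- mean(run_cor)
  }
  colnames(consensus) <- paste0("C", seq_len(k))
  list(consensus = consensus, rbar = stats::setNames(rbar,
                                                     colnames(consensus)),
       n_runs_used = length(loads))
}

#' Select the component count by cross-run reproducibility
#'
#' For every candidate count an ICA ensemble is run and consensus
#' reproducibility computed; the selected count `n_star` is the largest
#' whose minimum per-component `rbar` exceeds `r_cut` (the reference
#' analysis requires r > 0.999). If no count passes, `n_star` is `NA` and
#' the full table is returned for inspection.
#'
#' @inheritParams run_ica_ensemble
#' @param counts candidate component counts (default 2:8).
#' @param r_cut reproducibility threshold.
#' @return An object of class `ica_result`: list with `n_star`, `rbar_table`
#'   (tibble `n_components`, `component`, `rbar`), `consensus` (the
#'   consensus loads of the selected count, or `NULL`), `activation`
#'   (selected-count component x sample activation matrix), `n_failed`
#'   (non-converged run count per candidate).
#' @export
select_component_count <- function(X, counts = 2:8, r_cut = 0.999,
                                   n_iter = 250, seed = 1L,
                                   method = "parallel") {
  X <- as.matrix(X)
  counts <- sort(counts)
  fits <- purrr::map(seq_along(counts), function(i) {
    tryCatch({
      ens <- run_ica_ensemble(X, counts[i], n_iter = n_iter,
                              seed = seed + i - 1L, method = method)
      cons <- align_components(ens)
      list(count = counts[i], cons = cons,
           n_failed = sum(!ens$converged))
    }, error = function(e) {
      # e.g. data rank below the candidate count: the count cannot pass
      list(count = counts[i],
           cons = list(consensus = NULL,
                       rbar = stats::setNames(rep(0, counts[i]),
                                              paste0("C",
                                                     seq_len(counts[i])))),
           n_failed = n_iter)
    })
  })
  rbar_table <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(n_components = f$count,
                   component = names(f$cons$rbar),
                   rbar = unname(f$cons$rbar))
  })
  min_rbar <- purrr::map_dbl(fits, ~ min(.x$cons$rbar))
  passing <- counts[min_rbar > r_cut]
  n_star <- if (length(passing)) max(passing) else NA_integer_
  consensus <- NULL
  activation <- NULL
  if (!is.na(n_star)) {
    consensus <- fits[[match(n_star, counts)]]$cons$consensus
    Xc <- scale(X, center = TRUE, scale = FALSE)
    activation <- solve(crossprod(consensus),
                        crossprod(consensus, Xc))
    colnames(activation) <- colnames(X)
  }
  structure(
    list(n_star = n_star, rbar_table = rbar_table, consensus = consensus,
         activation = activation,
         n_failed = stats::setNames(purrr::map_int(fits, "n_failed"),
                                    counts),
         r_cut = r_cut),
    class = "ica_result"
  )
}

#' Component membership by high consensus loads
#'
#' Genes whose absolute z-scored consensus load exceeds `z_cut` (default 3,
#' the conservative score cutoff) are called significant for a component,
#' with the load sign retained.
#'
#' @param consensus genes x components z-scored load matrix (or an
#'   `ica_result`).
#' @param z_cut absolute z threshold.
#' @return Tibble: `component`, `gene`, `load`, `direction`.
#' @export
significant_loads <- function(consensus, z_cut = 3) {
  if (inherits(consensus, "ica_result")) {
    if (is.null(consensus$consensus)) {
      stop("no component count passed the reproducibility cut")
    }
    consensus <- consensus$consensus
  }
  purrr::map_dfr(colnames(consensus), function(cc) {
    z <- consensus[, cc]
    hit <- abs(z) > z_cut
    tibble::tibble(component = cc, gene = rownames(consensus)[hit],
                   load = unname(z[hit]),
                   direction = ifelse(z[hit] > 0, "positive", "negative")) %>%
      dplyr::mutate(direction = as.character(.data$direction))
  })
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> n* = %s (r_cut = %g); candidates %s\n",
              ifelse(is.na(x$n_star), "none", x$n_star), x$r_cut,
              paste(sort(unique(x$rbar_table$n_components)),
                    collapse = ",")))
  invisible(x)
}

#' @rdname select_component_count
#' @param x an `ica_result`.
#' @param ... unused.
#' @export
tidy.ica_result <- function(x, ...) x$rbar_table

#' @rdname select_component_count
#' @export
glance.ica_result <- function(x, ...) {
  tibble::tibble(
    n_star = x$n_star,
    r_cut = x$r_cut,
    n_significant = if (is.null(x$consensus)) NA_integer_ else
      dplyr::n_distinct(significant_loads(x)$gene)
  )
}
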