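# Signed co-expression network: soft-thresholded signed adjacency,
# topological overlap, average-linkage module detection with a static tree
# cut, module eigengenes, and hub classification by connectivity, degree on
# a Spearman threshold graph, and betweenness centrality.

# WGCNA's conventional size-ordered module color sequence
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3"
)

as_expr_matrix <- function(x, genes = NULL) {
  m <- if (inherits(x, "timecourse")) x$signal else as.matrix(x)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  m
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation across
#' all samples; perfectly anti-correlated genes get adjacency 0, perfectly
#' correlated genes 1. The diagonal is set to 1.
#'
#' @param x gene-level [timecourse()] or genes x samples matrix.
#' @param beta soft-thresholding power (default 12, the customary signed
#'   default).
#' @param genes optional restriction (the expressed universe).
#' @return Symmetric genes x genes adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(x, beta = 12, genes = NULL) {
  if (beta < 1) stop("beta must be >= 1")
  m <- as_expr_matrix(x, genes)
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s), drop before building the network: ",
         paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", "),
         if (sum(sds == 0) > 5) " ..." else "")
  }
  a <- ((1 + stats::cor(t(m))) / 2)^beta
  diag(a) <- 1
  a
}

#' Pick the soft power by approximate scale-free fit
#'
#' For each candidate power, computes connectivity `k_i = sum_j a_ij` and
#' the R-squared of the linear fit of `log10 p(k)` on `log10 k` over 10
#' connectivity bins; picks the smallest power reaching `r2_cut` with a
#' negative slope, falling back (with a warning) to the power maximizing
#' the fit.
#'
#' @inheritParams signed_adjacency
#' @param grid candidate powers.
#' @param r2_cut scale-free fit threshold (default 0.8).
#' @return List: `beta` (chosen power) and `fit_table` (tibble `beta`,
#'   `r_squared`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(x, grid = c(2, 4, 6, 8, 10, 12, 14, 16),
                                r2_cut = 0.8, genes = NULL) {
  m <- as_expr_matrix(x, genes)
  scale_free_fit <- function(k) {
    bins <- cut(k, breaks = 10)
    dk <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    ok <- !is.na(dk) & dk > 0
    if (sum(ok) < 3) return(c(r2 = 0, slope = 0))
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
  }
  tab <- purrr::map_dfr(grid, function(b) {
    a <- signed_adjacency(m, beta = b)
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k)
    tibble::tibble(beta = b, r_squared = sf[["r2"]],
                   slope = sf[["slope"]], mean_k = mean(k))
  })
  pass <- tab$beta[tab$r_squared >= r2_cut & tab$slope < 0]
  beta <- if (length(pass)) min(pass) else {
    warning("no power reached scale-free fit R^2 >= ", r2_cut,
            "; using the best-fitting power")
    tab$beta[which.max(tab$r_squared)]
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu` and the sum over shared
#' neighbors `u != i, j`; `TOM_ii = 1`.
#'
#' @param adjacency a [signed_adjacency()] matrix.
#' @return Symmetric TOM in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- rowSums(a) - 1
  cross <- a %*% a - 2 * a          # removes u = i and u = j terms (a_ii = 1)
  num <- cross + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by static tree cut on the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of `1 - TOM`; the tree is cut at
#' `cut_height`, branches smaller than `min_size` are assigned to "grey"
#' (unassigned), and the remaining modules are named by the conventional
#' size-ordered color palette (largest module = "turquoise").
#'
#' @param tom a [topological_overlap()] matrix.
#' @param min_size minimum module size (default 30).
#' @param cut_height static cut height on `1 - TOM` (default 0.99).
#' @return Tibble: `gene`, `module`.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.99) {
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep("grey", length(raw))
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    palette <- c(module_colors,
                 paste0("module_", seq_len(max(0, length(ord) -
                                                 length(module_colors)))))
    for (i in seq_along(ord)) {
      module[raw == as.integer(ord[i])] <- palette[i]
    }
  }
  tibble::tibble(gene = rownames(tom), module = module)
}

#' Module eigengenes and their log2-FC trajectories
#'
#' The eigengene of a module is the first principal component of its
#' standardized genes x samples submatrix, sign-oriented to correlate
#' positively with the module's mean expression profile. The trajectory
#' version applies the same construction to replicate-mean log2 fold
#' changes versus the baseline.
#'
#' @param x a log2-scale gene-level [timecourse()].
#' @param modules tibble `gene`, `module` from [detect_modules()].
#' @param baseline baseline time point for the trajectory eigengene.
#' @return List: `eigengenes` (samples x modules matrix), `trajectories`
#'   (time points x modules matrix of log2-FC eigengenes),
#'   `variance_explained` (per module).
#' @export
module_eigengene <- function(x, modules, baseline = 0) {
  stopifnot(inherits(x, "timecourse"))
  mods <- sort(setdiff(unique(modules$module), "grey"))
  if (!length(mods)) stop("no non-grey modules")
  fc <- log2fc_trajectories(x, baseline = baseline)
  eigen_of <- function(m) {
    if (nrow(m) == 1) {
      v <- drop(scale(t(m)))
      return(list(e = v / max(stats::sd(v), 1e-12), ve = 1))
    }
    std <- t(scale(t(m)))
    s <- svd(std, nu = 0, nv = 1)
    e <- s$v[, 1]
    if (stats::cor(e, colMeans(m)) < 0) e <- -e
    list(e = e, ve = s$d[1]^2 / sum(s$d^2))
  }
  res <- purrr::map(mods, function(mod) {
    g <- modules$gene[modules$module == mod]
    full <- eigen_of(x$signal[g, , drop = FALSE])
    traj <- eigen_of(fc[g, , drop = FALSE])
    list(full = full, traj = traj)
  })
  eg <- vapply(res, function(r) r$full$e, numeric(ncol(x$signal)))
  tr <- vapply(res, function(r) r$traj$e, numeric(ncol(fc)))
  dimnames(eg) <- list(colnames(x$signal), mods)
  dimnames(tr) <- list(colnames(fc), mods)
  list(eigengenes = eg, trajectories = tr,
       variance_explained = stats::setNames(
         purrr::map_dbl(res, ~ .x$full$ve), mods))
}

#' Hub metrics and top-10% hub sets
#'
#' Three hub definitions: Connectivity (sum of signed adjacency to all
#' other genes), Degree (number of partners with Spearman correlation
#' strictly above `spearman_cut` in an unweighted graph) and Betweenness
#' (shortest-path betweenness on that graph, unnormalized, contributions
#' split across equal-length shortest paths). Each metric's hub set is the
#' top `ceiling(hub_quantile * n)` genes by descending value, ties broken
#' by gene ID.
#'
#' @param x gene-level [timecourse()] or genes x samples matrix.
#' @param adjacency matching [signed_adjacency()] matrix.
#' @param spearman_cut edge threshold (default 0.90, strict inequality).
#' @param hub_quantile hub fraction (default 0.10).
#' @param genes optional restriction.
#' @return An object of class `hub_result`: list with `table` (tibble
#'   `gene`, `connectivity`, `degree`, `betweenness`) and `hubs` (named
#'   list of top sets per metric).
#' @export
hub_metrics <- function(x, adjacency, spearman_cut = 0.90,
                        hub_quantile = 0.10, genes = NULL) {
  m <- as_expr_matrix(x, genes)
  stopifnot(nrow(m) >= 3, identical(rownames(m), rownames(adjacency)))
  connectivity <- rowSums(adjacency) - 1
  rho <- stats::cor(t(m), method = "spearman")
  edge <- rho > spearman_cut
  diag(edge) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(edge, mode = "undirected")
  degree <- igraph::degree(g)
  betweenness <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  tab <- tibble::tibble(gene = rownames(m),
                        connectivity = unname(connectivity),
                        degree = unname(degree),
                        betweenness = unname(betweenness))
  n_top <- ceiling(hub_quantile * nrow(tab))
  top_set <- function(value) {
    tab$gene[order(-value, tab$gene)][seq_len(n_top)]
  }
  structure(
    list(table = tab,
         hubs = list(connectivity = top_set(tab$connectivity),
                     degree = top_set(tab$degree),
                     betweenness = top_set(tab$betweenness)),
         spearman_cut = spearman_cut, hub_quantile = hub_quantile),
    class = "hub_result"
  )
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf(
    "<hub_result> %d gene(s); top %d hubs per metric (Spearman > %g graph)\n",
    nrow(x$table), length(x$hubs$connectivity), x$spearman_cut))
  invisible(x)
}

#' @rdname hub_metrics
#' @param ... unused.
#' @export
tidy.hub_result <- function(x, ...) x$table
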