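# Gene-set over-representation: Fisher exact tests on 2x2 tables with
# grid-wide BH control, rank-rank hypergeometric overlap maps, and
# DAG-aware enrichment with bottom-up elim decorrelation.

#' Fisher exact enrichment of a gene list in a cluster
#'
#' The 2x2 table is `a = |list & cluster|`, `b = |cluster \ list|`,
#' `c = |list \ cluster|`, `d` the remainder of the universe. The p-value
#' sums hypergeometric point masses (two-sided: all tables with point mass
#' at most the observed one; one-sided: the upper tail). The odds ratio is
#' the sample odds ratio `ad / bc`, with a Haldane 0.5 continuity
#' correction applied iff any cell is zero.
#'
#' @param list,cluster,universe character vectors of gene IDs; `list` and
#'   `cluster` must be subsets of `universe`.
#' @param alternative `"two.sided"` (default; the reference analysis also
#'   reports under-representation) or `"greater"`.
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `log_or`
#'   (natural log), `p`.
#' @export
fisher_enrichment <- function(list, cluster, universe,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(universe)) stop("universe must be non-empty")
  list <- intersect(unique(list), universe)
  cluster <- intersect(unique(cluster), universe)
  N <- length(unique(universe))
  a <- length(intersect(list, cluster))
  b <- length(cluster) - a
  cc <- length(list) - a
  d <- N - a - b - cc
  p <- hyper_table_p(a, b, cc, d, alternative)
  tab <- c(a = a, b = b, c = cc, d = d)
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[["a"]] * tab[["d"]]) / (tab[["b"]] * tab[["c"]])
  tibble::tibble(a = a, b = b, c = cc, d = d, odds_ratio = or,
                 log_or = log(or), p = p)
}

# hypergeometric summation p for the table [[a,b],[c,d]]; margins fixed
hyper_table_p <- function(a, b, cc, d, alternative) {
  m <- a + cc                       # list size (white balls)
  n <- b + d                        # non-list (black balls)
  k <- a + b                        # cluster size (drawn)
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- logp[a - lo + 1]
  if (alternative == "greater") {
    sum(exp(logp[support >= a]))
  } else {
    min(1, sum(exp(logp[logp <= obs + 1e-7])))
  }
}

#' All-pairs enrichment grid with BH control over the whole grid
#'
#' Tests every (gene list, cluster) pair with [fisher_enrichment()] and
#' adjusts p-values by Benjamini-Hochberg over exactly
#' `n_lists * n_clusters` tests. Reporting tiers follow the convention of
#' showing log odds ratios at FDR < `fdr_report` with significance marks
#' at FDR < 0.05 and FDR < 0.01.
#'
#' @param catalog named list of gene lists (e.g. from [read_gmt()]).
#' @param clusters named list of cluster gene sets.
#' @param universe platform gene universe.
#' @param fdr_report reporting threshold (default 0.1).
#' @inheritParams fisher_enrichment
#' @return An object of class `enrichment_grid`: tibble with `list`,
#'   `cluster`, the table cells, `odds_ratio`, `log_or`, `p`, `fdr`,
#'   `reported`, `tier`.
#' @export
enrichment_grid <- function(catalog, clusters, universe, fdr_report = 0.1,
                            alternative = "two.sided") {
  stopifnot(length(catalog) >= 1, length(clusters) >= 1)
  if (is.null(names(catalog)) || is.null(names(clusters))) {
    stop("catalog and clusters must be named")
  }
  grid <- tidyr::expand_grid(list = names(catalog),
                             cluster = names(clusters))
  res <- purrr::map2_dfr(grid$list, grid$cluster, function(l, cl) {
    fisher_enrichment(catalog[[l]], clusters[[cl]], universe,
                      alternative = alternative)
  })
  out <- dplyr::bind_cols(grid, res)
  out$fdr <- bh_fdr(out$p, m = nrow(out))
  out$reported <- out$fdr < fdr_report
  out$tier <- dplyr::case_when(
    out$fdr < 0.01 ~ "**",
    out$fdr < 0.05 ~ "*",
    out$fdr < fdr_report ~ ".",
    TRUE ~ ""
  )
  class(out) <- c("enrichment_grid", class(out))
  out
}

#' Rank-rank hypergeometric overlap map
#'
#' Both score vectors (signed per-gene scores over the same universe) are
#' ranked from most positive to most negative; for every pair of
#' threshold indices `(i * bin, j * bin)` the overlap of the two top sets
#' is tested with a one-sided hypergeometric test. The map of
#' `-log10(p)` values and its maximum (an overall agreement proxy) are
#' returned.
#'
#' @param scores_a,scores_b named numeric vectors over the same genes.
#' @param bin rank bin width (default 200).
#' @return An object of class `rrho_map`: list with `neglog10p` (matrix),
#'   `max_neglog10p`, `bin`.
#' @export
rrho_map <- function(scores_a, scores_b, bin = 200) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("score vectors must be named by gene")
  }
  if (!setequal(names(scores_a), names(scores_b))) {
    stop("the two score vectors must cover the same gene universe")
  }
  N <- length(scores_a)
  if (bin >= N) stop("bin must be smaller than the universe size")
  rank_a <- names(sort(scores_a, decreasing = TRUE))
  rank_b <- names(sort(scores_b, decreasing = TRUE))
  steps <- seq_len(N %/% bin) * bin
  in_top_b <- matrix(FALSE, N, length(steps))
  pos_in_b <- match(rank_a, rank_b)
  for (j in seq_along(steps)) in_top_b[, j] <- pos_in_b <= steps[j]
  cum_overlap <- apply(in_top_b, 2, cumsum)
  p <- matrix(NA_real_, length(steps), length(steps))
  for (i in seq_along(steps)) {
    k <- cum_overlap[steps[i], ]
    p[i, ] <- stats::phyper(k - 1, steps[i], N - steps[i], steps,
                            lower.tail = FALSE)
  }
  neglog <- -log10(pmax(p, .Machine$double.xmin))
  dimnames(neglog) <- list(steps, steps)
  structure(list(neglog10p = neglog,
                 max_neglog10p = max(neglog), bin = bin),
            class = "rrho_map")
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("<rrho_map> %dx%d bins of %d; max -log10(p) = %.3g\n",
              nrow(x$neglog10p), ncol(x$neglog10p), x$bin,
              x$max_neglog10p))
  invisible(x)
}

#' DAG-aware enrichment with bottom-up elim decorrelation
#'
#' Terms are processed leaves-first (reverse topological order). Each term
#' is Fisher-tested (one-sided enrichment) against the universe; when a
#' term is significant at `p_cut`, its annotated study genes are removed
#' from all of its ancestors before those are tested, decorrelating nested
#' terms. Annotations are expected to be pre-propagated to ancestors.
#'
#' @param annotations named list: term -> annotated genes.
#' @param dag data frame with columns `child`, `parent` (edges toward the
#'   root); must be acyclic.
#' @param study study gene set.
#' @param universe gene universe.
#' @param p_cut elimination threshold (default 0.01).
#' @return Tibble: `term`, `n_annotated`, `n_study`, `p`, ordered as
#'   processed.
#' @export
go_elim_enrichment <- function(annotations, dag, study, universe,
                               p_cut = 0.01) {
  terms <- names(annotations)
  dag <- tibble::as_tibble(dag)
  stopifnot(all(c("child", "parent") %in% names(dag)))
  if (!all(c(dag$child, dag$parent) %in% terms)) {
    stop("dag mentions terms without annotations")
  }
  # Kahn topological sort, leaves (no children) first
  children_of <- split(dag$child, dag$parent)
  parents_of <- split(dag$parent, dag$child)
  n_children <- vapply(terms, function(t)
    length(children_of[[t]]), integer(1))
  queue <- terms[n_children == 0]
  order_out <- character(0)
  remaining <- n_children
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, t)
    for (p in parents_of[[t]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order_out) < length(terms)) stop("cycle detected in dag")

  ancestors <- function(t) {
    seen <- character(0); frontier <- parents_of[[t]]
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- unique(unlist(parents_of[frontier]))
      frontier <- setdiff(frontier, seen)
    }
    seen
  }
  study <- intersect(study, universe)
  ann <- lapply(annotations, intersect, y = universe)
  res <- purrr::map_dfr(order_out, function(t) {
    genes_t <- ann[[t]]
    r <- fisher_enrichment(study, genes_t, universe,
                           alternative = "greater")
    if (r$p < p_cut) {
      drop <- intersect(genes_t, study)
      for (anc in ancestors(t)) {
        ann[[anc]] <<- setdiff(ann[[anc]], drop)
      }
    }
    tibble::tibble(term = t, n_annotated = length(genes_t),
                   n_study = r$a, p = r$p)
  })
  res
}
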