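# Per-time-point differential expression versus the baseline with a
# replicate random intercept, BH control over the expressed universe, and
# up/down/union call sets.
#
# With two dichotomized time points and a balanced replicate design the
# random-intercept model has a closed-form REML solution (the classical
# balanced-block ANOVA estimators), which is used here so the fit can be
# vectorized over all genes; on balanced data it coincides with lme4::lmer
# to numerical precision, which the test suite checks.

#' Fit one time-point-vs-baseline contrast for every gene
#'
#' Model per gene: `signal ~ intercept + I(div == t)` with a random
#' intercept per replicate; variance components by REML. Returns the
#' fixed-effect log2-scale difference, its standard error and a Wald-type
#' p-value. The reference distribution is the exact small-sample t: with a
#' positive replicate variance component the balanced design makes the
#' Wald statistic exactly t with `n_replicates - 1` degrees of freedom
#' (the paired-contrast result); when the replicate variance component is
#' estimated as zero the fit degenerates to ordinary least squares and the
#' t reference has `2 * n_replicates - 2` degrees of freedom. A normal
#' reference would be anti-conservative at n = 6 and would invalidate the
#' downstream FDR control.
#'
#' @param x a log2-scale gene-level [timecourse()].
#' @param t the time point contrasted against `baseline`.
#' @param baseline baseline time point (default 0).
#' @param genes optional gene IDs to restrict to (the expressed set).
#' @return Tibble: `gene`, `contrast`, `effect`, `se`, `p`, plus the method
#'   used (`"reml"` or `"ols"`).
#' @export
fit_contrast <- function(x, t, baseline = 0, genes = NULL) {
  stopifnot(inherits(x, "timecourse"))
  if (!x$log2) stop("signal must be log2 scale")
  sel0 <- x$samples$div == baseline
  sel1 <- x$samples$div == t
  if (sum(sel0) < 2 || sum(sel1) < 2) {
    stop("need >= 2 replicates at both time points")
  }
  sig <- x$signal
  if (!is.null(genes)) sig <- sig[rownames(sig) %in% genes, , drop = FALSE]
  # order both groups by replicate so columns pair up
  r0 <- order(x$samples$replicate[sel0])
  r1 <- order(x$samples$replicate[sel1])
  y0 <- sig[, which(sel0)[r0], drop = FALSE]
  y1 <- sig[, which(sel1)[r1], drop = FALSE]
  nr <- ncol(y0)
  if (ncol(y1) != nr) stop("unbalanced replicates between time points")

  m0 <- rowMeans(y0); m1 <- rowMeans(y1)
  effect <- m1 - m0
  grand <- (m0 + m1) / 2
  rep_mean <- (y0 + y1) / 2                       # gene x replicate means
  # two-way (time + replicate) ANOVA, no interaction
  fit0 <- matrix(m0, nrow(y0), nr) + (rep_mean - grand)
  fit1 <- matrix(m1, nrow(y1), nr) + (rep_mean - grand)
  sse <- rowSums((y0 - fit0)^2) + rowSums((y1 - fit1)^2)
  df_e <- nr - 1                                  # (2-1)*(nr-1)
  mse <- sse / df_e
  msb <- 2 * rowSums((rep_mean - grand)^2) / (nr - 1)
  sigma2_b <- pmax((msb - mse) / 2, 0)

  reml <- sigma2_b > 0
  se <- p <- numeric(length(effect))
  se[reml] <- sqrt(2 * mse[reml] / nr)
  p[reml] <- 2 * stats::pt(-abs(effect[reml] / se[reml]), df = nr - 1)
  if (any(!reml)) {
    s2 <- (rowSums((y0 - m0)^2) + rowSums((y1 - m1)^2)) / (2 * nr - 2)
    se[!reml] <- sqrt(2 * s2[!reml] / nr)
    tt <- effect[!reml] / se[!reml]
    p[!reml] <- 2 * stats::pt(-abs(tt), df = 2 * nr - 2)
  }
  # degenerate zero-residual-variance genes
  zero <- se == 0
  p[zero] <- ifelse(effect[zero] == 0, 1, 0)
  tibble::tibble(gene = rownames(y0), contrast = t,
                 effect = unname(effect), se = unname(se), p = unname(p),
                 method = ifelse(reml, "reml", "ols"))
}

#' Benjamini-Hochberg step-up adjustment with an explicit test count
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of tests the correction accounts for; must be at least
#'   `length(p)`. Using the full universe size keeps the control honest when
#'   some genes were skipped.
#' @return Adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (m < length(p)) stop("m must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Differential-expression calls across all contrasts
#'
#' Fits every non-baseline time point against the baseline, adjusts
#' p-values per contrast with [bh_fdr()] over `m` tests, and assembles the
#' up/down call sets and their unions. A gene may be up at one time point
#' and down at another, in which case it appears in both `up_any` and
#' `down_any` (and once in `dex_any`).
#'
#' @inheritParams fit_contrast
#' @param q_cut FDR threshold for a call (default 0.05).
#' @param m number of tests per contrast; defaults to `length(genes)` (the
#'   expressed universe) or the gene count of `x`.
#' @return An object of class `dex_result`: list with `table` (tibble of
#'   per-gene, per-contrast results with `q` and `call`), `sets` (named
#'   list `up_any`, `down_any`, `dex_any` and per-contrast calls),
#'   `nominal_only` (contrasts where no gene passed `q_cut`, with the count
#'   of nominally significant genes), `q_cut`, `m`.
#' @export
classify_dex <- function(x, baseline = 0, genes = NULL, q_cut = 0.05,
                         m = NULL) {
  stopifnot(inherits(x, "timecourse"))
  if (is.null(genes)) genes <- rownames(x$signal)
  if (is.null(m)) m <- length(genes)
  divs <- setdiff(sort(unique(x$samples$div)), baseline)
  tab <- purrr::map_dfr(divs, function(d) {
    res <- fit_contrast(x, d, baseline = baseline, genes = genes)
    res$q <- bh_fdr(res$p, m = m)
    res
  })
  tab$call <- dplyr::case_when(
    tab$q < q_cut & tab$effect > 0 ~ "up",
    tab$q < q_cut & tab$effect < 0 ~ "down",
    TRUE ~ "ns"
  )
  per_contrast <- split(tab, tab$contrast)
  sets <- list(
    up_any = unique(tab$gene[tab$call == "up"]),
    down_any = unique(tab$gene[tab$call == "down"])
  )
  sets$dex_any <- union(sets$up_any, sets$down_any)
  sets$per_contrast <- lapply(per_contrast, function(d) {
    list(up = d$gene[d$call == "up"], down = d$gene[d$call == "down"])
  })
  nominal <- purrr::map_int(per_contrast, ~ sum(.x$p < 0.05))
  called <- purrr::map_int(per_contrast, ~ sum(.x$call != "ns"))
  structure(
    list(table = tab, sets = sets,
         nominal_only = tibble::tibble(
           contrast = as.numeric(names(per_contrast)),
           n_called = called, n_nominal = nominal)[called == 0, ],
         q_cut = q_cut, m = m, baseline = baseline),
    class = "dex_result"
  )
}

#' @export
print.dex_result <- function(x, ...) {
  cat(sprintf(
    "<dex_result> %d contrasts vs DIV %s; FDR < %g over m = %d tests\n",
    dplyr::n_distinct(x$table$contrast), format(x$baseline), x$q_cut, x$m))
  cat(sprintf("  up_any %d | down_any %d | dex_any %d\n",
              length(x$sets$up_any), length(x$sets$down_any),
              length(x$sets$dex_any)))
  invisible(x)
}

#' @rdname classify_dex
#' @param x a `dex_result`.
#' @param ... unused.
#' @export
tidy.dex_result <- function(x, ...) x$table

#' @rdname classify_dex
#' @export
glance.dex_result <- function(x, ...) {
  both <- intersect(x$sets$up_any, x$sets$down_any)
  tibble::tibble(
    n_up = length(x$sets$up_any),
    n_down = length(x$sets$down_any),
    n_both = length(both),
    n_dex = length(x$sets$dex_any),
    q_cut = x$q_cut,
    m = x$m
  )
}
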