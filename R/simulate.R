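# Synthetic probe-level time courses with planted ground truth.
#
# The generator emulates the design of a 7-point (DIV 0,1,3,5,7,9,11)
# neuronal differentiation course measured in triplicate on an Illumina-style
# BeadChip: raw linear-scale summary intensities plus detection p-values,
# multi-probe genes, a background (non-expressed) fraction, planted
# monotone/transient log2-FC trajectories, latent co-expression modules and
# risk-gene lists with a requested enrichment odds ratio.

#' Configuration for the synthetic time-course generator
#'
#' @param n_genes number of genes.
#' @param frac_multi_probe fraction of genes carrying a second probe.
#' @param n_timepoints number of time points; 7 reproduces the DIV grid
#'   0,1,3,5,7,9,11, other values use an evenly spaced grid.
#' @param n_replicates biological replicates per time point.
#' @param class_fractions named fractions over the gene classes
#'   `flat_expressed`, `not_expressed`, `monotone_up`, `monotone_down`,
#'   `transient`; must sum to 1.
#' @param effect_size log2-fold-change amplitude reached by the dynamic
#'   classes (at the final time point for monotone classes, at the peak for
#'   the transient bump).
#' @param noise_sd residual Gaussian SD on the log2 scale. The default
#'   (0.002) represents near-noise-free summary data: replicate-averaged
#'   trajectory noise then sits far below the DTW noise-calibration grid,
#'   the only regime in which the noise-floor threshold behaves as a null
#'   filter; see the methods vignette for the analysis behind this choice.
#' @param replicate_sd SD of the per-gene, per-replicate random offset
#'   (constant across time; this is the variance component the mixed model
#'   estimates).
#' @param n_modules number of latent co-expression factors planted among
#'   flat expressed genes. Requires `n_modules + 2 <= n_timepoints` so the
#'   latent curves can be built orthogonal to the monotone and transient
#'   archetypes.
#' @param module_size genes per module.
#' @param seed integer seed; the whole generation is deterministic given it.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       frac_multi_probe = 0.2,
                       n_timepoints = 7,
                       n_replicates = 3,
                       class_fractions = c(flat_expressed = 0.45,
                                           not_expressed = 0.25,
                                           monotone_up = 0.12,
                                           monotone_down = 0.12,
                                           transient = 0.06),
                       effect_size = 2,
                       noise_sd = 0.002,
                       replicate_sd = 0.1,
                       n_modules = 3,
                       module_size = 40,
                       seed = 1L) {
  classes <- c("flat_expressed", "not_expressed", "monotone_up",
               "monotone_down", "transient")
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named exactly: ",
         paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  }
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (n_genes < 1 || n_timepoints < 3 || n_replicates < 2) {
    stop("need n_genes >= 1, n_timepoints >= 3, n_replicates >= 2")
  }
  if (frac_multi_probe < 0 || frac_multi_probe > 1) {
    stop("frac_multi_probe must be in [0,1]")
  }
  if (noise_sd < 0 || replicate_sd < 0) {
    stop("noise_sd and replicate_sd must be >= 0")
  }
  if (n_modules > 0 && n_modules + 2 > n_timepoints) {
    stop("n_modules + 2 must not exceed n_timepoints")
  }
  structure(
    list(n_genes = as.integer(n_genes), frac_multi_probe = frac_multi_probe,
         n_timepoints = as.integer(n_timepoints),
         n_replicates = as.integer(n_replicates),
         class_fractions = class_fractions, effect_size = effect_size,
         noise_sd = noise_sd, replicate_sd = replicate_sd,
         n_modules = as.integer(n_modules),
         module_size = as.integer(module_size), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run code under a seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# deterministic apportionment of n into counts proportional to fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# class archetype trajectories on the div grid, 0 at baseline, max |.| = 1
class_archetypes <- function(divs) {
  s <- (divs - divs[1]) / (divs[length(divs)] - divs[1])
  bump <- exp(-(s - 0.5)^2 / (2 * 0.18^2))
  bump <- bump - bump[1]
  bump <- bump / max(bump)
  cbind(monotone_up = s, monotone_down = -s, transient = bump)
}

# latent module curves orthogonal (after centering) to the archetypes
latent_trajectories <- function(divs, n_modules) {
  if (n_modules == 0) return(NULL)
  arch <- class_archetypes(divs)
  base <- cbind(arch[, "monotone_up"], arch[, "transient"],
                matrix(stats::rnorm(length(divs) * n_modules),
                       nrow = length(divs)))
  q <- qr.Q(qr(scale(base, center = TRUE, scale = FALSE)))
  lat <- q[, 2 + seq_len(n_modules), drop = FALSE]
  lat <- sweep(lat, 2, apply(abs(lat), 2, max), `/`)
  colnames(lat) <- paste0("module_", seq_len(n_modules))
  rownames(lat) <- as.character(divs)
  lat
}

#' Generate a synthetic probe-level time course with known truth
#'
#' Signal model, on the log2 scale, for gene g, probe p, time t, replicate r:
#' `baseline_g + atten_p * (class_g(t) * effect + load_g * latent_m(t)) +
#' offset_{g,r} + noise`. The written/returned signal is `2^log2signal`
#' (linear scale, as exported from array scanner software), so downstream
#' preprocessing genuinely exercises the log2 step. Secondary probes of
#' multi-probe genes are attenuated (factor 0.6) so the primary probe always
#' carries the larger variance. Expressed genes draw detection p-values from
#' Uniform(0, 0.04); non-expressed genes from Uniform(0.05, 1), so the
#' detection-p filter recovers the expressed classes exactly.
#'
#' @param config a [sim_config()].
#' @return A list with `experiment` (probe-level linear-scale
#'   [timecourse()]) and `truth`, itself a list: `genes` (tibble of gene,
#'   class, module), `probe_map` (tibble probe, gene), `archetypes`,
#'   `latent` (time x module matrix), `divs`, and an empty `risk_lists`
#'   list.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    n <- config$n_genes
    divs <- if (config$n_timepoints == 7) c(0, 1, 3, 5, 7, 9, 11) else
      seq(0, 11, length.out = config$n_timepoints)
    nt <- length(divs)
    nr <- config$n_replicates

    counts <- apportion(n, config$class_fractions)
    class <- rep(names(config$class_fractions), counts)
    gene <- sprintf("g%05d", seq_len(n))

    # module membership among flat expressed genes only, so dynamic-class
    # trajectories stay exact archetypes
    module <- rep("unassigned", n)
    lat <- latent_trajectories(divs, config$n_modules)
    if (config$n_modules > 0) {
      flat <- which(class == "flat_expressed")
      need <- config$n_modules * config$module_size
      if (need > length(flat)) {
        stop("not enough flat_expressed genes (", length(flat),
             ") for ", config$n_modules, " modules of size ",
             config$module_size)
      }
      picked <- sample(flat, need)
      module[picked] <- rep(colnames(lat), each = config$module_size)
    }
    load <- ifelse(module == "unassigned", 0, stats::runif(n, 0.5, 1.5))

    arch <- class_archetypes(divs)
    dynamic <- matrix(0, n, nt)                      # gene x time log2 FC
    for (cl in colnames(arch)) {
      idx <- class == cl
      if (any(idx)) {
        dynamic[idx, ] <- matrix(arch[, cl] * config$effect_size,
                                 sum(idx), nt, byrow = TRUE)
      }
    }
    if (!is.null(lat)) {
      for (m in colnames(lat)) {
        idx <- module == m
        dynamic[idx, ] <- dynamic[idx, ] +
          config$effect_size * outer(load[idx], lat[, m])
      }
    }

    baseline <- ifelse(class == "not_expressed",
                       stats::rnorm(n, 5, 0.5), stats::rnorm(n, 8, 1))
    offsets <- matrix(stats::rnorm(n * nr, 0, config$replicate_sd), n, nr)

    n_multi <- round(config$frac_multi_probe * n)
    multi <- if (n_multi > 0) sort(sample.int(n, n_multi)) else integer(0)
    probe_gene <- c(seq_len(n), multi)
    atten <- c(rep(1, n), rep(0.6, length(multi)))
    probe_id <- c(sprintf("p%05d_1", seq_len(n)),
                  sprintf("p%05d_2", multi))
    ord <- order(probe_id)
    probe_gene <- probe_gene[ord]; atten <- atten[ord]
    probe_id <- probe_id[ord]
    np <- length(probe_id)

    sample_tbl <- tibble::tibble(
      sample = sprintf("DIV%02d_r%d", rep(divs, each = nr),
                       rep(seq_len(nr), nt)),
      div = rep(divs, each = nr),
      replicate = rep(seq_len(nr), nt)
    )
    ns <- nrow(sample_tbl)

    t_idx <- match(sample_tbl$div, divs)
    log2sig <- baseline[probe_gene] +
      atten * dynamic[probe_gene, t_idx, drop = FALSE] +
      offsets[cbind(rep(probe_gene, ns),
                    rep(sample_tbl$replicate, each = np))] +
      matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
    rownames(log2sig) <- probe_id
    colnames(log2sig) <- sample_tbl$sample

    expressed <- class[probe_gene] != "not_expressed"
    detection <- matrix(0, np, ns, dimnames = dimnames(log2sig))
    detection[expressed, ] <- stats::runif(sum(expressed) * ns, 0, 0.04)
    detection[!expressed, ] <- stats::runif(sum(!expressed) * ns, 0.05, 1)

    truth <- list(
      genes = tibble::tibble(gene = gene, class = class, module = module,
                             module_loading = load),
      probe_map = tibble::tibble(probe = probe_id, gene = gene[probe_gene]),
      archetypes = arch, latent = lat, divs = divs,
      risk_lists = list()
    )
    list(
      experiment = timecourse(2^log2sig, sample_tbl, detection,
                              level = "probe", log2 = FALSE),
      truth = truth
    )
  })
}

#' Genes with a planted non-flat trajectory
#'
#' The union of the dynamic truth classes (monotone up/down, transient) and
#' the module members, whose latent factor trajectories are non-flat by
#' construction. This is the positive set for sensitivity/specificity of
#' the dynamic-gene and differential-expression stages.
#'
#' @param truth the `truth` component of [simulate_timecourse()].
#' @return Character vector of gene IDs.
#' @export
truth_dynamic_genes <- function(truth) {
  g <- truth$genes
  g$gene[g$class %in% c("monotone_up", "monotone_down", "transient") |
           g$module != "unassigned"]
}

#' Sensitivity and specificity of a called gene set against truth
#'
#' @param called character vector of called genes.
#' @param positive character vector of true positives.
#' @param universe evaluation universe.
#' @return One-row tibble: `sensitivity`, `specificity`, `n_called`,
#'   `n_positive`.
#' @export
recovery_stats <- function(called, positive, universe) {
  called <- intersect(called, universe)
  positive <- intersect(positive, universe)
  negative <- setdiff(universe, positive)
  tibble::tibble(
    sensitivity = length(intersect(called, positive)) /
      max(1L, length(positive)),
    specificity = length(setdiff(negative, called)) /
      max(1L, length(negative)),
    n_called = length(called),
    n_positive = length(positive)
  )
}

#' Sample a risk-gene list with a requested enrichment odds ratio
#'
#' Draws a gene list whose 2x2 contingency table against a target truth
#' class (list membership x class membership, over the whole simulated gene
#' universe) has expected sample odds ratio equal to `odds_ratio`. The
#' expected in-class overlap solves the quadratic implied by
#' `OR = ad/(bc)` and is rounded to the nearest achievable integer, so the
#' realized table reproduces the request up to integer rounding.
#'
#' @param truth the `truth` component of [simulate_timecourse()].
#' @param target_class one of the generator's class labels, or a module
#'   label, defining the "signal" gene set.
#' @param odds_ratio requested odds ratio (> 0).
#' @param list_size number of genes in the list.
#' @param seed integer seed.
#' @return A list: `genes` (character vector), `table` (2x2 realized
#'   contingency matrix), `odds_ratio_realized`, `odds_ratio_requested`.
#' @export
simulate_risk_list <- function(truth, target_class, odds_ratio, list_size,
                               seed = 1L) {
  genes <- truth$genes
  in_class <- if (target_class %in% genes$class) {
    genes$class == target_class
  } else {
    genes$module == target_class
  }
  if (!any(in_class)) stop("target class '", target_class, "' is empty")
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  N <- nrow(genes); K <- sum(in_class); n <- as.integer(list_size)
  if (n > N) stop("list_size (", n, ") exceeds universe size (", N, ")")

  # expected overlap a: (1-w) a^2 + (N-K-n + w(n+K)) a - w n K = 0
  w <- odds_ratio
  a <- if (abs(w - 1) < 1e-12) n * K / N else {
    A <- 1 - w; B <- (N - K - n) + w * (n + K); C <- -w * n * K
    (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  }
  a_int <- round(a)
  lo <- max(0L, n + K - N); hi <- min(n, K)
  or_at <- function(a) {
    (a * (N - K - n + a)) / ((n - a) * (K - a))
  }
  if (a_int >= hi || a_int < lo) {
    # the rounded overlap would empty a table cell (infinite sample OR)
    stop("odds_ratio ", odds_ratio, " not achievable for this class/list ",
         "size; maximum achievable is about ", signif(or_at(hi - 1), 3))
  }
  local_seed(seed, {
    inside <- sample(genes$gene[in_class], a_int)
    outside <- sample(genes$gene[!in_class], n - a_int)
    listed <- sort(c(inside, outside))
    # rows = list in/out, cols = class in/out
    tab <- matrix(c(a_int, n - a_int, K - a_int, N - K - n + a_int),
                  2, 2, byrow = TRUE,
                  dimnames = list(list = c("in", "out"),
                                  class = c("in", "out")))
    or_real <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    list(genes = listed, table = tab, odds_ratio_realized = or_real,
         odds_ratio_requested = odds_ratio)
  })
}
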