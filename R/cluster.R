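# Cluster-based Monte Carlo permutation statistics over sensors or grid
# sources, nonparametric ROI tests with Bonferroni correction, and the
# mixed ANOVA used for cerebro-acoustic coherence.

#' Build an adjacency graph from node positions
#'
#' Nodes within `max_dist` of each other (exclusive of self) are
#' neighbours; with a regular grid and `max_dist` slightly above the grid
#' spacing this yields face (6-)connectivity.
#'
#' @param positions Nodes x k coordinate matrix.
#' @param max_dist Neighbour distance threshold.
#' @return An `ft_adjacency`: `neighbors` (list of integer vectors),
#'   `positions`, `max_dist`.
#' @export
build_adjacency <- function(positions, max_dist) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  nb <- lapply(seq_len(n), function(i) {
    which(d[i, ] <= max_dist + 1e-12 & seq_len(n) != i)
  })
  structure(list(neighbors = nb, positions = positions, max_dist = max_dist),
            class = "ft_adjacency")
}

# node-level t statistics; paired: x = subject x node difference matrix
.ft_t_paired <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
  list(t = m / (s / sqrt(n)), df = n - 1)
}

.ft_t_unpaired <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  list(t = (ma - mb) / (sp * sqrt(1 / na + 1 / nb)), df = na + nb - 2)
}

# suprathreshold clustering with the minimum-neighbour rule: a node is kept
# only if at least min_neighbors of its graph neighbours are also
# suprathreshold with the same sign (single pruning pass); clusters are the
# connected components of the kept set
.ft_clusters <- function(tvals, tcrit, graph, min_neighbors) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvals > tcrit)
    if (length(supra) == 0) next
    in_supra <- logical(length(tvals)); in_supra[supra] <- TRUE
    if (min_neighbors > 0) {
      keep <- supra[vapply(supra, function(i)
        sum(in_supra[graph$neighbors[[i]]]) >= min_neighbors, logical(1))]
    } else keep <- supra
    if (length(keep) == 0) next
    in_keep <- logical(length(tvals)); in_keep[keep] <- TRUE
    seen <- logical(length(tvals))
    for (start in keep) {
      if (seen[start]) next
      comp <- integer(0); queue <- start; seen[start] <- TRUE
      while (length(queue) > 0) {
        i <- queue[[1]]; queue <- queue[-1]
        comp <- c(comp, i)
        nbs <- graph$neighbors[[i]]
        new <- nbs[in_keep[nbs] & !seen[nbs]]
        seen[new] <- TRUE
        queue <- c(queue, new)
      }
      out[[length(out) + 1]] <- list(nodes = sort(comp),
                                     stat = sum(tvals[comp]), sign = sgn)
    }
  }
  out
}

.ft_max_cluster_stats <- function(tvals, tcrit, graph, min_neighbors) {
  cl <- .ft_clusters(tvals, tcrit, graph, min_neighbors)
  stats_ <- vapply(cl, function(c) c$stat, numeric(1))
  c(max = if (any(stats_ > 0)) max(stats_) else 0,
    min = if (any(stats_ < 0)) min(stats_) else 0)
}

#' Cluster-based Monte Carlo permutation test
#'
#' Computes per-node t statistics (paired or independent two-sample),
#' clusters suprathreshold nodes (node-level alpha `cluster_alpha`,
#' two-sided) by graph adjacency subject to the minimum-neighbour rule, and
#' compares each observed cluster's summed t against the Monte Carlo
#' distribution of the maximum (most positive / most negative) cluster
#' statistic under random relabelling: sign flips within subject for the
#' paired design, group-label shuffles for the unpaired design. Clusters
#' are flagged significant when their summed t exceeds the 97.5th (positive)
#' or falls below the 2.5th (negative) percentile of that distribution,
#' i.e. a two-sided test at 5%.
#'
#' @param values_a,values_b Subjects x nodes matrices (paired: same subject
#'   order and count).
#' @param graph An [build_adjacency()] graph over the nodes.
#' @param design `"paired"` or `"unpaired"`.
#' @param n_perm Number of random permutations (default 1000; a warning is
#'   issued below 100).
#' @param cluster_alpha Node-level threshold (default 0.05, two-sided).
#' @param min_neighbors Minimum suprathreshold neighbours per cluster node
#'   (default 2).
#' @param seed RNG seed.
#' @return An `ft_cluster_result`: `clusters` (tibble: `cluster`, `sign`,
#'   `n_nodes`, `sum_t`, `p_value`, `significant`, `nodes` list column),
#'   `t` (per-node t), `df`, `tcrit`, `perm_max`, `perm_min`, `n_perm`,
#'   `cluster_alpha`.
#' @export
cluster_permutation <- function(values_a, values_b, graph,
                                design = c("paired", "unpaired"),
                                n_perm = 1000, cluster_alpha = 0.05,
                                min_neighbors = 2, seed = 1) {
  design <- match.arg(design)
  values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
  stopifnot(ncol(values_a) == ncol(values_b),
            ncol(values_a) == length(graph$neighbors))
  if (n_perm < 100) warn("n_perm < 100 gives a coarse Monte Carlo p value")
  set.seed(seed)

  if (design == "paired") {
    if (nrow(values_a) != nrow(values_b)) {
      abort("paired design needs matched subject counts")
    }
    d <- values_a - values_b
    n <- nrow(d)
    obs <- .ft_t_paired(d)
    tcrit <- stats::qt(1 - cluster_alpha / 2, obs$df)
    ss <- colSums(d^2)
    if (2^n <= n_perm) {
      # complete enumeration of sign flips: an exact test, invariant to
      # subject order
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      n_perm <- nrow(signs)
    } else {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    }
    ms <- (signs %*% d) / n
    vs <- sweep(-n * ms^2, 2, ss, "+") / (n - 1)
    ts <- ms / sqrt(vs / n)
    perm <- t(vapply(seq_len(n_perm), function(p)
      .ft_max_cluster_stats(ts[p, ], tcrit, graph, min_neighbors), numeric(2)))
  } else {
    na <- nrow(values_a)
    xall <- rbind(values_a, values_b)
    ntot <- nrow(xall)
    obs <- .ft_t_unpaired(values_a, values_b)
    tcrit <- stats::qt(1 - cluster_alpha / 2, obs$df)
    perm <- matrix(0, n_perm, 2)
    for (p in seq_len(n_perm)) {
      idx <- sample(ntot, na)
      tp <- .ft_t_unpaired(xall[idx, , drop = FALSE],
                           xall[-idx, , drop = FALSE])$t
      perm[p, ] <- .ft_max_cluster_stats(tp, tcrit, graph, min_neighbors)
    }
  }

  clusters <- .ft_clusters(obs$t, tcrit, graph, min_neighbors)
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    tol <- 1e-9 * (abs(cl$stat) + 1)       # tie tolerance: the identity
    p_val <- if (cl$sign > 0) {             # relabelling reproduces the stat
      (sum(perm[, 1] >= cl$stat - tol) + 1) / (n_perm + 1)
    } else {
      (sum(perm[, 2] <= cl$stat + tol) + 1) / (n_perm + 1)
    }
    tibble(cluster = i, sign = cl$sign, n_nodes = length(cl$nodes),
           sum_t = cl$stat, p_value = p_val,
           significant = p_val < cluster_alpha / 2,
           nodes = list(cl$nodes))
  })
  structure(
    list(clusters = if (length(rows) > 0) dplyr::bind_rows(rows) else
           tibble(cluster = integer(), sign = numeric(), n_nodes = integer(),
                  sum_t = numeric(), p_value = numeric(),
                  significant = logical(), nodes = list()),
         t = obs$t, df = obs$df, tcrit = tcrit,
         perm_max = perm[, 1], perm_min = perm[, 2],
         n_perm = n_perm, cluster_alpha = cluster_alpha,
         design = design),
    class = "ft_cluster_result")
}

#' @export
print.ft_cluster_result <- function(x, ...) {
  cat(sprintf("<ft_cluster_result> %s design, %d permutations, %d cluster(s), %d significant\n",
              x$design, x$n_perm, nrow(x$clusters), sum(x$clusters$significant)))
  if (nrow(x$clusters) > 0) print(dplyr::select(x$clusters, -"nodes"))
  invisible(x)
}

#' Nonparametric ROI tests with Bonferroni correction
#'
#' Wilcoxon signed-rank (paired) or Mann-Whitney-Wilcoxon (unpaired) test
#' per ROI, two-sided; exact p for small tie-free samples, normal
#' approximation with tie correction otherwise. The corrected alpha is
#' `alpha / n_tests` (defaulting to the number of ROIs here).
#'
#' @param values_a,values_b Subjects x ROIs matrices (columns named by ROI
#'   if available).
#' @param design `"paired"` or `"unpaired"`.
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_tests Bonferroni family size (default `ncol(values_a)`).
#' @return Tibble: `roi`, `p_value`, `p_corrected`, `alpha_corrected`,
#'   `significant`.
#' @export
roi_tests <- function(values_a, values_b, design = c("paired", "unpaired"),
                      alpha = 0.05, n_tests = NULL) {
  design <- match.arg(design)
  values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
  stopifnot(ncol(values_a) == ncol(values_b))
  if (is.null(n_tests)) n_tests <- ncol(values_a)
  rois <- colnames(values_a) %||% paste0("roi", seq_len(ncol(values_a)))
  p <- vapply(seq_len(ncol(values_a)), function(j) {
    if (design == "paired" && all(values_a[, j] == values_b[, j])) return(1)
    suppressWarnings(stats::wilcox.test(
      values_a[, j], values_b[, j], paired = design == "paired",
      alternative = "two.sided")$p.value)
  }, numeric(1))
  tibble(roi = rois, p_value = p, p_corrected = pmin(1, p * n_tests),
         alpha_corrected = alpha / n_tests, significant = p < alpha / n_tests)
}

#' Mixed ANOVA: within-subject condition and hemisphere, between-subject
#' experiment
#'
#' Classical sums-of-squares decomposition for a balanced
#' 2 (condition, within) x 2 (hemisphere, within) x 2 (experiment, between)
#' design via `aov()` with an `Error(subject/(condition*hemisphere))`
#' stratum, returning F, degrees of freedom, p, and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)` within each effect's stratum).
#'
#' @param data Data frame with columns `subject`, `value`, and the factors
#'   named by `within` and `between`.
#' @param within Names of the within-subject factors (default
#'   `c("condition", "hemisphere")`).
#' @param between Name of the between-subject factor (default
#'   `"experiment"`).
#' @return An `ft_anova`: `table` (tibble: `effect`, `df1`, `df2`, `F`,
#'   `p_value`, `pes`), `fit` (the `aov` object).
#' @export
mixed_anova <- function(data, within = c("condition", "hemisphere"),
                        between = "experiment") {
  stopifnot(is.data.frame(data),
            all(c("subject", "value", within, between) %in% names(data)))
  data <- as.data.frame(data)
  for (v in c("subject", within, between)) data[[v]] <- factor(data[[v]])
  cells <- table(data[c(within, between)])
  if (any(cells == 0)) abort("missing cells in the design")
  if (length(unique(cells)) != 1) abort("design is unbalanced")

  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(subject/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste("value ~", rhs, "+", err))
  fit <- stats::aov(form, data = data)

  rows <- list()
  for (stratum in names(summary(fit))) {
    sm <- summary(fit)[[stratum]][[1]]
    terms_ <- trimws(rownames(sm))
    resid_row <- which(terms_ == "Residuals")
    if (length(resid_row) == 0) next
    ss_err <- sm[resid_row, "Sum Sq"]
    df_err <- sm[resid_row, "Df"]
    for (i in seq_len(nrow(sm))) {
      if (i == resid_row) next
      rows[[length(rows) + 1]] <- tibble(
        effect = terms_[i], df1 = sm[i, "Df"], df2 = df_err,
        F = sm[i, "F value"], p_value = sm[i, "Pr(>F)"],
        pes = sm[i, "Sum Sq"] / (sm[i, "Sum Sq"] + ss_err))
    }
  }
  structure(list(table = dplyr::bind_rows(rows), fit = fit),
            class = "ft_anova")
}

#' @export
print.ft_anova <- function(x, ...) {
  cat("<ft_anova> mixed ANOVA\n")
  print(x$table)
  invisible(x)
}
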