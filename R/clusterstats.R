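#' Chain adjacency over a 1-D frequency grid
#'
#' @param n Number of bins.
#' @return List of integer neighbor vectors, one per bin.
#' @export
chain_adjacency <- function(n) {
  lapply(seq_len(n), function(i) {
    nb <- c(i - 1L, i + 1L)
    nb[nb >= 1L & nb <= n]
  })
}

#' Graph-product adjacency for frequency-by-space bins
#'
#' Bins are indexed frequency-fastest: bin of (frequency `f`, channel `c`)
#' is `(c - 1) * n_freq + f`. Two bins are neighbors when they share a
#' channel and are adjacent in frequency, or share a frequency and are
#' neighboring channels.
#'
#' @param n_freq Number of frequency bins.
#' @param spatial_adj List of neighbor vectors over channels (e.g. from
#'   [chain_adjacency()] for a linear probe), or `NULL` for no spatial
#'   neighbors (each channel clusters only along frequency).
#' @param n_chan Number of channels (required when `spatial_adj` is NULL).
#' @return List of integer neighbor vectors over `n_freq * n_chan` bins.
#' @export
grid_adjacency <- function(n_freq, spatial_adj = NULL, n_chan = NULL) {
  if (is.null(spatial_adj)) {
    stopifnot(!is.null(n_chan))
    spatial_adj <- lapply(seq_len(n_chan), function(i) integer(0))
  }
  nc <- length(spatial_adj)
  lapply(seq_len(n_freq * nc), function(b) {
    f <- ((b - 1L) %% n_freq) + 1L
    ch <- ((b - 1L) %/% n_freq) + 1L
    nb <- integer(0)
    if (f > 1L) nb <- c(nb, b - 1L)
    if (f < n_freq) nb <- c(nb, b + 1L)
    c(nb, (spatial_adj[[ch]] - 1L) * n_freq + f)
  })
}

# Connected components of the supra-threshold mask under an adjacency list.
# Returns a list of integer member vectors.
connected_components <- function(mask, adj) {
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  comp <- list()
  seen <- logical(length(mask))
  for (s in idx) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      for (w in adj[[v]]) {
        if (!seen[w] && mask[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    comp[[length(comp) + 1L]] <- sort(members)
  }
  comp
}

# Max cluster mass (absolute) of a statistic map under a two-sided threshold.
max_cluster_mass <- function(stat, thresh, adj, one_sided = FALSE) {
  m <- 0
  for (cl in connected_components(stat > thresh, adj))
    m <- max(m, sum(stat[cl]))
  if (!one_sided) {
    for (cl in connected_components(stat < -thresh, adj))
      m <- max(m, abs(sum(stat[cl])))
  }
  m
}

#' Cluster-based permutation dependent-samples t test
#'
#' Computes a paired t statistic per bin for the condition difference
#' (`data[, 1, ] - data[, 2, ]`), forms positive and negative clusters
#' separately from bins exceeding the two-sided critical t at
#' `cluster_alpha`, and scores each cluster by its mass (summed t). The
#' null distribution is the maximal absolute cluster mass over random
#' within-subject condition-label sign flips; cluster p-values include the
#' observed statistic, `p = (1 + #\{null >= observed\}) / (1 + n_perm)`,
#' so the smallest attainable p is `1 / (1 + n_perm)`. Under the two-sided
#' convention a cluster is significant at level `alpha` when
#' `p <= alpha / 2` (see [significant_clusters()]).
#'
#' @param data Numeric array subjects x 2 (conditions) x bins. A subjects x
#'   bins matrix of precomputed differences is also accepted.
#' @param adjacency Neighbor list over bins (default: 1-D chain).
#' @param cluster_alpha Cluster-forming threshold as a two-sided p-value
#'   (default 0.01).
#' @param n_perm Number of sign-flip permutations (default 1000; a warning
#'   is issued below 100).
#' @param seed Integer seed for the permutation draw.
#' @return An object of class `cluster_result`: list with `clusters` (each
#'   with `members`, `mass`, `p`, `sign`), `stat_map` (observed t per bin),
#'   `df`, `threshold`, `n_perm`, `cluster_alpha`, `seed`.
#' @export
cluster_perm_ttest <- function(data, adjacency = NULL, cluster_alpha = 0.01,
                               n_perm = 1000L, seed = 1L) {
  d <- if (length(dim(data)) == 3L) {
    if (dim(data)[2] != 2L) stop("need exactly 2 conditions", call. = FALSE)
    data[, 1, , drop = TRUE] - data[, 2, , drop = TRUE]
  } else data
  d <- matrix(d, nrow = if (length(dim(data)) == 3L) dim(data)[1] else nrow(data))
  n <- nrow(d); B <- ncol(d)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  if (is.null(adjacency)) adjacency <- chain_adjacency(B)
  if (length(adjacency) != B)
    stop("adjacency length does not match the number of bins", call. = FALSE)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  tmap_of <- function(means, vars) means / sqrt(vars / n)
  m0 <- colMeans(d)
  v0 <- apply(d, 2, stats::var)
  tmap <- tmap_of(m0, v0)

  pos <- connected_components(tmap > tcrit, adjacency)
  neg <- connected_components(tmap < -tcrit, adjacency)
  clusters <- c(
    lapply(pos, function(cl) list(members = cl, mass = sum(tmap[cl]), sign = 1L)),
    lapply(neg, function(cl) list(members = cl, mass = sum(tmap[cl]), sign = -1L)))

  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
  ssq <- colSums(d^2)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    mp <- drop(signs[p, ] %*% d) / n
    vp <- (ssq - n * mp^2) / (n - 1)
    tp <- tmap_of(mp, vp)
    null_max[p] <- max_cluster_mass(tp, tcrit, adjacency)
  }
  for (i in seq_along(clusters)) {
    obs <- abs(clusters[[i]]$mass)
    clusters[[i]]$p <- (1 + sum(null_max >= obs)) / (1 + n_perm)
  }
  structure(list(clusters = clusters, stat_map = tmap, df = n - 1,
                 threshold = tcrit, n_perm = as.integer(n_perm),
                 cluster_alpha = cluster_alpha, seed = as.integer(seed),
                 null_max = null_max),
            class = "cluster_result")
}

#' Significant clusters of a cluster permutation result
#'
#' For the two-sided dependent t test, positive and negative clusters are
#' each compared against `alpha / 2`; for F-based (ANOVA) results the
#' comparison is one-sided against `alpha`.
#'
#' @param result A `cluster_result`.
#' @param alpha Significance level (default 0.05).
#' @return The subset of clusters passing the criterion.
#' @export
significant_clusters <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "cluster_result"))
  two_sided <- any(vapply(result$clusters, function(cl)
    !is.null(cl$sign), TRUE))
  cut <- if (two_sided) alpha / 2 else alpha
  Filter(function(cl) cl$p <= cut, result$clusters)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold |t|>%.2f (df=%d), %d permutations\n",
              length(x$clusters), x$threshold, x$df, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  sign %+d, %d bins, mass %.2f, p = %.4f\n",
                if (is.null(cl$sign)) 1L else cl$sign,
                length(cl$members), cl$mass, cl$p))
  invisible(x)
}

# Closed-form mixed-design ANOVA (one between factor, two-level within
# factor), vectorized over bins. y1/y2: subjects x bins matrices for the two
# within-factor levels; groups: factor of length subjects.
# Returns per-effect F matrices and dfs. Sums of squares follow the standard
# subject-mean / subject-difference decomposition of the split-plot design.
safe_f <- function(ss_num, df_num, ss_den, df_den) {
  out <- (ss_num / df_num) / (ss_den / df_den)
  out[ss_num == 0] <- 0      # no effect variance: F = 0, not 0/0
  out
}

mixed_anova_f <- function(y1, y2, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  n_g <- table(groups)
  k <- nlevels(groups)
  N <- nrow(y1)
  if (k < 2)
    stop("need at least 2 groups for the mixed design", call. = FALSE)
  if (any(n_g < 2)) stop("every group needs at least 2 subjects", call. = FALSE)
  m <- (y1 + y2) / 2
  d <- y2 - y1
  gm <- colMeans(m)
  ss_btot <- 2 * colSums(sweep(m, 2, gm)^2)
  gmeans <- rowsum(m, groups) / as.vector(n_g)          # k x bins
  ss_group <- 2 * colSums(as.vector(n_g) * sweep(gmeans, 2, gm)^2)
  ss_subj <- pmax(ss_btot - ss_group, 0)
  F_group <- safe_f(ss_group, k - 1, ss_subj, N - k)

  dsum <- colSums(d)
  ss_wtot <- colSums(d^2) / 2
  ss_mod <- dsum^2 / (2 * N)
  gsums <- rowsum(d, groups)                            # k x bins
  ss_modgrp <- colSums(gsums^2 / as.vector(n_g)) / 2
  ss_int <- pmax(ss_modgrp - ss_mod, 0)
  ss_res <- pmax(ss_wtot - ss_modgrp, 0)
  F_mod <- safe_f(ss_mod, 1, ss_res, N - k)
  F_int <- safe_f(ss_int, k - 1, ss_res, N - k)
  list(group = list(F = F_group, df1 = k - 1, df2 = N - k),
       modality = list(F = F_mod, df1 = 1, df2 = N - k),
       interaction = list(F = F_int, df1 = k - 1, df2 = N - k))
}

#' Cluster permutation mixed 2 x 3 ANOVA over bins
#'
#' Mixed-design ANOVA per bin -- modality (two levels, within-subject)
#' crossed with group (between-subject) -- on forward-minus-backward
#' contrast values, with cluster-based permutation correction per effect.
#' Clusters are formed from bins with `F` above the parametric critical
#' value at `cluster_alpha`; cluster mass is summed F. Permutation schemes:
#' group labels are permuted across subjects for the group effect; modality
#' labels are flipped within subjects for the modality effect; the same
#' within-subject flips under fixed group labels approximate the null for
#' the interaction (an exact interaction permutation does not exist).
#'
#' @param contrasts Numeric array subjects x 2 (modalities) x bins of
#'   forward-minus-backward contrast values.
#' @param groups Factor (or vector) of group labels, length subjects; every
#'   group needs >= 2 subjects.
#' @param adjacency Neighbor list over bins (default 1-D chain).
#' @param cluster_alpha Cluster-forming threshold p-value (default 0.01).
#' @param n_perm Permutations per effect (default 1000).
#' @param seed Integer seed.
#' @return An object of class `anova_result`: per-effect list with `F` map,
#'   dfs, critical F and a `cluster_result`; plus the inputs' group table.
#' @export
cluster_perm_mixed_anova <- function(contrasts, groups, adjacency = NULL,
                                     cluster_alpha = 0.01, n_perm = 1000L,
                                     seed = 1L) {
  stopifnot(length(dim(contrasts)) == 3L, dim(contrasts)[2] == 2L)
  groups <- as.factor(groups)
  N <- dim(contrasts)[1]; B <- dim(contrasts)[3]
  if (length(groups) != N) stop("one group label per subject", call. = FALSE)
  if (is.null(adjacency)) adjacency <- chain_adjacency(B)
  y1 <- matrix(contrasts[, 1, ], nrow = N)
  y2 <- matrix(contrasts[, 2, ], nrow = N)
  obs <- mixed_anova_f(y1, y2, groups)
  set.seed(as.integer(seed))
  effects <- list()
  for (eff in names(obs)) {
    o <- obs[[eff]]
    fcrit <- stats::qf(1 - cluster_alpha, o$df1, o$df2)
    comps <- connected_components(o$F > fcrit, adjacency)
    clusters <- lapply(comps, function(cl)
      list(members = cl, mass = sum(o$F[cl]), sign = NULL))
    null_max <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      if (eff == "group") {
        gp <- sample(groups)
        Fp <- mixed_anova_f(y1, y2, gp)[[eff]]$F
      } else {
        flip <- sample(c(TRUE, FALSE), N, replace = TRUE)
        z1 <- y1; z2 <- y2
        z1[flip, ] <- y2[flip, ]
        z2[flip, ] <- y1[flip, ]
        Fp <- mixed_anova_f(z1, z2, groups)[[eff]]$F
      }
      null_max[p] <- max_cluster_mass(Fp, fcrit, adjacency, one_sided = TRUE)
    }
    for (i in seq_along(clusters)) {
      clusters[[i]]$p <- (1 + sum(null_max >= clusters[[i]]$mass)) / (1 + n_perm)
    }
    effects[[eff]] <- list(
      F = o$F, df1 = o$df1, df2 = o$df2, f_crit = fcrit,
      clusters = structure(list(clusters = clusters, stat_map = o$F,
                                df = c(o$df1, o$df2), threshold = fcrit,
                                n_perm = as.integer(n_perm),
                                cluster_alpha = cluster_alpha,
                                seed = as.integer(seed)),
                           class = "cluster_result"))
  }
  structure(list(effects = effects, groups = table(groups),
                 n_perm = as.integer(n_perm), cluster_alpha = cluster_alpha,
                 seed = as.integer(seed)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  for (eff in names(x$effects)) {
    e <- x$effects[[eff]]
    if (length(e$F) == 1L) {
      cat(sprintf("  %s: F(%d,%d) = %.3f, p = %.4g\n",
                  eff, e$df1, e$df2, e$F, e$p))
    } else {
      ncl <- length(e$clusters$clusters)
      cat(sprintf("  %s: F map over %d bins, %d cluster(s)\n",
                  eff, length(e$F), ncl))
    }
  }
  invisible(x)
}

#' Parametric mixed ANOVA at a single bin or ROI value
#'
#' The same mixed-design decomposition as the cluster ANOVA, evaluated at
#' one value per subject and modality, with parametric F p-values (no
#' permutation) and post hoc tests: a paired t across modalities and Welch
#' t tests between groups.
#'
#' @param values Numeric matrix subjects x 2 (modalities) of contrast
#'   values.
#' @param groups Group labels, length subjects.
#' @return An `anova_result` with per-effect `F`, dfs, parametric `p`, and
#'   a `posthoc` data.frame.
#' @export
point_anova <- function(values, groups) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 2L)
  groups <- as.factor(groups)
  res <- mixed_anova_f(values[, 1, drop = FALSE], values[, 2, drop = FALSE],
                       groups)
  effects <- lapply(res, function(o)
    list(F = unname(o$F), df1 = o$df1, df2 = o$df2,
         p = unname(stats::pf(o$F, o$df1, o$df2, lower.tail = FALSE))))
  ph <- posthoc_tests(rowMeans(values), groups = groups,
                      paired_with = list(values[, 1], values[, 2]))
  structure(list(effects = effects, groups = table(groups), posthoc = ph),
            class = "anova_result")
}

#' Post hoc tests: paired t within subjects, Welch t between groups
#'
#' Between-group comparisons use the unequal-variance (Welch) t test with
#' Satterthwaite fractional degrees of freedom; within-subject comparisons
#' use the dependent-samples t test. All p-values are two-sided and
#' uncorrected.
#'
#' @param values Numeric vector, one value per subject (used for the
#'   between-group comparisons).
#' @param groups Optional group labels; all pairwise group comparisons are
#'   reported.
#' @param paired_with Optional list of two numeric vectors (per-subject
#'   values under two within-subject levels); their paired t is reported.
#' @return data.frame with columns `comparison`, `t`, `df`, `p`, `variant`.
#' @export
posthoc_tests <- function(values, groups = NULL, paired_with = NULL) {
  rows <- list()
  if (!is.null(paired_with)) {
    a <- paired_with[[1]]; b <- paired_with[[2]]
    dd <- b - a
    if (stats::sd(dd) < .Machine$double.eps^0.5) {
      if (all(abs(dd) < .Machine$double.eps^0.5)) {
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = "level2 - level1", t = 0, df = length(dd) - 1, p = 1,
          variant = "paired")
      } else {
        warning("zero-variance paired differences; paired t undefined")
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = "level2 - level1", t = NA_real_, df = length(dd) - 1,
          p = NA_real_, variant = "paired")
      }
    } else {
      tt <- stats::t.test(b, a, paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "level2 - level1", t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, variant = "paired")
    }
  }
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    lv <- levels(groups)
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j <= i) next
      x <- values[groups == lv[i]]; y <- values[groups == lv[j]]
      if (stats::sd(x) < .Machine$double.eps^0.5 &&
          stats::sd(y) < .Machine$double.eps^0.5) {
        warning("zero-variance cells; Welch t undefined")
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = sprintf("%s - %s", lv[i], lv[j]), t = NA_real_,
          df = NA_real_, p = NA_real_, variant = "welch")
        next
      }
      tt <- stats::t.test(x, y, var.equal = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s - %s", lv[i], lv[j]),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
        variant = "welch")
    }
  }
  do.call(rbind, rows)
}
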