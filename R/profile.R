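# Cluster profiling: per-cluster summaries with one-way ANOVA F statistics,
# computable from raw records or from printed summary statistics alone.

#' One-way ANOVA from group summary statistics
#'
#' Computes the one-way ANOVA F statistic for a continuous variable from
#' per-group sizes, means and (sample) standard deviations:
#' \deqn{F = \frac{\sum_k n_k (\bar x_k - \bar x)^2 / (K-1)}
#'            {\sum_k (n_k - 1) s_k^2 / (N-K)}}
#' with \eqn{\bar x} the size-weighted grand mean. This is algebraically
#' identical to `anova(lm(...))` on the raw observations.
#'
#' @param ns Integer group sizes.
#' @param means Group means.
#' @param sds Group sample standard deviations (variance contribution of a
#'   singleton group is zero).
#' @return List with `f`, `p` (upper tail of the F distribution on
#'   (K-1, N-K) df), `df1`, `df2`. Zero within-group variance with unequal
#'   means yields `f = Inf`, `p = 0`.
#' @examples
#' anova_f_continuous(c(71, 84, 56, 42), c(3.1, 3.2, 3.1, 3.8),
#'                    c(2.2, 2.2, 2.2, 2.1)) # F ~ 1.10
#' @export
anova_f_continuous <- function(ns, means, sds) {
  k <- length(ns)
  if (k < 2L) stop_domain("at least two groups are required")
  if (length(means) != k || length(sds) != k)
    stop_domain("ns, means and sds must have equal length")
  if (any(ns < 1L)) stop_domain("group sizes must be positive")
  if (any(sds < 0)) stop_domain("standard deviations must be non-negative")
  n_total <- sum(ns)
  grand <- sum(ns * means) / n_total
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- n_total - k
  if (ss_w == 0) {
    f <- if (ss_b == 0) 0 else Inf
  } else {
    f <- (ss_b / df1) / (ss_w / df2)
  }
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' One-way ANOVA for a dummy-coded categorical level
#'
#' Treats the level indicator as 0/1 data: with per-group proportions
#' \eqn{p_k}, the within-group sum of squares of a 0/1 vector about its
#' mean is exactly \eqn{n_k p_k (1 - p_k)}, so
#' \eqn{F = [\sum_k n_k (p_k - \bar p)^2 / (K-1)] /
#'          [\sum_k n_k p_k (1-p_k) / (N-K)]}.
#' Identical to [anova_f_continuous()] applied to the expanded 0/1 vectors.
#'
#' @param ns Integer group sizes.
#' @param ps Per-group proportions in `[0, 1]`.
#' @return List with `f`, `p`, `df1`, `df2`, and `flag` (`"degenerate"`
#'   when the level is absent or universal overall, leaving F undefined).
#' @examples
#' anova_f_binary(c(71, 84, 56, 42), c(0.746, 1, 0.429, 0)) # F ~ 95.97
#' @export
anova_f_binary <- function(ns, ps) {
  k <- length(ns)
  if (k < 2L) stop_domain("at least two groups are required")
  if (length(ps) != k) stop_domain("ns and ps must have equal length")
  if (any(ps < 0 | ps > 1)) stop_domain("proportions must lie in [0, 1]")
  if (any(ns < 1L)) stop_domain("group sizes must be positive")
  n_total <- sum(ns)
  p_bar <- sum(ns * ps) / n_total
  df1 <- k - 1L
  df2 <- n_total - k
  if (p_bar %in% c(0, 1)) {
    return(list(f = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                flag = "degenerate"))
  }
  ss_b <- sum(ns * (ps - p_bar)^2)
  ss_w <- sum(ns * ps * (1 - ps))
  f <- if (ss_w == 0) { if (ss_b == 0) 0 else Inf } else
    (ss_b / df1) / (ss_w / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, flag = NULL)
}

#' Size-weighted grand mean
#'
#' Pools per-cluster means (or proportions) into the overall cohort figure:
#' \eqn{\sum_k n_k x_k / \sum_k n_k}.
#'
#' @param ns Group sizes.
#' @param xs Group means or proportions.
#' @return The grand mean.
#' @examples
#' grand_mean(c(71, 84, 56, 42), c(70.7, 74.5, 73.6, 73.9)) # 73.1
#' @export
grand_mean <- function(ns, xs) {
  if (length(ns) != length(xs)) stop_domain("ns and xs must have equal length")
  if (sum(ns) == 0) stop_domain("total size is zero")
  sum(ns * xs) / sum(ns)
}

# Which categorical levels get a profile row: every level for variables
# with three or more levels; a single indicator level for two-level
# variables (the "1"/male convention of the published table).
profile_levels <- function(levels) {
  if (length(levels) > 2L) return(levels)
  if ("1" %in% levels) "1" else levels[1L]
}

#' Per-cluster risk-profile table
#'
#' Reproduces the published table layout from raw records and a cluster
#' labeling: one row per continuous variable (per-cluster mean and SD) and
#' one dummy-coded row per profiled categorical level (per-cluster
#' percentage), each with its one-way ANOVA F statistic and p-value on
#' (K-1, N-K) degrees of freedom.
#'
#' @param records Complete-case patient record data frame.
#' @param labels Integer cluster labels (length `nrow(records)`, values
#'   1..K), or a named vector keyed by `patient_id`.
#' @param schema An `"amd_schema"` naming the profiled variables.
#' @param bonferroni Add a Bonferroni-adjusted p-value column (default off;
#'   the published table reports raw p-values).
#' @return Object of class `"amd_profile"`: list with `sizes`, `pct`,
#'   `rows` (data frame: variable, level, kind, per-cluster statistics,
#'   `f`, `p`), `k`, `n`.
#' @export
profile_clusters <- function(records, labels, schema = feature_schema(),
                             bonferroni = FALSE) {
  stopifnot(is.data.frame(records))
  if (!is.null(names(labels)) && !is.null(records$patient_id)) {
    if (!all(records$patient_id %in% names(labels)))
      stop_domain("labels do not cover all records")
    labels <- labels[as.character(records$patient_id)]
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(records))
    stop_domain("labels must cover all records")
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L)) stop_domain("empty cluster index in labels")
  n_total <- sum(sizes)
  if (k < 2L)
    warning("single-cluster labeling: F statistics are undefined", call. = FALSE)
  if (any(sizes < 2L))
    warning("cluster of size < 2: its variance contribution is zero", call. = FALSE)

  rows <- list()
  for (v in schema$continuous) {
    x <- as.numeric(records[[v]])
    means <- vapply(seq_len(k), function(g) mean(x[labels == g]), numeric(1))
    sds <- vapply(seq_len(k), function(g) {
      xs <- x[labels == g]
      if (length(xs) < 2L) 0 else stats::sd(xs)
    }, numeric(1))
    ft <- if (k >= 2L) anova_f_continuous(sizes, means, sds)
          else list(f = NA_real_, p = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA_character_, kind = "continuous",
      t(stats::setNames(means, paste0("stat_", seq_len(k)))),
      t(stats::setNames(sds, paste0("sd_", seq_len(k)))),
      f = ft$f, p = ft$p)
  }
  for (v in names(schema$categorical)) {
    lv <- schema$categorical[[v]]
    for (l in profile_levels(lv)) {
      ind <- cat_chr(records[[v]]) == l
      ps <- vapply(seq_len(k), function(g) mean(ind[labels == g]), numeric(1))
      ft <- if (k >= 2L) anova_f_binary(sizes, ps)
            else list(f = NA_real_, p = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l, kind = "binary",
        t(stats::setNames(100 * ps, paste0("stat_", seq_len(k)))),
        t(stats::setNames(rep(NA_real_, k), paste0("sd_", seq_len(k)))),
        f = ft$f, p = ft$p)
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  if (bonferroni) rows$p_bonferroni <- pmin(rows$p * nrow(rows), 1)
  structure(list(sizes = sizes, pct = 100 * sizes / n_total, rows = rows,
                 k = k, n = n_total),
            class = "amd_profile")
}

#' @export
print.amd_profile <- function(x, digits = 2, ...) {
  cat(sprintf("Patient clusters defined by risk characteristics (N = %d)\n", x$n))
  hdr <- paste0("Cluster ", seq_len(x$k), " (n = ", x$sizes, ", ",
                formatC(x$pct, format = "f", digits = 1), "%)")
  cat(" ", paste(hdr, collapse = "  "), "\n")
  for (i in seq_len(nrow(x$rows))) {
    r <- x$rows[i, ]
    label <- if (is.na(r$level)) r$variable else paste0(r$variable, " [", r$level, "]")
    stats_txt <- vapply(seq_len(x$k), function(g) {
      s <- r[[paste0("stat_", g)]]
      sd <- r[[paste0("sd_", g)]]
      if (r$kind == "continuous")
        sprintf("%.1f ± %.1f", s, sd)
      else sprintf("%.1f%%", s)
    }, character(1))
    cat(sprintf("  %-28s %s   F = %s, P = %s\n", label,
                paste(formatC(stats_txt, width = 13), collapse = " "),
                formatC(r$f, format = "fg", digits = 4),
                format.pval(r$p, digits = 3, eps = 1e-3)))
  }
  invisible(x)
}

#' Write a profile table to CSV
#'
#' @param profile An `"amd_profile"`.
#' @param path Output CSV path.
#' @return The profile, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "amd_profile"))
  utils::write.csv(profile$rows, path, row.names = FALSE, quote = FALSE)
  invisible(profile)
}
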