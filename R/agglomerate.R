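# Agglomerative merging of pre-clusters under the log-likelihood distance,
# with BIC computed per candidate number of clusters.

#' Finite-mixture log-likelihood of a partition
#'
#' Treats the partition as a fitted finite mixture: component weights
#' \eqn{n_k/N}, per-component independent Gaussian densities for the
#' continuous variables (variance \eqn{\hat\sigma^2_{vk} + f_v}, the same
#' variance floor as the clustering distance) and multinomial probabilities
#' for the categorical variables, all read off the exact cluster features.
#' Returns the total log-likelihood of the records under that mixture,
#' \eqn{\sum_i \log \sum_k w_k f_k(x_i)}. Unlike the summed
#' classification terms \eqn{\sum \xi_v}, this quantity does not reward
#' hard entropy-carving of iid data, which makes it the sound basis for
#' choosing the number of clusters.
#'
#' @param cfs List of cluster features forming a partition.
#' @param enc The shared `"amd_encoding"` (supplies the records).
#' @return Scalar log-likelihood.
#' @export
mixture_log_likelihood <- function(cfs, enc) {
  n <- enc$n
  K <- length(cfs)
  sizes <- vapply(cfs, `[[`, numeric(1), "n")
  w <- sizes / sum(sizes)
  p <- ncol(enc$X)
  comp_ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    cf <- cfs[[k]]
    mu <- cf$sum / cf$n
    v <- pmax(cf$sumsq / cf$n - mu^2, 0) + enc$floors
    ll <- rep(log(w[k]), n)
    for (j in seq_len(p))
      ll <- ll + stats::dnorm(enc$X[, j], mu[j], sqrt(v[j]), log = TRUE)
    if (ncol(enc$C)) {
      pr <- cf$counts / cf$n
      lp <- ifelse(pr > 0, log(pr), -Inf)
      for (j in seq_len(ncol(enc$C))) ll <- ll + lp[enc$C[, j]]
    }
    comp_ll[, k] <- ll
  }
  m <- apply(comp_ll, 1L, max)
  sum(m + log(rowSums(exp(comp_ll - m))))
}

#' Mixture BIC of a partition
#'
#' \eqn{-2\,\ell_{mix} + [\,(K-1) + K\,(2p + \sum_c (L_c-1))\,] \log N}
#' with \eqn{\ell_{mix}} from [mixture_log_likelihood()]: the standard
#' Bayesian information criterion for a K-component mixture, counting the
#' K-1 free weights on top of the per-component parameters.
#'
#' @inheritParams mixture_log_likelihood
#' @return Scalar BIC (smaller is better).
#' @export
mixture_bic <- function(cfs, enc) {
  K <- length(cfs)
  n_total <- sum(vapply(cfs, `[[`, numeric(1), "n"))
  m_k <- (K - 1) + K * params_per_cluster(enc$schema)
  -2 * mixture_log_likelihood(cfs, enc) + m_k * log(n_total)
}

#' Classification BIC of a partition
#'
#' \eqn{\mathrm{BIC}(K) = -2\sum_v \xi_v + m_K \log N} where the sum runs
#' over the K clusters and \eqn{m_K = K\,(2p + \sum_c (L_c - 1))} counts a
#' mean and variance per continuous variable and \eqn{L_c - 1} free
#' proportions per categorical variable, per cluster. This is the
#' hard-assignment criterion that accompanies the log-likelihood distance;
#' because any partition of even iid data compresses within-cluster
#' entropy, it systematically favors large K and is reported per solution
#' but not used for selecting K by default (see [mixture_bic()] and
#' [select_k()]).
#'
#' @param cfs List of cluster features forming a partition.
#' @param enc The shared `"amd_encoding"`.
#' @return Scalar BIC (smaller is better).
#' @export
partition_bic <- function(cfs, enc) {
  xi <- sum(vapply(cfs, cf_log_likelihood, numeric(1), enc = enc))
  n_total <- sum(vapply(cfs, `[[`, numeric(1), "n"))
  -2 * xi + length(cfs) * params_per_cluster(enc$schema) * log(n_total)
}

# Lexicographically smallest (i, j), i < j, attaining the minimum of the
# active-distance matrix. Deterministic tie-break.
min_pair <- function(D, alive) {
  idx <- which(alive)
  best <- c(NA_integer_, NA_integer_); best_d <- Inf
  for (a in seq_along(idx)[-length(idx)]) {
    i <- idx[a]
    js <- idx[idx > i]
    d <- D[i, js]
    j <- js[which.min(d)]
    if (min(d) < best_d) { best_d <- min(d); best <- c(i, j) }
  }
  list(i = best[1L], j = best[2L], d = best_d)
}

#' Greedy agglomeration over pre-clusters
#'
#' Classic agglomerative routine: starting from the pre-clusters, at each
#' step merge the pair with the smallest log-likelihood distance (ties
#' broken by the lowest index pair), recording one solution per candidate
#' number of clusters K in `k_range`, each with its BIC.
#'
#' @param pre An `"amd_preclusters"` object (or a plain list of cluster
#'   features, in which case `assignment` maps records to them).
#' @param enc The `"amd_encoding"` the pre-clusters were built under.
#' @param k_range Integer vector of candidate cluster counts (contiguous
#'   range including 1 recommended, so [select_k()] can apply its rules).
#' @return A list of class `"amd_solutions"`, one entry per K (descending),
#'   each a list with `k`, `labels` (integer per record, 1..K), `assignment`
#'   (pre-cluster -> cluster), `cluster_features`, `sizes`, `bic`, and the
#'   `merge_trace` up to that solution (columns `i`, `j`, `distance`,
#'   `k_after`, `bic_after`).
#' @export
agglomerate <- function(pre, enc, k_range = 1:8) {
  stopifnot(inherits(pre, "amd_preclusters"), inherits(enc, "amd_encoding"))
  k_range <- sort(unique(as.integer(k_range)))
  m <- length(pre$cfs)
  if (any(k_range < 1L) || any(k_range > m))
    stop_domain("k_range must lie within [1, number of pre-clusters]")

  cfs <- pre$cfs
  alive <- rep(TRUE, m)
  # cluster_of[p]: current cluster slot of pre-cluster p
  cluster_of <- seq_len(m)
  D <- matrix(Inf, m, m)
  if (m > 1L) for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m))
    D[i, j] <- cluster_distance(cfs[[i]], cfs[[j]], enc)

  trace <- data.frame(i = integer(), j = integer(), distance = numeric(),
                      k_after = integer(), bic_after = numeric())
  solutions <- list()

  snapshot <- function(k) {
    slots <- which(alive)
    remap <- integer(m); remap[slots] <- seq_along(slots)
    assignment <- remap[cluster_of]
    labels <- assignment[pre$assignment]
    cl_cfs <- cfs[slots]
    list(k = k, labels = labels, assignment = assignment,
         cluster_features = cl_cfs,
         sizes = vapply(cl_cfs, `[[`, numeric(1), "n"),
         bic = partition_bic(cl_cfs, enc),
         mixture_bic = mixture_bic(cl_cfs, enc),
         merge_trace = trace)
  }

  k_now <- m
  if (k_now %in% k_range) solutions[[as.character(k_now)]] <- snapshot(k_now)
  while (k_now > 1L) {
    p <- min_pair(D, alive)
    cfs[[p$i]] <- cf_merge(cfs[[p$i]], cfs[[p$j]])
    alive[p$j] <- FALSE
    cluster_of[cluster_of == p$j] <- p$i
    for (t in which(alive)) {
      if (t == p$i) next
      d <- cluster_distance(cfs[[p$i]], cfs[[t]], enc)
      D[min(p$i, t), max(p$i, t)] <- d
    }
    k_now <- k_now - 1L
    bic_now <- partition_bic(cfs[alive], enc)
    trace <- rbind(trace, data.frame(i = p$i, j = p$j, distance = p$d,
                                     k_after = k_now, bic_after = bic_now))
    if (k_now %in% k_range) solutions[[as.character(k_now)]] <- snapshot(k_now)
  }
  structure(solutions[order(-as.integer(names(solutions)))],
            class = "amd_solutions")
}

#' @export
print.amd_solutions <- function(x, ...) {
  cat("Agglomerative solutions (log-likelihood distance):\n")
  for (s in x)
    cat(sprintf("  K = %d  classification BIC = %.2f  mixture BIC = %.2f  sizes: %s\n",
                s$k, s$bic, s$mixture_bic, paste(s$sizes, collapse = ", ")))
  invisible(x)
}

#' Select the number of clusters
#'
#' Applies an argmin-with-fallback rule to a BIC curve over the candidate
#' K range: the K minimizing the criterion; when the curve is monotone
#' decreasing over the whole range (so the raw minimum sits at the
#' boundary and is uninformative), fall back to the largest K whose
#' BIC-change ratio \eqn{[BIC(K-1) - BIC(K)] / [BIC(1) - BIC(2)]} still
#' exceeds `ratio_cutoff`. By default the rule is applied to the mixture
#' BIC ([mixture_bic()]); `criterion = "classification"` applies it to the
#' hard-assignment BIC instead, which on mixed-type data tends to select
#' the top of the range. An explicit `k_override` bypasses selection,
#' mirroring the manual review of candidate solutions that the published
#' analysis applied on top of BIC.
#'
#' @param solutions An `"amd_solutions"` list covering a contiguous K range
#'   that includes K = 1.
#' @param ratio_cutoff BIC-change ratio cutoff for the monotone fallback
#'   (default 0.04).
#' @param k_override Optional integer forcing the returned K.
#' @param criterion `"mixture"` (default) or `"classification"`.
#' @return The selected solution (one element of `solutions`).
#' @export
select_k <- function(solutions, ratio_cutoff = 0.04, k_override = NULL,
                     criterion = c("mixture", "classification")) {
  criterion <- match.arg(criterion)
  if (length(solutions) == 0L) stop_domain("no solutions to select from")
  ks <- vapply(solutions, `[[`, numeric(1), "k")
  if (!is.null(k_override)) {
    hit <- which(ks == k_override)
    if (!length(hit)) stop_domain("k_override not among computed solutions")
    return(solutions[[hit]])
  }
  if (!1 %in% ks || !all(diff(sort(ks)) == 1))
    stop_domain("solutions must cover a contiguous K range including K = 1")
  ord <- order(ks)
  ks <- ks[ord]
  field <- if (criterion == "mixture") "mixture_bic" else "bic"
  bic <- vapply(solutions, `[[`, numeric(1), field)[ord]
  monotone_dec <- all(diff(bic) < 0)
  if (!monotone_dec) return(solutions[[ord[which.min(bic)]]])
  denom <- bic[1L] - bic[2L]
  ratio <- (bic[-length(bic)] - bic[-1L]) / denom  # ratio[k] for step k -> k+1
  keep <- which(ratio > ratio_cutoff)
  k_star <- if (length(keep)) ks[max(keep) + 1L] else 1L
  solutions[[ord[which(ks == k_star)]]]
}

#' Two-step clustering of a patient cohort
#'
#' Full clustering stage: encode the records under the schema, compress
#' them into pre-clusters with the BIRCH-style cluster-feature tree, merge
#' greedily under the log-likelihood distance, and pick the number of
#' clusters by BIC. Identical records, seed and configuration yield
#' identical labels.
#'
#' @param records Complete-case patient record data frame (see
#'   [build_cohort()]).
#' @param schema An `"amd_schema"` (default: the published analysis set).
#' @param k_range Candidate cluster counts (default 1:8).
#' @param branching,leaf_budget,threshold CF-tree parameters, see
#'   [build_cf_tree()].
#' @param ratio_cutoff,k_override,criterion Selection parameters, see
#'   [select_k()].
#' @param seed Integer seed for the insertion-order shuffle.
#' @return Object of class `"amd_clustering"`: list with `solution` (the
#'   selected one), `solutions` (all K), `preclusters`, `encoding`, `k`,
#'   `labels` (named by patient id), `bic_table` (classification and
#'   mixture BIC per K).
#' @export
two_step_cluster <- function(records, schema = feature_schema(), k_range = 1:8,
                             branching = 8L, leaf_budget = 64L, threshold = 0,
                             ratio_cutoff = 0.04, k_override = NULL,
                             criterion = c("mixture", "classification"),
                             seed = NULL) {
  enc <- encode_records(records, schema)
  pre <- build_cf_tree(enc, branching = branching, leaf_budget = leaf_budget,
                       threshold = threshold, seed = seed)
  k_range <- k_range[k_range <= length(pre$cfs)]
  if (!length(k_range)) stop_domain("fewer pre-clusters than every requested K")
  sols <- agglomerate(pre, enc, k_range = k_range)
  sol <- select_k(sols, ratio_cutoff = ratio_cutoff, k_override = k_override,
                  criterion = criterion)
  labels <- stats::setNames(sol$labels, enc$ids)
  structure(list(solution = sol, solutions = sols, preclusters = pre,
                 encoding = enc, k = sol$k, labels = labels,
                 bic_table = data.frame(
                   k = vapply(sols, `[[`, numeric(1), "k"),
                   bic = vapply(sols, `[[`, numeric(1), "bic"),
                   mixture_bic = vapply(sols, `[[`, numeric(1), "mixture_bic"),
                   row.names = NULL)),
            class = "amd_clustering")
}

#' @export
print.amd_clustering <- function(x, ...) {
  cat(sprintf("Two-step clustering: K = %d over %d records (%d pre-clusters)\n",
              x$k, length(x$labels), length(x$preclusters$cfs)))
  cat("  cluster sizes:", paste(x$solution$sizes, collapse = ", "), "\n")
  cat(sprintf("  BIC at K = %d: %.2f\n", x$k, x$solution$bic))
  invisible(x)
}
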