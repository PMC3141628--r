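# BIRCH-style cluster-feature tree: one-pass pre-clustering of records
# under a log-likelihood distance threshold, with threshold-raising
# rebuilds when the leaf-entry budget is exceeded.

# A tree node is a list:
#   leaf node:     list(leaf = TRUE,  entries = list of <entry>)
#   internal node: list(leaf = FALSE, children = list of <node>, cf = list of child CFs)
# An <entry> is list(cf = <cluster feature>, members = integer record indices).

node_cf <- function(node) {
  cfs <- if (node$leaf) lapply(node$entries, `[[`, "cf") else node$cf
  Reduce(cf_merge, cfs)
}

# Split a list of entries (or child nodes with CFs) into two groups seeded
# by the farthest pair; others join the nearer seed. Deterministic.
split_two <- function(cfs, enc) {
  m <- length(cfs)
  best <- c(1L, 2L); best_d <- -1
  for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
    d <- cluster_distance(cfs[[i]], cfs[[j]], enc)
    if (d > best_d) { best_d <- d; best <- c(i, j) }
  }
  g <- integer(m)
  g[best] <- c(1L, 2L)
  for (i in setdiff(seq_len(m), best)) {
    d1 <- cluster_distance(cfs[[i]], cfs[[best[1L]]], enc)
    d2 <- cluster_distance(cfs[[i]], cfs[[best[2L]]], enc)
    g[i] <- if (d1 <= d2) 1L else 2L
  }
  g
}

# Insert an entry; returns a list of one node (no split) or two (split).
tree_insert <- function(node, entry, thr, branching, enc) {
  if (node$leaf) {
    if (length(node$entries)) {
      d <- vapply(node$entries, function(e)
        cluster_distance(e$cf, entry$cf, enc), numeric(1))
      j <- which.min(d)
      if (d[j] <= thr) {
        node$entries[[j]]$cf <- cf_merge(node$entries[[j]]$cf, entry$cf)
        node$entries[[j]]$members <- c(node$entries[[j]]$members, entry$members)
        return(list(node))
      }
    }
    node$entries <- c(node$entries, list(entry))
    if (length(node$entries) <= branching) return(list(node))
    g <- split_two(lapply(node$entries, `[[`, "cf"), enc)
    list(list(leaf = TRUE, entries = node$entries[g == 1L]),
         list(leaf = TRUE, entries = node$entries[g == 2L]))
  } else {
    d <- vapply(node$cf, function(cf) cluster_distance(cf, entry$cf, enc), numeric(1))
    j <- which.min(d)
    res <- tree_insert(node$children[[j]], entry, thr, branching, enc)
    node$children[[j]] <- res[[1L]]
    node$cf[[j]] <- node_cf(res[[1L]])
    if (length(res) == 2L) {
      node$children <- append(node$children, res[2L], after = j)
      node$cf <- append(node$cf, list(node_cf(res[[2L]])), after = j)
    }
    if (length(node$children) <= branching) return(list(node))
    g <- split_two(node$cf, enc)
    list(list(leaf = FALSE, children = node$children[g == 1L], cf = node$cf[g == 1L]),
         list(leaf = FALSE, children = node$children[g == 2L], cf = node$cf[g == 2L]))
  }
}

root_insert <- function(root, entry, thr, branching, enc) {
  res <- tree_insert(root, entry, thr, branching, enc)
  if (length(res) == 1L) return(res[[1L]])
  list(leaf = FALSE, children = res, cf = lapply(res, node_cf))
}

collect_entries <- function(node) {
  if (node$leaf) return(node$entries)
  do.call(c, lapply(node$children, collect_entries))
}

min_pairwise_distance <- function(cfs, enc) {
  m <- length(cfs)
  best <- Inf
  for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
    d <- cluster_distance(cfs[[i]], cfs[[j]], enc)
    if (d < best) best <- d
  }
  best
}

#' BIRCH-style pre-clustering of patient records
#'
#' One sequential pass over the records (in seeded shuffled order) inserts
#' each record into a height-balanced cluster-feature tree: descending by
#' nearest child CF, a record is absorbed into the closest leaf entry when
#' the log-likelihood distance is within the threshold, and starts a new
#' entry otherwise. When the number of leaf entries exceeds the budget the
#' tree is rebuilt with a larger threshold (seeded from the smallest
#' pairwise entry distance, doubled thereafter), so the pass ends with at
#' most `leaf_budget` pre-clusters. With threshold 0, only records with
#' identical feature vectors share a pre-cluster.
#'
#' @param enc An `"amd_encoding"` from [encode_records()].
#' @param branching Maximum entries per node (default 8).
#' @param leaf_budget Maximum total leaf entries before a rebuild
#'   (default 64); the number of pre-clusters handed to [agglomerate()].
#' @param threshold Initial absorption threshold (default 0).
#' @param seed Seed for the insertion-order shuffle (`NULL` = input order).
#' @return An object of class `"amd_preclusters"`: list with `cfs` (list of
#'   cluster features), `assignment` (record index -> pre-cluster),
#'   `threshold` (final), `n_rebuilds`.
#' @export
build_cf_tree <- function(enc, branching = 8L, leaf_budget = 64L,
                          threshold = 0, seed = NULL) {
  stopifnot(inherits(enc, "amd_encoding"))
  if (enc$n < 1L) stop_domain("empty input")
  if (branching < 2L) stop_domain("branching factor must be at least 2")
  ord <- with_seed(seed, sample.int(enc$n))
  if (is.null(seed)) ord <- seq_len(enc$n)

  thr <- threshold
  n_rebuilds <- 0L
  root <- list(leaf = TRUE, entries = list())
  for (i in ord) {
    root <- root_insert(root, list(cf = cf_build(enc, i), members = i),
                        thr, branching, enc)
    entries <- collect_entries(root)
    while (length(entries) > leaf_budget) {
      cfs <- lapply(entries, `[[`, "cf")
      thr_new <- max(2 * thr, min_pairwise_distance(cfs, enc), 1e-12)
      repeat {
        root <- list(leaf = TRUE, entries = list())
        for (e in entries) root <- root_insert(root, e, thr_new, branching, enc)
        rebuilt <- collect_entries(root)
        if (length(rebuilt) < length(entries)) break
        thr_new <- 2 * thr_new
      }
      thr <- thr_new
      n_rebuilds <- n_rebuilds + 1L
      entries <- rebuilt
    }
  }

  entries <- collect_entries(root)
  assignment <- integer(enc$n)
  for (k in seq_along(entries)) assignment[entries[[k]]$members] <- k
  structure(list(cfs = lapply(entries, `[[`, "cf"), assignment = assignment,
                 threshold = thr, n_rebuilds = n_rebuilds),
            class = "amd_preclusters")
}

#' @export
print.amd_preclusters <- function(x, ...) {
  cat(sprintf("BIRCH pre-clustering: %d pre-clusters over %d records (threshold %.4g, %d rebuild%s)\n",
              length(x$cfs), length(x$assignment), x$threshold, x$n_rebuilds,
              if (x$n_rebuilds == 1L) "" else "s"))
  invisible(x)
}
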