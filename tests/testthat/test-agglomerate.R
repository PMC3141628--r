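# Greedy agglomeration vs an exhaustive brute-force oracle, BIC
# bookkeeping, and the cluster-number selection rules.

singleton_preclusters <- function(enc) {
  structure(list(cfs = lapply(seq_len(enc$n), function(i) cf_build(enc, i)),
                 assignment = seq_len(enc$n), threshold = 0, n_rebuilds = 0L),
            class = "amd_preclusters")
}

test_that("greedy merging reproduces exhaustive minimal-pair search on singletons", {
  for (seed in c(13, 31)) {
    rec <- random_records(8, seed = seed)
    enc <- encode_records(rec)
    sols <- agglomerate(singleton_preclusters(enc), enc, k_range = 1:8)
    oracle <- oracle_agglomerate(rec)
    trace <- sols[["1"]]$merge_trace
    expect_equal(nrow(trace), 7L)
    for (s in seq_len(7L)) {
      k_after <- 8L - s
      expect_equal(trace$distance[s], oracle[[s]]$d, tolerance = 1e-9)
      if (k_after >= 1L) {
        sol <- sols[[as.character(max(k_after, 1))]]
        # identical partitions at every intermediate K
        expect_setequal(partition_of(sol$labels), oracle[[s]]$partition)
      }
    }
  }
})

test_that("summed log-likelihood terms are non-increasing along the merge trace", {
  co <- simulate_cohort(table1_preset(120L), seed = 17)
  enc <- encode_records(co$records)
  pre <- build_cf_tree(enc, seed = 17)
  sols <- agglomerate(pre, enc, k_range = 1:6)
  trace <- sols[["1"]]$merge_trace
  expect_true(all(trace$distance >= 0))
  # each merge subtracts its distance from the total xi; BIC differences
  # between successive K reflect exactly that plus the parameter penalty
  ks <- vapply(sols, `[[`, numeric(1), "k")
  xi <- vapply(sols, function(s)
    sum(vapply(s$cluster_features, cf_log_likelihood, numeric(1), enc = enc)),
    numeric(1))
  expect_true(all(diff(xi[order(ks)]) >= -1e-9))
})

test_that("classification BIC equals its closed form on every solution", {
  rec <- random_records(20, seed = 23)
  enc <- encode_records(rec)
  pre <- build_cf_tree(enc, seed = 23)
  sols <- agglomerate(pre, enc, k_range = 1:5)
  p <- length(enc$schema$continuous)
  m_per <- 2 * p + sum(lengths(enc$schema$categorical) - 1)
  for (s in sols) {
    xi <- sum(vapply(s$cluster_features, cf_log_likelihood, numeric(1), enc = enc))
    expect_equal(s$bic, -2 * xi + s$k * m_per * log(20), tolerance = 1e-9)
    expect_true(is.finite(s$bic))
    expect_equal(sum(s$sizes), 20)
  }
})

test_that("a single pre-cluster yields one solution with an empty trace", {
  rec <- random_records(5, seed = 40)
  rec[] <- rec[rep(1, 5), ]
  rec$patient_id <- sprintf("P%d", 1:5)
  enc <- encode_records(rec)
  pre <- build_cf_tree(enc, threshold = 0, seed = 1)
  expect_equal(length(pre$cfs), 1L)
  sols <- agglomerate(pre, enc, k_range = 1)
  expect_equal(length(sols), 1L)
  expect_equal(nrow(sols[["1"]]$merge_trace), 0L)
  expect_error(agglomerate(pre, enc, k_range = 1:3), "k_range")
})

fake_solutions <- function(bic, mixture = bic) {
  structure(lapply(seq_along(bic), function(k)
    list(k = k, bic = bic[k], mixture_bic = mixture[k], labels = rep(1, 10),
         sizes = 10, cluster_features = list(), merge_trace = NULL)),
    class = "amd_solutions")
}

test_that("selection takes the argmin and falls back to the change ratio when monotone", {
  sols <- fake_solutions(c(100, 60, 58, 59))
  expect_equal(select_k(sols)$k, 3L)
  # monotone decreasing curve: largest K whose drop exceeds 4% of the first
  sols2 <- fake_solutions(c(100, 60, 55, 54.9))
  expect_equal(select_k(sols2)$k, 3L)  # 5/40 = .125 > .04; 0.1/40 = .0025 < .04
  expect_equal(select_k(sols2, ratio_cutoff = 0.2)$k, 2L)
  expect_equal(select_k(sols2, k_override = 4)$k, 4L)
  expect_error(select_k(sols2, k_override = 9), "k_override")
  expect_error(select_k(fake_solutions(c(10, 9))[2], ), "K = 1")
  # classification criterion selects on the other column
  sols3 <- fake_solutions(c(100, 90, 95, 96), mixture = c(50, 60, 70, 80))
  expect_equal(select_k(sols3, criterion = "classification")$k, 2L)
  expect_equal(select_k(sols3, criterion = "mixture")$k, 1L)
})

test_that("the clustering pipeline is deterministic given records, seed and config", {
  co <- simulate_cohort(table1_preset(), seed = 3)
  c1 <- two_step_cluster(co$records, seed = 5)
  c2 <- two_step_cluster(co$records, seed = 5)
  expect_identical(c1$labels, c2$labels)
  expect_equal(c1$bic_table, c2$bic_table)
  c3 <- two_step_cluster(co$records, seed = 6)
  expect_equal(sum(vapply(c3$solution$cluster_features, `[[`, numeric(1), "n")), 253)
})

test_that("k_override forces the returned number of clusters", {
  co <- simulate_cohort(table1_preset(150L), seed = 12)
  cl <- two_step_cluster(co$records, k_override = 4, seed = 12)
  expect_equal(cl$k, 4L)
  expect_equal(length(unique(cl$labels)), 4L)
})

test_that("the mixture likelihood never rewards splitting iid data past the penalty", {
  nul <- simulate_null_cohort(200L, seed = 77)
  enc <- encode_records(nul$records)
  pre <- build_cf_tree(enc, seed = 77)
  sols <- agglomerate(pre, enc, k_range = 1:5)
  mb <- vapply(sols, `[[`, numeric(1), "mixture_bic")
  ks <- vapply(sols, `[[`, numeric(1), "k")
  expect_equal(unname(ks[which.min(mb)]), 1)
})
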