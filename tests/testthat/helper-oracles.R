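# Brute-force oracles and record builders shared across tests. The oracles
# recompute every quantity directly from raw record lists (scale(), var(),
# table(), lm()) and never touch the cluster-feature machinery they check.

random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = round(runif(n, 55, 90), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    pack_years = round(pmax(rnorm(n, 25, 30), 0), 1),
    alcohol_decades = sample(0:8, n, replace = TRUE),
    bmi = round(runif(n, 18, 40), 1),
    htn_history = runif(n) < 0.6,
    chol_history = runif(n) < 0.5,
    cfh_genotype = sample(c("CC", "CT", "TT"), n, replace = TRUE),
    arms2_genotype = sample(c("CC", "TC", "TT"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Standardize exactly as the encoding defines it: z-score by sample SD,
# floors = population variance of the standardized columns.
oracle_standardize <- function(records, schema = feature_schema()) {
  X <- sapply(schema$continuous, function(v) as.numeric(records[[v]]))
  X <- matrix(X, nrow = nrow(records))
  colnames(X) <- schema$continuous
  if (schema$standardize) {
    for (j in seq_len(ncol(X))) {
      s <- sd(X[, j])
      X[, j] <- (X[, j] - mean(X[, j])) / (if (s > 0) s else 1)
    }
  }
  floors <- apply(X, 2, function(v) mean((v - mean(v))^2))
  list(X = X, floors = floors)
}

# xi recomputed from the raw records of one cluster: population variances
# of the standardized continuous block, plus per-variable entropies.
oracle_xi <- function(records, idx, std, schema = feature_schema()) {
  n <- length(idx)
  cont <- 0
  for (j in seq_along(schema$continuous)) {
    v <- std$X[idx, j]
    sig2 <- mean((v - mean(v))^2)
    cont <- cont + 0.5 * log(sig2 + std$floors[j])
  }
  ent <- 0
  for (v in names(schema$categorical)) {
    x <- records[[v]][idx]
    if (is.logical(x)) x <- as.integer(x)
    p <- as.vector(table(factor(as.character(x), levels = schema$categorical[[v]]))) / n
    p <- p[p > 0]
    ent <- ent - sum(p * log(p))
  }
  unname(-n * (cont + ent))
}

oracle_distance <- function(records, ia, ib, std, schema = feature_schema()) {
  oracle_xi(records, ia, std, schema) + oracle_xi(records, ib, std, schema) -
    oracle_xi(records, c(ia, ib), std, schema)
}

# Exhaustive greedy agglomeration over record-index groups: at each step
# scan every pair, merge the minimum (lexicographic tie-break into the
# lower slot), and record the merged pair and the partition.
oracle_agglomerate <- function(records, schema = feature_schema()) {
  std <- oracle_standardize(records, schema)
  groups <- as.list(seq_len(nrow(records)))
  steps <- list()
  while (length(groups) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(groups) - 1L)) for (j in seq(i + 1L, length(groups))) {
      d <- oracle_distance(records, groups[[i]], groups[[j]], std, schema)
      d <- max(d, 0)
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups <- groups[-best[2L]]
    steps[[length(steps) + 1L]] <- list(d = best_d, partition = lapply(groups, sort))
  }
  steps
}

# One-way ANOVA on raw vectors through R's linear-model machinery.
oracle_anova <- function(y, g) {
  a <- anova(lm(y ~ factor(g)))
  list(f = a$`F value`[1], p = a$`Pr(>F)`[1])
}

partition_of <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}
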