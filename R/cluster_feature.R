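# Mixed-type cluster features (sufficient statistics) and the
# log-likelihood distance that drives both clustering stages.

#' Feature schema for mixed-type clustering
#'
#' Declares which record columns enter the clustering as continuous
#' (Gaussian log-likelihood term) and which as categorical (multinomial
#' entropy term), and whether continuous variables are z-scored before
#' clustering. The default schema is the published analysis set: age,
#' pack-years, alcohol decades and BMI as continuous; sex, hypertension and
#' hypercholesterolemia histories and the two genotypes as categorical.
#'
#' @param continuous Character vector of continuous variable names.
#' @param categorical Named list: variable name -> character vector of levels.
#' @param standardize Z-score continuous variables before clustering
#'   (default `TRUE`; without it pack-years, with an SD near 32, would
#'   dominate BMI and alcohol decades).
#' @return An object of class `"amd_schema"`.
#' @export
feature_schema <- function(continuous = c("age_years", "pack_years",
                                          "alcohol_decades", "bmi"),
                           categorical = list(
                             sex = c("male", "female"),
                             htn_history = c("0", "1"),
                             chol_history = c("0", "1"),
                             cfh_genotype = c("CC", "CT", "TT"),
                             arms2_genotype = c("CC", "TC", "TT")
                           ),
                           standardize = TRUE) {
  stopifnot(is.character(continuous), is.list(categorical))
  if (length(categorical) && is.null(names(categorical)))
    stop_domain("categorical must be a named list of level sets")
  if (any(lengths(categorical) == 0L)) stop_domain("empty level set")
  nm <- c(continuous, names(categorical))
  if (anyDuplicated(nm)) stop_domain("duplicate variable names in schema")
  structure(list(continuous = continuous, categorical = categorical,
                 standardize = isTRUE(standardize)),
            class = "amd_schema")
}

# Number of free parameters per cluster: mean + variance per continuous
# variable, L - 1 free proportions per categorical variable.
params_per_cluster <- function(schema) {
  2L * length(schema$continuous) + sum(lengths(schema$categorical) - 1L)
}

#' Encode records for clustering
#'
#' Converts a record data frame into the numeric representation used by the
#' cluster-feature machinery: a (optionally z-scored) continuous matrix, a
#' matrix of global category-cell indices, and the per-variable variance
#' floors (the whole-cohort variance of each encoded continuous variable)
#' that regularize the Gaussian term.
#'
#' @param records Data frame of complete-case patient records.
#' @param schema An `"amd_schema"`.
#' @return An encoding object (class `"amd_encoding"`) used by
#'   [cf_build()], [cf_log_likelihood()] and [cluster_distance()].
#' @export
encode_records <- function(records, schema = feature_schema()) {
  stopifnot(is.data.frame(records), inherits(schema, "amd_schema"))
  n <- nrow(records)
  if (n == 0L) stop_domain("no records to encode")
  miss <- setdiff(c(schema$continuous, names(schema$categorical)), names(records))
  if (length(miss))
    stop_domain("records lack schema variable(s): ", paste(miss, collapse = ", "))

  X <- matrix(0, n, length(schema$continuous),
              dimnames = list(NULL, schema$continuous))
  for (v in schema$continuous) X[, v] <- as.numeric(records[[v]])
  center <- scale_sd <- rep(0, ncol(X))
  if (schema$standardize && ncol(X)) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2L, stats::sd)
    scale_sd[!is.finite(scale_sd) | scale_sd == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_sd, "/")
  }
  # population variance of the encoded columns: the variance floor
  floors <- apply(X, 2L, function(v) mean(v^2) - mean(v)^2)
  floors[floors <= 0] <- 1e-12

  lvl_counts <- lengths(schema$categorical)
  offsets <- cumsum(c(0L, lvl_counts))[seq_along(lvl_counts)]
  names(offsets) <- names(schema$categorical)
  C <- matrix(0L, n, length(schema$categorical),
              dimnames = list(NULL, names(schema$categorical)))
  for (v in names(schema$categorical)) {
    lv <- schema$categorical[[v]]
    idx <- match(cat_chr(records[[v]]), lv)
    if (anyNA(idx))
      stop_domain("value outside schema levels for ", v)
    C[, v] <- idx + offsets[[v]]
  }
  structure(list(
    X = X, C = C, n = n,
    ids = as.character(records$patient_id %||% seq_len(n)),
    floors = floors, n_cells = sum(lvl_counts), offsets = offsets,
    center = center, scale = scale_sd, schema = schema
  ), class = "amd_encoding")
}

#' Build a cluster feature from a set of records
#'
#' A cluster feature (CF) is the additive sufficient-statistics tuple for a
#' group of records: size, per-variable sums and sums of squares for the
#' continuous block, and per-level counts for the categorical block. CFs
#' merge exactly by field-wise addition, which is what makes the BIRCH-style
#' pre-clustering and the agglomerative stage consistent with raw-record
#' computation.
#'
#' @param enc An `"amd_encoding"`.
#' @param idx Integer indices of the member records.
#' @return A cluster feature (list with `n`, `sum`, `sumsq`, `counts`).
#' @export
cf_build <- function(enc, idx) {
  stopifnot(inherits(enc, "amd_encoding"), length(idx) >= 1L)
  Xi <- enc$X[idx, , drop = FALSE]
  list(
    n = length(idx),
    sum = colSums(Xi),
    sumsq = colSums(Xi^2),
    counts = tabulate(as.vector(enc$C[idx, , drop = FALSE]), nbins = enc$n_cells)
  )
}

#' Merge two cluster features
#'
#' Exact field-wise addition of the sufficient statistics.
#'
#' @param a,b Cluster features built under the same encoding.
#' @return The merged cluster feature.
#' @export
cf_merge <- function(a, b) {
  list(n = a$n + b$n, sum = a$sum + b$sum, sumsq = a$sumsq + b$sumsq,
       counts = a$counts + b$counts)
}

#' Per-cluster log-likelihood term
#'
#' The cluster's contribution to the clustering criterion:
#' \deqn{\xi = -n \left( \sum_k \tfrac12 \log(\hat\sigma^2_k + f_k) +
#'   \sum_c \hat E_c \right)}
#' where \eqn{\hat\sigma^2_k} is the within-cluster (population) variance of
#' continuous variable \eqn{k}, \eqn{f_k} its whole-cohort variance floor,
#' and \eqn{\hat E_c} the empirical entropy of categorical variable
#' \eqn{c} within the cluster (with \eqn{0 \log 0 = 0}). The floor keeps the
#' term finite when a variable is constant inside a cluster.
#'
#' @param cf A cluster feature.
#' @param enc The `"amd_encoding"` it was built under (supplies the floors).
#' @return The scalar \eqn{\xi} (finite for all valid inputs).
#' @export
cf_log_likelihood <- function(cf, enc) {
  if (cf$n < 1L) stop_domain("empty cluster feature")
  n <- cf$n
  mu <- cf$sum / n
  v <- pmax(cf$sumsq / n - mu^2, 0)
  cont <- 0.5 * sum(log(v + enc$floors))
  p <- cf$counts[cf$counts > 0] / n
  ent <- -sum(p * log(p))
  -n * (cont + ent)
}

#' Log-likelihood distance between two clusters
#'
#' The decrease in summed log-likelihood terms caused by merging:
#' \eqn{d(a,b) = \xi_a + \xi_b - \xi_{a \cup b} \ge 0}, with the merged term
#' computed on the exact merged sufficient statistics. This is the standard
#' mixed-type (Gaussian + multinomial) distance used by two-step clustering.
#'
#' @param a,b Disjoint cluster features under the same encoding.
#' @param enc The shared `"amd_encoding"`.
#' @return Non-negative distance.
#' @export
cluster_distance <- function(a, b, enc) {
  if (length(a$sum) != length(b$sum) || length(a$counts) != length(b$counts))
    stop_domain("cluster features come from different schemas")
  d <- cf_log_likelihood(a, enc) + cf_log_likelihood(b, enc) -
    cf_log_likelihood(cf_merge(a, b), enc)
  max(d, 0)
}
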