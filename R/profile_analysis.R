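## Compound effect-profile comparison: correlation matrices, Euclidean
## distances, k-means with silhouette-chosen k, PCA, and univariate 0-10
## scaling with subtraction panels.

as_effect_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (any(apply(m, 1, function(r) all(is.na(r))))) {
    cs_abort("effect matrix contains an all-missing row", "analysis_error")
  }
  if (anyDuplicated(colnames(m))) {
    cs_abort("effect matrix column labels must be unique", "analysis_error")
  }
  m
}

#' Pairwise Pearson correlation of effect-matrix columns
#'
#' Pairwise-complete handling of missing values; zero-variance columns get
#' missing correlations with a warning.
#'
#' @param matrix Numeric matrix / data frame, rows = conditions or
#'   compounds, cols = parameters.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation matrix with unit diagonal.
#' @export
parameter_correlation <- function(matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_effect_matrix(matrix)
  zero_var <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE)) == 0
  if (any(zero_var, na.rm = TRUE)) {
    cs_warn(sprintf("zero-variance column(s): %s; correlations set missing",
                    paste(colnames(m)[which(zero_var)], collapse = ", ")),
            "analysis_warning")
  }
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs", method = method))
  diag(cc) <- 1
  cc
}

#' Euclidean distance matrix between effect profiles
#'
#' @param matrix Numeric matrix, rows = profiles.
#' @param standardize Standardize columns (mean 0, SD 1) first; distances
#'   are then invariant to affine rescaling of any column.
#' @return Square symmetric matrix with zero diagonal.
#' @export
euclidean_distances <- function(matrix, standardize = TRUE) {
  m <- as_effect_matrix(matrix)
  if (standardize) {
    m <- scale(m)
    m[, attr(m, "scaled:scale") == 0] <- 0
  }
  incomplete <- apply(m, 1, function(r) any(is.na(r)))
  if (any(incomplete)) {
    cs_warn(sprintf("dropping %d incomplete row(s) from the distance matrix",
                    sum(incomplete)), "analysis_warning")
    m <- m[!incomplete, , drop = FALSE]
  }
  d <- as.matrix(dist(m, method = "euclidean"))
  diag(d) <- 0
  d
}

## mean silhouette width from a precomputed distance matrix
mean_silhouette <- function(d, assignment) {
  sil <- cluster::silhouette(assignment, dmatrix = d)
  mean(sil[, "sil_width"])
}

#' k-means clustering of effect profiles with silhouette-chosen k
#'
#' Standard k-means with 50 seeded restarts per candidate k; the k in
#' `k_range` maximizing the mean silhouette width is chosen. Deterministic
#' given the seed.
#'
#' @param matrix Numeric matrix, complete rows.
#' @param k_range Candidate cluster counts (each `2 <= k < nrow`).
#' @param seed Integer seed.
#' @param standardize Standardize columns first (default `TRUE`).
#' @return List: `assignments` (named), `chosen_k`, `diagnostics` (tibble of
#'   k, mean silhouette, total within-SS).
#' @export
kmeans_profiles <- function(matrix, k_range = 2:4, seed = 1,
                            standardize = TRUE) {
  m <- as_effect_matrix(matrix)
  if (any(is.na(m))) cs_abort("k-means requires complete rows", "analysis_error")
  if (nrow(m) < 3) cs_abort("need at least 3 profiles to cluster", "analysis_error")
  if (standardize) {
    m <- scale(m)
    m[, attr(m, "scaled:scale") == 0] <- 0
  }
  if (sum(apply(m, 2, stats::var)) == 0) {
    cs_abort("zero variance: all profiles identical", "analysis_error")
  }
  k_range <- k_range[k_range >= 2 & k_range < nrow(m)]
  if (length(k_range) == 0) cs_abort("no valid k in k_range", "analysis_error")
  d <- as.matrix(dist(m))
  fits <- withr::with_seed(as.integer(seed), lapply(k_range, function(k) {
    km <- kmeans(m, centers = k, nstart = 50, iter.max = 100)
    list(k = k, km = km, sil = mean_silhouette(d, km$cluster))
  }))
  sils <- vapply(fits, `[[`, 0, "sil")
  best <- fits[[which.max(sils)]]
  assignments <- best$km$cluster
  names(assignments) <- rownames(m)
  list(assignments = assignments, chosen_k = best$k,
       diagnostics = tibble::tibble(
         k = vapply(fits, `[[`, 0, "k"),
         mean_silhouette = sils,
         tot_withinss = vapply(fits, function(f) f$km$tot.withinss, 0)))
}

#' Principal component scores of effect profiles
#'
#' Columns are standardized internally; components are ordered by decreasing
#' explained variance and sign-fixed so the largest-magnitude loading of
#' each component is positive.
#'
#' @param matrix Numeric matrix, complete rows.
#' @param n_components Number of components to keep (truncated to the rank
#'   with a warning).
#' @param scale Standardize columns first (default); covariance PCA
#'   (`FALSE`) preserves the spectrum under orthogonal rotations of the
#'   input.
#' @return List: `scores`, `loadings`, `explained_variance` (fractions).
#' @export
pca_scores <- function(matrix, n_components = 2, scale = TRUE) {
  m <- as_effect_matrix(matrix)
  if (any(is.na(m))) cs_abort("PCA requires complete rows", "analysis_error")
  sds <- apply(m, 2, sd)
  pc <- prcomp(m, center = TRUE, scale. = scale && all(sds > 0))
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > rank) {
    cs_warn(sprintf("n_components truncated from %d to rank %d", n_components,
                    rank), "analysis_warning")
    n_components <- rank
  }
  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[keep])
}

#' Univariate 0-10 scaling of a condition x parameter panel
#'
#' Each column is min-max rescaled to `[0, 10]` across the scaling domain
#' (all conditions); a constant column cannot be scaled and maps to all 0
#' with a warning. Already-scaled columns spanning `[0, 10]` are left
#' unchanged (idempotence).
#'
#' @param panel Numeric matrix / data frame of raw condition means.
#' @return Matrix of the same shape scaled to `[0, 10]`.
#' @export
univariate_scale <- function(panel) {
  m <- as_effect_matrix(panel)
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j], na.rm = TRUE)
    if (diff(rng) == 0) {
      cs_warn(sprintf("constant column '%s' scaled to all 0", colnames(m)[j]),
              "analysis_warning")
      m[, j] <- 0
    } else {
      m[, j] <- (m[, j] - rng[1]) / diff(rng) * 10
    }
  }
  m
}

#' Subtraction panel (treated minus control)
#'
#' Rows and columns are aligned by label before subtracting; negative values
#' mean a decrease versus control. Both panels must carry identical label
#' sets.
#'
#' @param treated,control Scaled panels (e.g. [univariate_scale()] outputs).
#' @return Elementwise difference, range within `[-10, 10]` for 0-10-scaled
#'   inputs.
#' @export
subtraction_matrix <- function(treated, control) {
  tm <- as_effect_matrix(treated)
  cm <- as_effect_matrix(control)
  if (is.null(rownames(tm))) rownames(tm) <- seq_len(nrow(tm))
  if (is.null(rownames(cm))) rownames(cm) <- seq_len(nrow(cm))
  if (!setequal(rownames(tm), rownames(cm)) ||
      !setequal(colnames(tm), colnames(cm))) {
    cs_abort("treated and control panels must share row and column labels",
             "analysis_error")
  }
  tm[rownames(cm), colnames(cm), drop = FALSE] - cm
}
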