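# Independent brute-force oracle: enumerate the proportion simplex at a
# fixed step and return the vector minimizing the reconstruction RMSE of
# X %*% p against y. Only 2- and 3-type problems are enumerated (101 and
# 5151 candidate points at step 0.01).
simplex_grid_oracle <- function(X, y, step = 0.01) {
  K <- ncol(X)
  stopifnot(K %in% c(2, 3))
  g <- seq(0, 1, by = step)
  P <- if (K == 2) {
    cbind(g, 1 - g)
  } else {
    do.call(rbind, lapply(g, function(a) {
      b <- seq(0, 1 - a, by = step)
      cbind(a, b, 1 - a - b)
    }))
  }
  resid <- X %*% t(P) - as.vector(y)
  best <- which.min(colSums(resid^2))
  stats::setNames(P[best, ], colnames(X))
}

# Restrict a subject_profiles object to a subset of types (keeps the
# cross-subject structure intact).
restrict_profiles <- function(prof, types) {
  prof$mean_profiles <- prof$mean_profiles[, types, drop = FALSE]
  prof$subject_means <- lapply(prof$subject_means,
                               function(m) m[, types, drop = FALSE])
  prof$var <- prof$var[, types, drop = FALSE]
  prof$size_factors <- prof$size_factors[types]
  prof$cell_counts <- prof$cell_counts[, types, drop = FALSE]
  prof$types <- types
  prof
}

endocrine_types <- c("somatotroph", "lactotroph", "thyrotroph",
                     "gonadotroph", "corticotroph", "stem_cell", "pro_pit1")
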