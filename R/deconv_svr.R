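#' Configuration for the nu-SVR deconvolution engine
#'
#' @param nu_grid Candidate `nu` values in (0, 1); the value minimizing the
#'   reconstruction RMSE is kept per sample. The default `{0.25, 0.5, 0.75}`
#'   is the published SVR-deconvolution convention.
#' @param n_permutations Number of random pseudo-mixtures used for the
#'   permutation p-value (0 disables p-values).
#' @param standardize Z-score the signature and each mixture column on the
#'   shared gene set before regression (default TRUE).
#' @return An `svr_config` list.
#' @export
svr_config <- function(nu_grid = c(0.25, 0.5, 0.75), n_permutations = 100,
                       standardize = TRUE) {
  if (any(nu_grid <= 0 | nu_grid >= 1)) {
    stop_pitdeconv("`nu_grid` values must lie in (0, 1).",
                   "pitdeconv_config_error")
  }
  check_scalar_number(n_permutations, "n_permutations", lower = 0,
                      integerish = TRUE)
  structure(
    list(nu_grid = nu_grid, n_permutations = as.integer(n_permutations),
         standardize = isTRUE(standardize)),
    class = "svr_config"
  )
}

#' Deconvolution result container
#'
#' @param proportions Samples x types matrix; non-negative rows summing to 1.
#' @param stats Tibble with per-sample `rmse`, `pearson_r`, `p_value`,
#'   `converged`.
#' @param engine Engine id (`"svr"` or `"wnnls"`).
#' @param signature_id Label of the signature/profile set used.
#' @return A `deconv_result` object.
#' @export
deconv_result <- function(proportions, stats, engine, signature_id = NA) {
  proportions <- as.matrix(proportions)
  if (any(proportions < -1e-12) ||
      any(abs(rowSums(proportions) - 1) > 1e-9)) {
    stop_pitdeconv("proportions must be non-negative rows summing to 1.",
                   "pitdeconv_internal_error")
  }
  structure(
    list(proportions = proportions, stats = as_tibble(stats),
         engine = engine, signature_id = signature_id),
    class = "deconv_result"
  )
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result engine=%s signature=%s> %d samples x %d types\n",
              x$engine, x$signature_id, nrow(x$proportions),
              ncol(x$proportions)))
  invisible(x)
}

# One nu-SVR fit in standardized space; returns normalized weights and fit
# statistics of the reconstruction under those weights.
svr_core <- function(X, y, nu_grid) {
  fits <- map(nu_grid, function(nu) {
    m <- e1071::svm(X, y, type = "nu-regression", kernel = "linear",
                    nu = nu, scale = FALSE)
    w <- as.vector(crossprod(m$coefs, m$SV))
    w[w < 0] <- 0
    q <- if (sum(w) > 0) w / sum(w) else rep(1 / ncol(X), ncol(X))
    recon <- as.vector(X %*% q)
    r <- suppressWarnings(cor(recon, y))
    if (!is.finite(r)) r <- 0  # constant reconstruction carries no signal
    list(q = q, rmse = sqrt(mean((recon - y)^2)), r = r)
  })
  best <- which.min(map_dbl(fits, "rmse"))
  fits[[best]]
}

#' Estimate cell-type proportions by linear nu-support-vector regression
#'
#' The SVR engine of the framework: per sample the mixture and the signature
#' are restricted to their shared genes and z-scored, a linear nu-SVR of the
#' sample on the signature columns is fitted for each value of `nu`, and the
#' fit minimizing reconstruction RMSE is kept. Negative coefficients are
#' clipped to zero and the rest normalized to sum 1 (relative mode).
#' Significance is assessed against a null distribution of reconstruction
#' correlations from random pseudo-mixtures whose gene values are drawn with
#' replacement from the full mixture matrix.
#'
#' @param mixture Genes x samples CPM matrix (a [mixture_set()] is also
#'   accepted).
#' @param signature A [signature_matrix()] or a plain genes x types matrix.
#' @param cfg An [svr_config()].
#' @param seed Integer seed for the permutation null.
#' @return A [deconv_result()] with per-sample `rmse`, `pearson_r` and
#'   permutation `p_value` (NA when `n_permutations = 0`).
#' @export
svr_deconvolve <- function(mixture, signature, cfg = svr_config(), seed = 1L) {
  if (inherits(mixture, "mixture_set")) mixture <- mixture$mixtures
  mixture <- check_expression_matrix(mixture, "mixture")
  sig_id <- NA_character_
  if (inherits(signature, "signature_matrix")) {
    sig_id <- signature$id
    signature <- signature$values
  }
  signature <- check_expression_matrix(signature, "signature")
  if (ncol(signature) < 2) {
    stop_pitdeconv("signature must contain at least two cell types.",
                   "pitdeconv_input_error")
  }

  shared <- intersect(rownames(mixture), rownames(signature))
  if (length(shared) < 2) {
    stop_pitdeconv("fewer than 2 genes shared between mixture and signature.",
                   "pitdeconv_shared_genes_error")
  }
  M <- mixture[shared, , drop = FALSE]
  X <- signature[shared, , drop = FALSE]
  bad_cols <- colSums(M) == 0 | apply(M, 2, sd) == 0
  if (any(bad_cols)) {
    stop_pitdeconv(
      paste0("all-zero or constant sample(s) on the shared gene set ",
             "cannot be deconvolved: ",
             paste(colnames(M)[bad_cols], collapse = ", ")),
      "pitdeconv_input_error"
    )
  }

  if (cfg$standardize) {
    Xs <- (X - mean(X)) / sd(as.vector(X))
  } else {
    Xs <- X
  }
  std_y <- function(y) if (cfg$standardize) (y - mean(y)) / sd(y) else y

  S <- ncol(M)
  K <- ncol(X)
  props <- matrix(0, S, K, dimnames = list(colnames(M), colnames(X)))
  rmse <- r_obs <- numeric(S)
  for (s in seq_len(S)) {
    fit <- svr_core(Xs, std_y(M[, s]), cfg$nu_grid)
    props[s, ] <- fit$q
    rmse[s] <- fit$rmse
    r_obs[s] <- fit$r
  }

  p_value <- rep(NA_real_, S)
  if (cfg$n_permutations > 0) {
    pool <- as.vector(M)
    null_r <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(cfg$n_permutations), function(i) {
        ystar <- sample(pool, length(shared), replace = TRUE)
        if (sd(ystar) == 0) return(0)
        svr_core(Xs, std_y(ystar), cfg$nu_grid)$r
      }, numeric(1))
    })
    p_value <- vapply(r_obs, function(r) mean(null_r >= r), numeric(1))
  }

  deconv_result(
    props,
    tibble(sample = colnames(M), rmse = rmse, pearson_r = r_obs,
           p_value = p_value, converged = TRUE),
    engine = "svr", signature_id = sig_id
  )
}

#' Build a signature matrix directly from annotated single cells
#'
#' The single-cell signature mode: cell types with fewer than `min_cells`
#' cells are excluded; per-type mean CPM profiles are computed; candidate
#' genes are ranked per type by fold change of the type's mean over the
#' maximum mean of the other types; for each candidate size `G` in `g_range`
#' the union of per-type top-`G` genes forms a signature, and the `G`
#' minimizing the 2-norm condition number of the resulting matrix is
#' selected (a well-conditioned signature separates the types best).
#'
#' @param data An [annotated_counts()] object (QC-filtered).
#' @param g_range Candidate per-type gene counts (default `seq(50, 200, 25)`).
#' @param min_cells Low-representation exclusion threshold (default 50).
#' @param max_kappa Condition number above which a signature is considered
#'   singular (default 1e9).
#' @return A [signature_matrix()] with id `"SC-G<G>"`.
#' @export
build_signature_from_cells <- function(data, g_range = seq(50, 200, by = 25),
                                       min_cells = 50, max_kappa = 1e9) {
  stopifnot(inherits(data, "annotated_counts"))
  tab <- table(data$annotation$cell_type)
  kept <- names(tab)[tab >= min_cells]
  dropped <- setdiff(names(tab), kept)
  if (length(dropped) > 0) {
    inform(paste0(
      "build_signature_from_cells: excluding low-representation type(s) (<",
      min_cells, " cells): ", paste(dropped, collapse = ", ")
    ))
  }
  if (length(kept) < 2) {
    stop_pitdeconv("need at least two cell types after the low-count exclusion.",
                   "pitdeconv_input_error")
  }
  keep_cells <- data$annotation$cell_type %in% kept
  cpm <- cpm_normalize(data$counts[, keep_cells, drop = FALSE])
  labels <- data$annotation$cell_type[keep_cells]
  prof <- type_profiles(cpm, labels)

  K <- ncol(prof)
  ranked <- map(setNames(seq_len(K), colnames(prof)), function(k) {
    others <- prof[, -k, drop = FALSE]
    fc <- (prof[, k] + 1) / (apply(others, 1, max) + 1)
    ord <- order(-fc, rownames(prof))
    rownames(prof)[ord]
  })

  kappas <- map_dbl(g_range, function(G) {
    genes <- sort(unique(unlist(map(ranked, head, G))))
    X <- prof[genes, , drop = FALSE]
    if (nrow(X) < K) return(Inf)
    kappa(X, exact = TRUE)
  })
  if (all(!is.finite(kappas)) || min(kappas) > max_kappa) {
    stop_pitdeconv(
      "signature is singular (collinear type profiles) at every candidate size.",
      "pitdeconv_singular_signature_error"
    )
  }
  G <- g_range[which.min(kappas)]
  members <- map(ranked, head, G)
  genes <- sort(unique(unlist(members)))
  vals <- prof[genes, , drop = FALSE]
  keep <- apply(vals, 1, max) > 1
  vals <- vals[keep, , drop = FALSE]
  members <- map(members, function(g) intersect(g, rownames(vals)))
  signature_matrix(vals, members, n = G, id = paste0("SC-G", G))
}
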