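#' Multi-subject cell-type profiles for weighted NNLS
#'
#' Summarizes an annotated reference per (subject, cell type): the mean CPM
#' profile and cell count, the cross-subject variance of each (gene, type)
#' mean, and a per-type cell size factor (mean library size), which converts
#' RNA-mass coefficients into cell-count proportions.
#'
#' @param data An [annotated_counts()] object.
#' @param min_cells Cell types with fewer total cells are dropped
#'   (default 50).
#' @return A `subject_profiles` object: `mean_profiles` (genes x types,
#'   across-subject mean CPM), `subject_means` (list per subject of genes x
#'   types matrices), `var` (genes x types cross-subject variance),
#'   `size_factors` (per type), `cell_counts` (subjects x types).
#' @export
subject_profiles <- function(data, min_cells = 50) {
  stopifnot(inherits(data, "annotated_counts"))
  tab <- table(data$annotation$cell_type)
  kept <- sort(names(tab)[tab >= min_cells])
  if (length(kept) < 2) {
    stop_pitdeconv("need at least two cell types after the low-count exclusion.",
                   "pitdeconv_input_error")
  }
  ann <- data$annotation |> filter(.data$cell_type %in% kept)
  cpm <- cpm_normalize(data$counts[, ann$cell_id, drop = FALSE])
  subjects <- sort(unique(ann$subject))
  genes <- rownames(cpm)

  subject_means <- map(setNames(subjects, subjects), function(su) {
    m <- matrix(NA_real_, length(genes), length(kept),
                dimnames = list(genes, kept))
    for (tp in kept) {
      cells <- ann$cell_id[ann$subject == su & ann$cell_type == tp]
      if (length(cells) > 0) {
        m[, tp] <- rowMeans(cpm[, cells, drop = FALSE])
      }
    }
    m
  })

  cell_counts <- vapply(kept, function(tp) {
    vapply(subjects, function(su) {
      sum(ann$subject == su & ann$cell_type == tp)
    }, numeric(1))
  }, numeric(length(subjects)))
  cell_counts <- matrix(cell_counts, nrow = length(subjects),
                        dimnames = list(subjects, kept))

  mean_profiles <- matrix(0, length(genes), length(kept),
                          dimnames = list(genes, kept))
  var_gt <- mean_profiles
  for (tp in kept) {
    mat <- vapply(subject_means, function(m) m[, tp], numeric(length(genes)))
    mat <- mat[, !apply(is.na(mat), 2, any), drop = FALSE]
    mean_profiles[, tp] <- rowMeans(mat)
    var_gt[, tp] <- if (ncol(mat) >= 2) row_vars(mat) else 0
  }

  size_factors <- vapply(kept, function(tp) {
    mean(ann$n_counts[ann$cell_type == tp])
  }, numeric(1))

  structure(
    list(mean_profiles = mean_profiles, subject_means = subject_means,
         var = var_gt, size_factors = size_factors,
         cell_counts = cell_counts, subjects = subjects, types = kept),
    class = "subject_profiles"
  )
}

#' @export
print.subject_profiles <- function(x, ...) {
  cat(sprintf("<subject_profiles> %d genes, %d types, %d subjects\n",
              nrow(x$mean_profiles), length(x$types), length(x$subjects)))
  invisible(x)
}

#' Deconvolution by iteratively reweighted non-negative least squares
#'
#' The multi-subject engine: the design matrix holds the across-subject mean
#' CPM profile of each type scaled by its cell size factor, so the fitted
#' non-negative coefficients are cell-count proportions after normalization.
#' Genes are weighted by the inverse cross-subject variance of the
#' reconstructed expression under the current proportion estimate
#' (`w_g = 1 / (eps + sigma2_g)`), down-weighting genes whose expected bulk
#' signal is inconsistent across donors; the NNLS fit and the weights are
#' alternated until the proportions move less than `tol` or `max_iter` is
#' reached. With a single subject (or zero cross-subject variance) this
#' reduces to plain NNLS.
#'
#' @param mixture Genes x samples CPM matrix (a [mixture_set()] is accepted).
#' @param profiles A [subject_profiles()] object.
#' @param tol Convergence tolerance on the maximum proportion change
#'   (default 1e-6).
#' @param max_iter Maximum number of reweighting iterations (default 100).
#' @return A [deconv_result()]; non-converged samples are flagged in
#'   `stats$converged`.
#' @export
wnnls_deconvolve <- function(mixture, profiles, tol = 1e-6, max_iter = 100) {
  if (inherits(mixture, "mixture_set")) mixture <- mixture$mixtures
  mixture <- check_expression_matrix(mixture, "mixture")
  stopifnot(inherits(profiles, "subject_profiles"))

  shared <- intersect(rownames(mixture), rownames(profiles$mean_profiles))
  if (length(shared) < 2) {
    stop_pitdeconv("fewer than 2 genes shared between mixture and profiles.",
                   "pitdeconv_shared_genes_error")
  }
  M <- mixture[shared, , drop = FALSE]
  K <- length(profiles$types)
  sf <- profiles$size_factors
  D <- sweep(profiles$mean_profiles[shared, , drop = FALSE], 2, sf, "*")

  n_subj <- length(profiles$subjects)
  single_subject <- n_subj < 2
  if (single_subject) {
    warn("wnnls_deconvolve: single subject; falling back to unweighted NNLS.")
  }
  # per-subject designs for the variance of the reconstruction; a subject
  # missing a type contributes the across-subject mean profile for it
  D_subj <- map(profiles$subject_means, function(m) {
    m <- m[shared, , drop = FALSE]
    miss <- apply(is.na(m), 2, any)
    if (any(miss)) {
      m[, miss] <- profiles$mean_profiles[shared, miss, drop = FALSE]
    }
    sweep(m, 2, sf, "*")
  })

  # column scaling for numerical conditioning; undone on the coefficients
  col_scale <- apply(D, 2, function(x) max(x, 1e-12))

  nnls_fit <- function(A, b) {
    as.vector(pracma::lsqnonneg(A, b)$x)
  }

  S <- ncol(M)
  props <- matrix(0, S, K, dimnames = list(colnames(M), profiles$types))
  rmse <- r_fit <- numeric(S)
  converged <- logical(S)

  for (s in seq_len(S)) {
    y <- M[, s]
    Dsc <- sweep(D, 2, col_scale, "/")
    beta <- nnls_fit(Dsc, y) / col_scale
    p <- if (sum(beta) > 0) beta / sum(beta) else rep(1 / K, K)
    ok <- single_subject
    if (!single_subject) {
      for (it in seq_len(max_iter)) {
        recon_subj <- vapply(D_subj, function(Ds) as.vector(Ds %*% p),
                             numeric(length(shared)))
        sigma2 <- row_vars(recon_subj)
        eps <- 1e-8 * mean(sigma2)
        if (mean(sigma2) == 0) { ok <- TRUE; break }
        w <- 1 / (eps + sigma2)
        sw <- sqrt(w / mean(w))
        beta <- nnls_fit(sweep(Dsc, 1, sw, "*"), y * sw) / col_scale
        p_new <- if (sum(beta) > 0) beta / sum(beta) else rep(1 / K, K)
        delta <- max(abs(p_new - p))
        p <- p_new
        if (delta < tol) { ok <- TRUE; break }
      }
    } else {
      ok <- TRUE
    }
    props[s, ] <- p
    recon <- as.vector(D %*% beta)
    rmse[s] <- sqrt(mean((recon - y)^2))
    r_fit[s] <- suppressWarnings(cor(recon, y))
    converged[s] <- ok
  }

  if (any(!converged)) {
    warn(sprintf(
      "wnnls_deconvolve: %d/%d sample(s) hit max_iter (%d) before the proportion change fell below tol; last iterates returned, flagged in stats$converged.",
      sum(!converged), S, max_iter
    ))
  }

  deconv_result(
    props,
    tibble(sample = colnames(M), rmse = rmse, pearson_r = r_fit,
           p_value = NA_real_, converged = converged),
    engine = "wnnls",
    signature_id = sprintf("subjects=%d", n_subj)
  )
}
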