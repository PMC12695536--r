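#' Pseudobulk mixture container
#'
#' @param mixtures Genes x samples CPM matrix.
#' @param true_proportions Samples x types matrix of fractions, rows summing
#'   to 1 (within 1e-9).
#' @param provenance Tibble (`sample`, `cell_id`, `cell_type`) of the cells
#'   summed into each sample.
#' @param seed Seed used to generate the set.
#' @return A `mixture_set` object.
#' @export
mixture_set <- function(mixtures, true_proportions, provenance = NULL,
                        seed = NA_integer_) {
  mixtures <- check_expression_matrix(mixtures, "mixtures")
  true_proportions <- as.matrix(true_proportions)
  if (nrow(true_proportions) != ncol(mixtures)) {
    stop_pitdeconv("one proportion row per mixture column is required.",
                   "pitdeconv_input_error")
  }
  if (any(true_proportions < 0) ||
      any(abs(rowSums(true_proportions) - 1) > 1e-9)) {
    stop_pitdeconv("true proportions must be non-negative rows summing to 1.",
                   "pitdeconv_input_error")
  }
  structure(
    list(mixtures = mixtures, true_proportions = true_proportions,
         provenance = provenance, seed = seed),
    class = "mixture_set"
  )
}

#' @export
print.mixture_set <- function(x, ...) {
  cat(sprintf("<mixture_set> %d genes x %d samples, %d cell types\n",
              nrow(x$mixtures), ncol(x$mixtures),
              ncol(x$true_proportions)))
  invisible(x)
}

#' Simulate pseudobulk mixtures with known composition
#'
#' Random-mixing scheme: for each sample a proportion vector is drawn
#' uniformly on the simplex over the reference's cell types (flat Dirichlet),
#' `cells_per_sample` cells are allocated multinomially, drawn with
#' replacement within type, and their raw counts summed and CPM-normalized.
#' No per-cell scaling factor is applied. True proportions are the
#' allocated-cell-count fractions. The defaults (150 samples of 500 cells)
#' are the standard benchmarking scenario.
#'
#' @param data An [annotated_counts()] reference.
#' @param n_samples Number of pseudobulk samples (default 150).
#' @param cells_per_sample Cells summed per sample (default 500).
#' @param seed Integer seed; the whole [mixture_set()] is reproducible from it.
#' @return A [mixture_set()].
#' @export
simulate_pseudobulk <- function(data, n_samples = 150, cells_per_sample = 500,
                                seed = 1L) {
  stopifnot(inherits(data, "annotated_counts"))
  check_scalar_number(n_samples, "n_samples", lower = 1, integerish = TRUE)
  check_scalar_number(cells_per_sample, "cells_per_sample", lower = 1,
                      integerish = TRUE)
  types <- sort(unique(data$annotation$cell_type))
  cells_by_type <- split(data$annotation$cell_id, data$annotation$cell_type)

  withr::with_seed(as.integer(seed), {
    K <- length(types)
    mix <- matrix(0, nrow = nrow(data$counts), ncol = n_samples,
                  dimnames = list(rownames(data$counts),
                                  sprintf("pb%03d", seq_len(n_samples))))
    props <- matrix(0, nrow = n_samples, ncol = K,
                    dimnames = list(colnames(mix), types))
    prov <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      # flat Dirichlet via normalized unit-rate gammas
      alpha <- rgamma(K, shape = 1)
      p <- alpha / sum(alpha)
      alloc <- as.vector(rmultinom(1, size = cells_per_sample, prob = p))
      picked <- unlist(map(seq_len(K), function(k) {
        if (alloc[k] == 0) return(character())
        sample(cells_by_type[[types[k]]], alloc[k], replace = TRUE)
      }))
      mix[, s] <- rowSums(data$counts[, picked, drop = FALSE])
      props[s, ] <- alloc / cells_per_sample
      prov[[s]] <- tibble(
        sample = colnames(mix)[s],
        cell_id = picked,
        cell_type = rep(types, alloc)
      )
    }
    mixture_set(cpm_normalize(mix), props,
                provenance = list_rbind(prov), seed = as.integer(seed))
  })
}

#' Pseudobulk from an explicit cell-to-sample assignment
#'
#' Sums the raw counts of the cells assigned to each sample, CPM-normalizes,
#' and records true proportions as the labelled cell-type fractions per
#' sample. Used to turn annotated tumor single-cell datasets into
#' ground-truth bulk profiles.
#'
#' @param data An [annotated_counts()] object.
#' @param assignment Named character vector mapping `cell_id` to sample id.
#' @return A [mixture_set()].
#' @export
pseudobulk_from_labels <- function(data, assignment) {
  stopifnot(inherits(data, "annotated_counts"))
  missing_cells <- setdiff(names(assignment), data$annotation$cell_id)
  if (length(missing_cells) > 0) {
    stop_pitdeconv(
      paste0("assignment names unknown cell(s): ",
             paste(head(missing_cells, 5), collapse = ", ")),
      "pitdeconv_input_error"
    )
  }
  samples <- sort(unique(unname(assignment)))
  if (length(assignment) == 0) {
    stop_pitdeconv("empty assignment.", "pitdeconv_input_error")
  }
  types <- sort(unique(data$annotation$cell_type))
  type_of <- setNames(data$annotation$cell_type, data$annotation$cell_id)

  mix <- matrix(0, nrow = nrow(data$counts), ncol = length(samples),
                dimnames = list(rownames(data$counts), samples))
  props <- matrix(0, nrow = length(samples), ncol = length(types),
                  dimnames = list(samples, types))
  prov <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    cells <- names(assignment)[assignment == samples[i]]
    if (length(cells) == 0) {
      stop_pitdeconv(sprintf("sample '%s' has no assigned cells.", samples[i]),
                     "pitdeconv_input_error")
    }
    mix[, i] <- rowSums(data$counts[, cells, drop = FALSE])
    tt <- table(factor(type_of[cells], levels = types))
    props[i, ] <- as.numeric(tt) / length(cells)
    prov[[i]] <- tibble(sample = samples[i], cell_id = cells,
                        cell_type = unname(type_of[cells]))
  }
  mixture_set(cpm_normalize(mix), props, provenance = list_rbind(prov))
}

#' @rdname tidy.deconv_result
#' @export
tidy.mixture_set <- function(x, ...) {
  as_tibble(x$true_proportions, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "cell_type",
                        values_to = "true_proportion")
}
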