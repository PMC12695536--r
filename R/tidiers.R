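#' Tidy and summarize deconvolution objects
#'
#' `tidy()` methods return long tibbles ready for dplyr/ggplot2; `glance()`
#' methods return one-row summaries.
#'
#' @param x A `deconv_result`, `mixture_set` or `signature_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.deconv_result <- function(x, ...) {
  as_tibble(x$proportions, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "cell_type",
                        values_to = "proportion") |>
    mutate(engine = x$engine, signature = x$signature_id)
}

#' @rdname tidy.deconv_result
#' @export
glance.deconv_result <- function(x, ...) {
  tibble(
    engine = x$engine,
    signature = x$signature_id,
    n_samples = nrow(x$proportions),
    n_types = ncol(x$proportions),
    mean_rmse = mean(x$stats$rmse),
    mean_r = mean(x$stats$pearson_r),
    prop_converged = mean(x$stats$converged)
  )
}

#' @rdname tidy.deconv_result
#' @export
tidy.signature_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell_type",
                        values_to = "mean_cpm")
  member_tbl <- imap(x$members, function(genes, tp) {
    tibble(gene = genes, cell_type = tp, member = TRUE)
  }) |> list_rbind()
  long |>
    left_join(member_tbl, by = c("gene", "cell_type")) |>
    mutate(member = !is.na(.data$member))
}

#' @rdname tidy.deconv_result
#' @export
glance.signature_matrix <- function(x, ...) {
  tibble(
    id = x$id,
    ges_size = x$n,
    n_genes = nrow(x$values),
    n_types = ncol(x$values),
    condition_number = kappa(x$values, exact = TRUE)
  )
}

#' Join estimated and true proportions in long format
#'
#' @param mixtures A [mixture_set()].
#' @param result A [deconv_result()] on the same samples.
#' @return Tibble: `sample`, `cell_type`, `true_proportion`, `proportion`,
#'   `engine`, `signature`.
#' @export
proportions_vs_truth <- function(mixtures, result) {
  stopifnot(inherits(mixtures, "mixture_set"),
            inherits(result, "deconv_result"))
  dplyr::inner_join(
    tidy(mixtures), tidy(result),
    by = c("sample", "cell_type")
  )
}
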