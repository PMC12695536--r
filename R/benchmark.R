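#' Validate estimated proportions against ground truth
#'
#' Per cell type, computes the Pearson correlation between true and estimated
#' proportions across samples together with its two-sided p-value, and flags
#' the type as validated when `r > 0.70` and `p < 0.05` (the standard
#' robustness rule for deconvolution benchmarks). Types present in the truth
#' but absent from the estimate (e.g. excluded from a signature) are reported
#' with reason `"absent"`; types where either vector is constant get reason
#' `"degenerate"`; both are never validated.
#'
#' @param truth Samples x types matrix of true proportions, or a
#'   [mixture_set()].
#' @param estimated Samples x types matrix, or a [deconv_result()].
#' @param r_threshold Validation bound on r (default 0.70, exclusive).
#' @param p_threshold Validation bound on the p-value (default 0.05,
#'   exclusive).
#' @return A `validation_report` tibble: `cell_type`, `pearson_r`, `p_value`,
#'   `n_samples`, `validated`, `reason`.
#' @export
evaluate_deconv <- function(truth, estimated, r_threshold = 0.70,
                            p_threshold = 0.05) {
  if (inherits(truth, "mixture_set")) truth <- truth$true_proportions
  if (inherits(estimated, "deconv_result")) estimated <- estimated$proportions
  truth <- as.matrix(truth)
  estimated <- as.matrix(estimated)

  if (is.null(rownames(truth)) || is.null(rownames(estimated))) {
    stop_pitdeconv("both matrices need sample rownames.",
                   "pitdeconv_input_error")
  }
  missing_samples <- setdiff(rownames(truth), rownames(estimated))
  if (length(missing_samples) > 0) {
    stop_pitdeconv(
      paste0("samples missing from the estimate: ",
             paste(head(missing_samples, 5), collapse = ", ")),
      "pitdeconv_axis_error"
    )
  }
  estimated <- estimated[rownames(truth), , drop = FALSE]

  types <- colnames(truth)
  extra <- setdiff(colnames(estimated), types)
  if (length(extra) > 0) {
    warn(paste0("estimated types not present in the truth (ignored): ",
                paste(extra, collapse = ", ")))
  }

  rows <- map(types, function(tp) {
    S <- nrow(truth)
    if (!tp %in% colnames(estimated)) {
      return(tibble(cell_type = tp, pearson_r = NA_real_,
                    p_value = NA_real_, n_samples = S,
                    validated = FALSE, reason = "absent"))
    }
    x <- truth[, tp]
    y <- estimated[, tp]
    if (sd(x) == 0 || sd(y) == 0 || S < 3) {
      return(tibble(cell_type = tp, pearson_r = NA_real_,
                    p_value = NA_real_, n_samples = S,
                    validated = FALSE, reason = "degenerate"))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    validated <- is.finite(ct$estimate) &&
      ct$estimate > r_threshold && ct$p.value < p_threshold
    tibble(cell_type = tp, pearson_r = unname(ct$estimate),
           p_value = ct$p.value, n_samples = S,
           validated = validated, reason = "ok")
  })
  out <- list_rbind(rows)
  class(out) <- c("validation_report", class(out))
  out
}

#' Run several engine/signature combinations on one mixture set
#'
#' Every run is one entry of `runs`: a list with `engine = "svr"` (plus
#' `signature`, optional `cfg`, `seed`) or `engine = "wnnls"` (plus
#' `profiles`, optional `tol`, `max_iter`). Failures are recorded per run
#' with reason `"error: <message>"` and the benchmark continues.
#'
#' @param mixtures A [mixture_set()].
#' @param runs Named list of run descriptions (names become the `run` column).
#' @param r_threshold,p_threshold Validation bounds, as in
#'   [evaluate_deconv()].
#' @return A `benchmark_report` tibble in long format: `run`, `engine`,
#'   `signature`, `cell_type`, `pearson_r`, `p_value`, `n_samples`,
#'   `validated`, `reason`.
#' @export
benchmark_engines <- function(mixtures, runs, r_threshold = 0.70,
                              p_threshold = 0.05) {
  stopifnot(inherits(mixtures, "mixture_set"))
  if (is.null(names(runs)) || any(names(runs) == "")) {
    stop_pitdeconv("`runs` must be a fully named list.",
                   "pitdeconv_config_error")
  }
  types <- colnames(mixtures$true_proportions)

  out <- imap(runs, function(spec, run_name) {
    res <- tryCatch(
      {
        fit <- switch(
          spec$engine,
          svr = svr_deconvolve(mixtures, spec$signature,
                               cfg = spec$cfg %||% svr_config(),
                               seed = spec$seed %||% 1L),
          wnnls = wnnls_deconvolve(mixtures, spec$profiles,
                                   tol = spec$tol %||% 1e-6,
                                   max_iter = spec$max_iter %||% 100),
          stop_pitdeconv(sprintf("unknown engine '%s'.", spec$engine),
                         "pitdeconv_config_error")
        )
        rep <- evaluate_deconv(mixtures, fit, r_threshold = r_threshold,
                               p_threshold = p_threshold)
        rep$signature <- if (spec$engine == "svr") {
          fit$signature_id %||% NA_character_
        } else {
          fit$signature_id
        }
        rep
      },
      error = function(e) {
        tibble(cell_type = types, pearson_r = NA_real_, p_value = NA_real_,
               n_samples = ncol(mixtures$mixtures), validated = FALSE,
               reason = paste0("error: ", conditionMessage(e)),
               signature = NA_character_)
      }
    )
    res$run <- run_name
    res$engine <- spec$engine
    res
  })
  out <- list_rbind(out) |>
    select("run", "engine", "signature", "cell_type", "pearson_r",
           "p_value", "n_samples", "validated", "reason")
  class(out) <- c("benchmark_report", class(out))
  out
}

#' @rdname evaluate_deconv
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
glance.validation_report <- function(x, ...) {
  tibble(
    n_types = nrow(x),
    n_validated = sum(x$validated),
    median_r = stats::median(x$pearson_r, na.rm = TRUE),
    min_r = suppressWarnings(min(x$pearson_r, na.rm = TRUE))
  )
}

#' @rdname benchmark_engines
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @export
glance.benchmark_report <- function(x, ...) {
  x |>
    group_by(.data$run, .data$engine) |>
    summarise(
      n_types = n(),
      n_validated = sum(.data$validated),
      median_r = stats::median(.data$pearson_r, na.rm = TRUE),
      .groups = "drop"
    )
}
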