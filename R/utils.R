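# Internal validators shared across modules. All user-facing errors are
# rlang conditions with a class so callers can test for them.

stop_pitdeconv <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "pitdeconv_error"), ...)
}

# A genes x columns expression matrix: numeric, non-negative, with rownames.
check_expression_matrix <- function(x, arg = "x", allow_missing_colnames = TRUE) {
  if (inherits(x, "sparseMatrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_pitdeconv(
      sprintf("`%s` must be a numeric genes x columns matrix.", arg),
      "pitdeconv_input_error"
    )
  }
  if (is.null(rownames(x))) {
    stop_pitdeconv(
      sprintf("`%s` must have gene identifiers as rownames.", arg),
      "pitdeconv_input_error"
    )
  }
  if (anyNA(x) || any(x < 0)) {
    stop_pitdeconv(
      sprintf("`%s` must be non-negative with no missing values.", arg),
      "pitdeconv_input_error"
    )
  }
  x
}

# Like check_expression_matrix but allows negative values (log scale,
# batch-adjusted residuals).
check_numeric_matrix <- function(x, arg = "x") {
  if (inherits(x, "sparseMatrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x)) {
    stop_pitdeconv(
      sprintf("`%s` must be a numeric matrix with no missing values.", arg),
      "pitdeconv_input_error"
    )
  }
  if (is.null(rownames(x))) {
    stop_pitdeconv(
      sprintf("`%s` must have gene identifiers as rownames.", arg),
      "pitdeconv_input_error"
    )
  }
  x
}

check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf,
                                integerish = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= lower && x <= upper && (!integerish || x == round(x))
  if (!ok) {
    stop_pitdeconv(
      sprintf(
        "`%s` must be a single %s in [%s, %s]; got %s.",
        arg, if (integerish) "integer" else "number",
        format(lower), format(upper), paste(format(x), collapse = ", ")
      ),
      "pitdeconv_config_error"
    )
  }
  invisible(x)
}

# Column-variance helpers kept base-R for speed on dense matrices.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(setNames(rep(0, nrow(m)), rownames(m)))
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}

`%||%` <- rlang::`%||%`
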