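#' Quality-control thresholds for single-cell filtering
#'
#' All bounds are strict inequalities: a cell is retained when
#' `min_features < n_features < max_features`, `n_counts > min_counts` and
#' `pct_mito < max_mito`. Defaults are the standard droplet-data thresholds
#' for nuclear pituitary data: 1,000 < detected genes < 5,000, more than 200
#' total counts, and under 5% mitochondrial content.
#'
#' @param min_features,max_features Exclusive bounds on genes detected per cell.
#' @param min_counts Exclusive lower bound on total counts per cell.
#' @param max_mito Exclusive upper bound on the mitochondrial count fraction.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_features = 1000, max_features = 5000,
                          min_counts = 200, max_mito = 0.05) {
  if (!(min_features < max_features)) {
    stop_pitdeconv("`min_features` must be below `max_features`.",
                   "pitdeconv_config_error")
  }
  check_scalar_number(max_mito, "max_mito", lower = 0, upper = 1)
  structure(
    list(min_features = min_features, max_features = max_features,
         min_counts = min_counts, max_mito = max_mito),
    class = "qc_thresholds"
  )
}

#' Filter low-quality cells
#'
#' Applies [qc_thresholds()] with strict inequalities and reports how many
#' cells each criterion removed. Metrics are recomputed from the count matrix
#' so stale annotation can never leak through. Idempotent.
#'
#' @param data An [annotated_counts()] object.
#' @param thr A [qc_thresholds()] object.
#' @return The filtered [annotated_counts()]; empty (0 cells) with a warning
#'   if nothing survives.
#' @export
qc_filter <- function(data, thr = qc_thresholds()) {
  stopifnot(inherits(data, "annotated_counts"))
  ann <- recompute_qc_metrics(data$counts, data$annotation, data$mito_genes)

  pass_feat <- ann$n_features > thr$min_features &
    ann$n_features < thr$max_features
  pass_counts <- ann$n_counts > thr$min_counts
  pass_mito <- ann$pct_mito < thr$max_mito
  keep <- pass_feat & pass_counts & pass_mito

  inform(sprintf(
    "qc_filter: %d/%d cells retained (removed: %d by feature bounds, %d by count bound, %d by mito bound)",
    sum(keep), length(keep), sum(!pass_feat), sum(!pass_counts),
    sum(!pass_mito)
  ))
  if (!any(keep)) {
    warn("qc_filter removed every cell; returning an empty reference.")
  }
  annotated_counts(
    data$counts[, keep, drop = FALSE],
    ann[keep, , drop = FALSE],
    mito_genes = data$mito_genes,
    marker_truth = data$marker_truth
  )
}

#' Counts-per-million normalization
#'
#' Scales each column to a total of one million. Used both for the
#' single-cell reference and for bulk counts ([bulk_cpm()] is an alias with
#' the bulk-side contract).
#'
#' @param counts Genes x columns non-negative matrix.
#' @return Matrix of the same shape on the CPM scale.
#' @export
cpm_normalize <- function(counts) {
  counts <- check_expression_matrix(counts, "counts")
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0] %||% which(cs == 0)
    stop_pitdeconv(
      paste0("zero-sum column(s) cannot be CPM-normalized: ",
             paste(utils::head(bad, 5), collapse = ", ")),
      "pitdeconv_zero_column_error"
    )
  }
  sweep(counts, 2, cs, "/") * 1e6
}

#' Log(x + 1) transformation
#'
#' @param cpm Non-negative matrix (CPM scale by convention).
#' @param base `"e"` for the natural log (reference preparation) or `"10"`
#'   (bulk marker heatmap scale).
#' @return Element-wise `log(x + 1)` in the requested base.
#' @export
log_transform <- function(cpm, base = c("e", "10")) {
  base <- match.arg(base)
  if (anyNA(cpm) || any(cpm < 0)) {
    stop_pitdeconv("log_transform requires non-negative input.",
                   "pitdeconv_input_error")
  }
  if (base == "e") log1p(cpm) else log10(cpm + 1)
}

#' Mean CPM profile per cell type
#'
#' @param cpm Genes x cells CPM matrix.
#' @param cell_types Character vector of labels, one per column.
#' @return Genes x types matrix of per-type mean CPM.
#' @export
type_profiles <- function(cpm, cell_types) {
  cpm <- check_expression_matrix(cpm, "cpm")
  stopifnot(length(cell_types) == ncol(cpm))
  types <- sort(unique(as.character(cell_types)))
  out <- vapply(types, function(tp) {
    rowMeans(cpm[, cell_types == tp, drop = FALSE])
  }, numeric(nrow(cpm)))
  rownames(out) <- rownames(cpm)
  out
}

# Vectorized bimodal likelihood over genes (rows): expression is a point mass
# at zero with probability 1 - pi plus a normal on the nonzero values; pi is
# clamped to [1e-5, 1 - 1e-5] and the normal SD falls back to 1 when fewer
# than two nonzero values exist (the upstream single-cell DE convention).
bimod_loglik <- function(x) {
  n <- ncol(x)
  pos <- x > 0
  n1 <- rowSums(pos)
  n0 <- n - n1
  pi_hat <- pmin(pmax(n1 / n, 1e-5), 1 - 1e-5)
  s1 <- rowSums(x * pos)
  s2 <- rowSums(x^2 * pos)
  mu <- ifelse(n1 > 0, s1 / n1, 0)
  ss <- pmax(s2 - n1 * mu^2, 0)
  sdv <- ifelse(n1 >= 2, sqrt(ss / pmax(n1 - 1, 1)), 1)
  sdv[sdv == 0] <- 1e-8  # degenerate nonzero values; matches sd() -> 0 guard
  lik0 <- n0 * log(1 - pi_hat)
  lik1 <- n1 * log(pi_hat) -
    n1 / 2 * log(2 * pi) - n1 * log(sdv) - ss / (2 * sdv^2)
  lik1[n1 == 0] <- 0
  lik0 + lik1
}

#' One-vs-rest marker detection with the bimodal likelihood-ratio test
#'
#' For each cell type, genes detected in at least `min_pct` of cells in the
#' type or in the rest are tested with the bimodal LRT used by single-cell DE
#' tools: per group a zero point mass with probability `1 - pi` plus a normal
#' on the nonzero natural-log CPM values; the statistic
#' `2 (l_type + l_rest - l_pooled)` is referred to a chi-squared distribution
#' with 3 degrees of freedom. `logFC` is the natural-log ratio of
#' `(mean CPM + 1)` between the type and the rest; `adj_p` is Bonferroni over
#' all genes in the matrix (per type tested).
#'
#' @param cpm Genes x cells CPM matrix.
#' @param cell_types Labels, one per column.
#' @param min_pct Minimum detection fraction in at least one group for a gene
#'   to be tested (default 0.25).
#' @param min_cells Cell types with fewer cells than this are dropped before
#'   testing (default 50, the usual low-representation exclusion).
#' @param adjust Multiple-testing adjustment, `"bonferroni"` (default,
#'   matching the upstream tool) or any method of [stats::p.adjust()].
#' @return A tibble (`cell_type`, `gene`, `p_value`, `adj_p`, `logFC`,
#'   `pct_in`, `pct_out`, `mean_cpm_in`), one row per tested (type, gene).
#' @export
find_markers <- function(cpm, cell_types, min_pct = 0.25, min_cells = 50,
                         adjust = "bonferroni") {
  cpm <- check_expression_matrix(cpm, "cpm")
  cell_types <- as.character(cell_types)
  stopifnot(length(cell_types) == ncol(cpm))

  tab <- table(cell_types)
  kept <- names(tab)[tab >= min_cells]
  dropped <- setdiff(names(tab), kept)
  if (length(dropped) > 0) {
    inform(paste0(
      "find_markers: dropping low-representation type(s) (<", min_cells,
      " cells): ", paste(dropped, collapse = ", ")
    ))
  }
  if (length(kept) < 2) {
    stop_pitdeconv("need at least two cell types with enough cells.",
                   "pitdeconv_input_error")
  }
  in_scope <- cell_types %in% kept
  cpm <- cpm[, in_scope, drop = FALSE]
  cell_types <- cell_types[in_scope]

  logx <- log1p(cpm)
  n_genes <- nrow(cpm)

  res <- map(sort(kept), function(tp) {
    grp <- cell_types == tp
    x_in <- logx[, grp, drop = FALSE]
    x_out <- logx[, !grp, drop = FALSE]
    pct_in <- rowMeans(x_in > 0)
    pct_out <- rowMeans(x_out > 0)
    testable <- pmax(pct_in, pct_out) >= min_pct
    if (!any(testable)) return(NULL)

    # group-specific fits vs a pooled fit over all cells
    lr <- 2 * (bimod_loglik(x_in[testable, , drop = FALSE]) +
                 bimod_loglik(x_out[testable, , drop = FALSE]) -
                 bimod_loglik(logx[testable, , drop = FALSE]))
    p <- pchisq(pmax(lr, 0), df = 3, lower.tail = FALSE)

    mean_in <- rowMeans(cpm[testable, grp, drop = FALSE])
    mean_out <- rowMeans(cpm[testable, !grp, drop = FALSE])

    tibble(
      cell_type = tp,
      gene = rownames(cpm)[testable],
      p_value = unname(p),
      adj_p = if (adjust == "bonferroni") {
        pmin(unname(p) * n_genes, 1)
      } else {
        p.adjust(unname(p), method = adjust)
      },
      logFC = log((mean_in + 1) / (mean_out + 1)),
      pct_in = unname(pct_in[testable]),
      pct_out = unname(pct_out[testable]),
      mean_cpm_in = unname(mean_in)
    )
  })
  list_rbind(res)
}

#' Signature (GES) matrix container
#'
#' @param values Genes x types matrix of mean CPM.
#' @param members Named list (per type) of the genes selected for that type.
#' @param n The per-type GES size requested.
#' @param id Optional label (e.g. `"GES300"`).
#' @return A `signature_matrix` object. Invariants: unique genes; every gene
#'   exceeds 1 CPM in at least one type; each member set has at most `n`
#'   genes, all present in the gene axis.
#' @export
signature_matrix <- function(values, members, n, id = NULL) {
  values <- check_expression_matrix(values, "values")
  if (anyDuplicated(rownames(values))) {
    stop_pitdeconv("signature gene axis contains duplicates.",
                   "pitdeconv_input_error")
  }
  if (ncol(values) < 2) {
    stop_pitdeconv("a signature needs at least two cell types.",
                   "pitdeconv_input_error")
  }
  stopifnot(is.list(members), all(names(members) %in% colnames(values)))
  bad <- setdiff(unlist(members), rownames(values))
  if (length(bad) > 0) {
    stop_pitdeconv("member genes missing from the signature gene axis.",
                   "pitdeconv_input_error")
  }
  structure(
    list(values = values, members = members, n = n,
         id = id %||% paste0("GES", n)),
    class = "signature_matrix"
  )
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix %s> %d genes x %d types\n",
              x$id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build a GES signature matrix from a marker table
#'
#' Per cell type, markers passing `adj_p <= alpha` and `logFC > logfc_min`
#' are ranked by within-type mean CPM (ties: smaller `adj_p`, then gene id)
#' and the top `n` taken (GES50 ... GES300). The union of the per-type sets
#' forms the gene axis; genes never exceeding `min_cpm` in any type are
#' dropped; values are the per-type mean CPM.
#'
#' @param markers Marker tibble from [find_markers()].
#' @param profiles Genes x types mean-CPM matrix from [type_profiles()].
#' @param n Per-type GES size (50, 100, 150, 200, 300, or any positive
#'   integer).
#' @param alpha Significance bound on `adj_p` (default 0.05).
#' @param logfc_min Exclusive lower bound on natural-log fold change
#'   (default 1).
#' @param min_cpm A gene must exceed this CPM in at least one type to stay in
#'   the signature (default 1).
#' @return A [signature_matrix()]. Types with no significant markers are kept
#'   with an empty member set, with a warning.
#' @export
build_ges <- function(markers, profiles, n, alpha = 0.05, logfc_min = 1,
                      min_cpm = 1) {
  check_scalar_number(n, "n", lower = 1, integerish = TRUE)
  profiles <- check_expression_matrix(profiles, "profiles")
  types <- intersect(colnames(profiles), unique(markers$cell_type))
  if (length(types) < 2) {
    stop_pitdeconv("need markers for at least two types present in `profiles`.",
                   "pitdeconv_input_error")
  }

  sig <- markers |>
    filter(.data$cell_type %in% types,
           .data$adj_p <= alpha, .data$logFC > logfc_min)

  members <- map(setNames(types, types), function(tp) {
    rows <- sig |>
      filter(.data$cell_type == tp) |>
      arrange(desc(.data$mean_cpm_in), .data$adj_p, .data$gene)
    head(rows$gene, n)
  })
  empty <- names(members)[lengths(members) == 0]
  if (length(empty) > 0) {
    warn(paste0("no significant markers for type(s): ",
                paste(empty, collapse = ", "),
                "; retained with empty member sets."))
  }

  genes <- sort(unique(unlist(members)))
  if (length(genes) == 0) {
    stop_pitdeconv("no significant markers for any type.",
                   "pitdeconv_input_error")
  }
  vals <- profiles[genes, types, drop = FALSE]
  keep <- apply(vals, 1, max) > min_cpm
  vals <- vals[keep, , drop = FALSE]
  members <- map(members, function(g) intersect(g, rownames(vals)))

  signature_matrix(vals, members, n = n)
}
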