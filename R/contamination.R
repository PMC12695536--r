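#' Lineage map: cell types to pituitary lineage classes
#'
#' Assigns every reference cell type to one of the lineage classes
#' `PIT1`, `TPIT`, `SF1`, `stem/progenitor`, `posterior`, `stromal`,
#' `immune`, and describes each histotype (tumor diagnosis) by its lineage
#' and tumor cell type(s). The partition drives
#' [contamination_score()]: anterior-pituitary endocrine signal outside the
#' tumor's lineage counts as residual normal tissue, stromal and immune
#' signal as tumor microenvironment.
#'
#' @param types Named character vector: cell type -> lineage class.
#' @param histotypes Tibble with columns `histotype`, `lineage`,
#'   `tumor_types` (list column of cell-type labels).
#' @param stem_as_same_lineage_pit1 Count stem/progenitor signal as
#'   same-lineage (not contamination) for PIT1 tumors; such signal in
#'   PIT1-lineage tumors typically reflects tumor-intrinsic reprogramming
#'   rather than entrapped normal tissue (default TRUE).
#' @return A `lineage_map` object.
#' @export
lineage_map <- function(types, histotypes,
                        stem_as_same_lineage_pit1 = TRUE) {
  classes <- c("PIT1", "TPIT", "SF1", "stem/progenitor", "posterior",
               "stromal", "immune")
  bad <- setdiff(unique(types), classes)
  if (length(bad) > 0) {
    stop_pitdeconv(
      paste0("unknown lineage class(es): ", paste(bad, collapse = ", ")),
      "pitdeconv_config_error"
    )
  }
  histotypes <- as_tibble(histotypes)
  stopifnot(all(c("histotype", "lineage", "tumor_types") %in%
                  names(histotypes)))
  endocrine <- names(types)[types %in% c("PIT1", "TPIT", "SF1")]
  not_endocrine <- setdiff(unlist(histotypes$tumor_types), endocrine)
  if (length(not_endocrine) > 0) {
    stop_pitdeconv(
      paste0("tumor type(s) must map to an endocrine lineage: ",
             paste(not_endocrine, collapse = ", ")),
      "pitdeconv_config_error"
    )
  }
  structure(
    list(types = types, histotypes = histotypes,
         stem_as_same_lineage_pit1 = isTRUE(stem_as_same_lineage_pit1)),
    class = "lineage_map"
  )
}

#' Default lineage map for the synthetic pituitary atlas
#'
#' @inheritParams lineage_map
#' @return A [lineage_map()] covering the 13 default cell types and the five
#'   hormone-secreting histotypes (GH, PRL, TSH, ACTH, FSH/LH).
#' @export
default_lineage_map <- function(stem_as_same_lineage_pit1 = TRUE) {
  types <- c(
    somatotroph = "PIT1", lactotroph = "PIT1", thyrotroph = "PIT1",
    gonadotroph = "SF1", corticotroph = "TPIT",
    stem_cell = "stem/progenitor", pro_pit1 = "stem/progenitor",
    endothelial = "stromal", fibroblast = "stromal",
    smooth_muscle = "stromal",
    macrophage = "immune", t_cell = "immune", nk_cell = "immune"
  )
  histotypes <- tibble(
    histotype = c("GH", "PRL", "TSH", "ACTH", "FSH/LH"),
    lineage = c("PIT1", "PIT1", "PIT1", "TPIT", "SF1"),
    tumor_types = list("somatotroph", "lactotroph", "thyrotroph",
                       "corticotroph", "gonadotroph")
  )
  lineage_map(types, histotypes, stem_as_same_lineage_pit1)
}

#' Bulk counts to CPM
#'
#' Column scaling of a raw bulk count matrix to counts per million; shares
#' its implementation (and error contract) with [cpm_normalize()].
#'
#' @param raw_counts Genes x samples non-negative count matrix.
#' @return CPM matrix of the same shape.
#' @export
bulk_cpm <- function(raw_counts) cpm_normalize(raw_counts)

#' Partition estimated proportions into tumor, residue and TME fractions
#'
#' For each sample, the estimated cell-type proportions are split into four
#' fractions that sum to one:
#' `tumor_fraction` (the histotype's tumor cell type(s)),
#' `same_lineage_fraction` (other endocrine types of the tumor's lineage,
#' plus stem/progenitor types for PIT1 tumors when the map says so),
#' `residual_normal_fraction` (endocrine types of other lineages, posterior
#' pituitary signal, and any stem/progenitor signal not counted as
#' same-lineage) and `tme_fraction` (stromal + immune). A sample is flagged
#' contaminated when its residual fraction reaches `flag_threshold`.
#'
#' @param proportions Samples x types matrix (or one-row matrix /
#'   [deconv_result()]).
#' @param histotype Histotype label, length 1 or one per sample.
#' @param map A [lineage_map()].
#' @param flag_threshold Contamination flag threshold on the residual
#'   fraction (default 0.20; a tool parameter, not a biological constant).
#' @return A `contamination_report` tibble: `sample`, `histotype`, the four
#'   fractions, `contaminated`.
#' @export
contamination_score <- function(proportions, histotype,
                                map = default_lineage_map(),
                                flag_threshold = 0.20) {
  if (inherits(proportions, "deconv_result")) {
    proportions <- proportions$proportions
  }
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions))) {
    rownames(proportions) <- sprintf("sample%03d", seq_len(nrow(proportions)))
  }
  S <- nrow(proportions)
  histotype <- rep_len(as.character(histotype), S)
  check_scalar_number(flag_threshold, "flag_threshold", lower = 0, upper = 1)

  unknown_types <- setdiff(colnames(proportions), names(map$types))
  if (length(unknown_types) > 0) {
    stop_pitdeconv(
      paste0("proportion column(s) missing from the lineage map: ",
             paste(unknown_types, collapse = ", ")),
      "pitdeconv_input_error"
    )
  }
  unknown_hist <- setdiff(unique(histotype), map$histotypes$histotype)
  if (length(unknown_hist) > 0) {
    stop_pitdeconv(
      paste0("histotype(s) missing from the lineage map: ",
             paste(unknown_hist, collapse = ", ")),
      "pitdeconv_input_error"
    )
  }

  lin <- map$types[colnames(proportions)]
  rows <- map(seq_len(S), function(s) {
    h <- map$histotypes[map$histotypes$histotype == histotype[s], ]
    tumor_types <- intersect(unlist(h$tumor_types), colnames(proportions))
    tumor_lineage <- h$lineage

    is_tumor <- colnames(proportions) %in% tumor_types
    is_tme <- lin %in% c("stromal", "immune")
    is_stem <- lin == "stem/progenitor"
    stem_same <- map$stem_as_same_lineage_pit1 && tumor_lineage == "PIT1"
    is_same <- (!is_tumor & lin == tumor_lineage) | (is_stem & stem_same)
    is_residual <- !is_tumor & !is_tme & !is_same

    p <- proportions[s, ]
    total <- sum(p)
    if (total <= 0) {
      stop_pitdeconv(sprintf("sample '%s' has zero total proportion.",
                             rownames(proportions)[s]),
                     "pitdeconv_input_error")
    }
    p <- p / total
    tibble(
      sample = rownames(proportions)[s],
      histotype = histotype[s],
      tumor_fraction = sum(p[is_tumor]),
      same_lineage_fraction = sum(p[is_same]),
      residual_normal_fraction = sum(p[is_residual]),
      tme_fraction = sum(p[is_tme])
    )
  })
  out <- list_rbind(rows) |>
    mutate(contaminated = .data$residual_normal_fraction >= flag_threshold)
  class(out) <- c("contamination_report", class(out))
  attr(out, "flag_threshold") <- flag_threshold
  out
}

#' @rdname contamination_score
#' @param x A `contamination_report`.
#' @param ... Unused.
#' @return `glance()`: one-row cohort summary — number of samples, number
#'   flagged, and mean and SD of the residual-normal fraction over the
#'   flagged samples.
#' @export
glance.contamination_report <- function(x, ...) {
  flagged <- x$residual_normal_fraction[x$contaminated]
  tibble(
    n_samples = nrow(x),
    n_contaminated = length(flagged),
    mean_contamination = if (length(flagged) > 0) mean(flagged) else NA_real_,
    sd_contamination = if (length(flagged) > 1) sd(flagged) else NA_real_
  )
}

#' Merge expression matrices across batches with location/scale adjustment
#'
#' Joins the matrices on their shared genes and, per gene, standardizes each
#' batch to the pooled mean and variance — a deliberate location/scale
#' simplification of empirical-Bayes batch correction that is adequate for
#' mean/variance batch shifts; `method = "combat"` delegates to
#' `sva::ComBat()` when finer control is needed. Batches of size 1 are only
#' re-centered, with a warning.
#'
#' @param matrices List of genes x samples log-CPM matrices (or a single
#'   merged matrix).
#' @param batches Batch label per matrix (recycled to samples), or per
#'   sample if a single matrix is given.
#' @param method `"scale"` (default) or `"combat"`.
#' @return Merged genes x samples matrix on the shared gene set.
#' @export
batch_adjust <- function(matrices, batches, method = c("scale", "combat")) {
  method <- match.arg(method)
  if (is.matrix(matrices)) {
    merged <- matrices
    batch <- rep_len(as.character(batches), ncol(merged))
  } else {
    stopifnot(is.list(matrices), length(matrices) == length(batches))
    shared <- Reduce(intersect, map(matrices, rownames))
    n_dropped <- max(map_dbl(matrices, nrow)) - length(shared)
    if (length(shared) < 2) {
      stop_pitdeconv("fewer than 2 genes shared across batches.",
                     "pitdeconv_input_error")
    }
    if (n_dropped > 0) {
      inform(sprintf("batch_adjust: %d gene(s) dropped by the inner join.",
                     n_dropped))
    }
    merged <- do.call(cbind, map(matrices, function(m) {
      m[shared, , drop = FALSE]
    }))
    batch <- rep(as.character(batches), map_dbl(matrices, ncol))
  }

  if (length(unique(batch)) == 1) return(merged)

  if (method == "combat") {
    if (!requireNamespace("sva", quietly = TRUE)) {
      stop_pitdeconv("method = 'combat' requires the sva package.",
                     "pitdeconv_config_error")
    }
    return(sva::ComBat(dat = merged, batch = batch))
  }

  pooled_mean <- rowMeans(merged)
  pooled_sd <- sqrt(row_vars(merged))
  out <- merged
  for (b in unique(batch)) {
    cols <- batch == b
    if (sum(cols) == 1) {
      # per-gene moments are not estimable from one sample: shift the whole
      # column so its grand mean matches the pooled grand mean, nothing else
      warn(sprintf("batch '%s' has a single sample; centered only.", b))
      out[, cols] <- merged[, cols] - mean(merged[, cols]) + mean(pooled_mean)
      next
    }
    m_b <- rowMeans(merged[, cols, drop = FALSE])
    sd_b <- sqrt(row_vars(merged[, cols, drop = FALSE]))
    scale_f <- ifelse(sd_b > 0 & pooled_sd > 0, pooled_sd / sd_b, 1)
    out[, cols] <- (merged[, cols, drop = FALSE] - m_b) * scale_f +
      pooled_mean
  }
  out
}

#' Select the most variable genes
#'
#' @param mat Genes x samples (log-CPM) matrix.
#' @param n Number of genes to keep (default 500), ranked by cross-sample
#'   variance, ties broken lexicographically by gene id.
#' @return Character vector of the selected gene ids.
#' @export
hvg_select <- function(mat, n = 500) {
  mat <- check_numeric_matrix(mat, "mat")
  check_scalar_number(n, "n", lower = 1, upper = nrow(mat),
                      integerish = TRUE)
  v <- row_vars(mat)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

#' Hierarchical clustering of samples
#'
#' Euclidean distances between sample columns (optionally restricted to a
#' gene subset), agglomerated with complete linkage.
#'
#' @param mat Genes x samples matrix (log-CPM).
#' @param genes Optional gene subset (e.g. from [hvg_select()]).
#' @return An [stats::hclust] object over samples.
#' @export
hclust_samples <- function(mat, genes = NULL) {
  mat <- check_numeric_matrix(mat, "mat")
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  if (ncol(mat) < 2) {
    stop_pitdeconv("need at least 2 samples to cluster.",
                   "pitdeconv_input_error")
  }
  hclust(dist(t(mat), method = "euclidean"), method = "complete")
}

#' Flag samples discordant with their annotated lineage
#'
#' Cuts the sample dendrogram into `k` clusters and flags the two cluster
#' patterns that betray residual tissue from another lineage: a sample whose
#' cluster is dominated by a different lineage (or has no > 50% majority at
#' all), and a sample that falls outside its own lineage's main cluster —
#' the "distinct group" pattern, where contaminated samples split away from
#' the bulk of their histological peers. A lineage's main cluster is the
#' cluster holding the plurality of that lineage's samples (ties broken
#' toward the lower cluster index).
#'
#' @param hc An [stats::hclust] over samples (e.g. from [hclust_samples()]).
#' @param lineages Named character vector: sample -> annotated lineage (or
#'   unnamed, in dendrogram label order).
#' @param k Number of clusters to cut; should be at least the number of
#'   distinct lineages.
#' @return Tibble: `sample`, `lineage`, `cluster`, `cluster_majority`
#'   (NA when no majority), `in_main_cluster`, `flagged`.
#' @export
flag_discordant <- function(hc, lineages, k) {
  stopifnot(inherits(hc, "hclust"))
  check_scalar_number(k, "k", lower = 1, upper = length(hc$labels),
                      integerish = TRUE)
  if (is.null(names(lineages))) {
    stopifnot(length(lineages) == length(hc$labels))
    names(lineages) <- hc$labels
  }
  missing_samples <- setdiff(hc$labels, names(lineages))
  if (length(missing_samples) > 0) {
    stop_pitdeconv(
      paste0("no lineage annotation for sample(s): ",
             paste(head(missing_samples, 5), collapse = ", ")),
      "pitdeconv_input_error"
    )
  }
  if (k < length(unique(lineages[hc$labels]))) {
    warn("k is below the number of distinct lineages; clusters must mix lineages.")
  }
  cl <- cutree(hc, k = k)
  out <- tibble(
    sample = hc$labels,
    lineage = unname(lineages[hc$labels]),
    cluster = unname(cl[hc$labels])
  )
  maj <- out |>
    group_by(.data$cluster) |>
    summarise(
      cluster_majority = {
        tt <- table(.data$lineage)
        if (max(tt) > sum(tt) / 2) names(tt)[which.max(tt)] else NA_character_
      },
      .groups = "drop"
    )
  # the cluster holding the plurality of each lineage's samples
  main <- out |>
    dplyr::count(.data$lineage, .data$cluster) |>
    arrange(.data$lineage, desc(.data$n), .data$cluster) |>
    group_by(.data$lineage) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("lineage", main_cluster = "cluster")
  out <- out |>
    left_join(maj, by = "cluster") |>
    left_join(main, by = "lineage") |>
    mutate(
      in_main_cluster = .data$cluster == .data$main_cluster,
      flagged = is.na(.data$cluster_majority) |
        .data$cluster_majority != .data$lineage |
        !.data$in_main_cluster
    ) |>
    select(-"main_cluster")
  out
}
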