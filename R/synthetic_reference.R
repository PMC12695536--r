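#' Configuration for the synthetic single-nucleus pituitary reference
#'
#' Describes a scaled-down normal-pituitary atlas: a fixed roster of cell
#' types (endocrine, stromal, immune), disjoint blocks of marker genes
#' enriched `marker_fold`-fold in their own type, log-normal donor effects
#' shared by all cells of a subject, and negative-binomial UMI counts with
#' per-cell library sizes. The defaults emulate an anterior-pituitary
#' single-nucleus dataset: seven endocrine populations (the five
#' hormone-secreting types plus stem cells and PIT1-lineage progenitors),
#' three stromal and three immune populations, with immune cells at low
#' abundance and one immune population rare enough to fall under the usual
#' 50-cell exclusion applied before signature construction.
#'
#' @param n_types Number of cell types (>= 2). If `type_names` is supplied its
#'   length wins.
#' @param type_names Character vector of type labels.
#' @param type_classes Character vector, one of `"endocrine"`, `"stromal"`,
#'   `"immune"` per type.
#' @param n_genes Total number of genes simulated.
#' @param markers_per_type Size of each type's disjoint marker block;
#'   `markers_per_type * n_types` must not exceed `n_genes` (a further small
#'   set of genes is reserved as mitochondrial and never used as markers).
#' @param cells_per_type Integer vector (length 1 or `n_types`) of cells to
#'   draw per type.
#' @param n_subjects Number of donors; cells are spread evenly across donors.
#' @param marker_fold Fold-change of marker genes in their own type (> 1 for a
#'   real signal; exactly 1 simulates a marker-free null).
#' @param nb_dispersion Negative-binomial dispersion (1/size); 0 gives Poisson
#'   counts.
#' @param libsize_mean Expected total counts per cell, length 1 or `n_types`.
#' @param libsize_cv Coefficient of variation of the log-normal per-cell
#'   library size.
#' @param mito_fraction_range Length-2 range of the per-cell expected
#'   mitochondrial count fraction.
#' @param n_mito Number of genes labelled mitochondrial.
#' @param subject_sd Log-scale SD of the per-subject, per-gene multiplicative
#'   donor effect.
#' @param gene_baseline_sdlog Log-scale SD of the gene baseline expression.
#' @param seed Integer seed; fixing it fixes every generated byte.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_types = 13,
                       type_names = NULL,
                       type_classes = NULL,
                       n_genes = 2000,
                       markers_per_type = 120,
                       cells_per_type = NULL,
                       n_subjects = 3,
                       marker_fold = 8,
                       nb_dispersion = 0.3,
                       libsize_mean = 5000,
                       libsize_cv = 0.2,
                       mito_fraction_range = c(0.01, 0.04),
                       n_mito = 20,
                       subject_sd = 0.15,
                       gene_baseline_sdlog = 1,
                       seed = 1L) {
  if (is.null(type_names)) {
    default_names <- c(
      "somatotroph", "lactotroph", "thyrotroph", "gonadotroph",
      "corticotroph", "stem_cell", "pro_pit1",
      "endothelial", "fibroblast", "smooth_muscle",
      "macrophage", "t_cell", "nk_cell"
    )
    default_classes <- rep(c("endocrine", "stromal", "immune"), c(7, 3, 3))
    if (n_types == 13) {
      type_names <- default_names
      type_classes <- type_classes %||% default_classes
    } else {
      type_names <- paste0("type", seq_len(n_types))
      type_classes <- type_classes %||% rep("endocrine", n_types)
    }
  }
  n_types <- length(type_names)
  type_classes <- type_classes %||% rep("endocrine", n_types)
  if (length(type_classes) != n_types) {
    stop_pitdeconv("`type_classes` must match `type_names` in length.",
                   "pitdeconv_config_error")
  }
  if (is.null(cells_per_type)) {
    cells_per_type <- ifelse(
      type_classes == "endocrine", 150L,
      ifelse(type_classes == "stromal", 80L, 60L)
    )
    # one rare immune population, mirroring the <50-nuclei exclusion scenario
    imm <- which(type_classes == "immune")
    if (length(imm) > 0) cells_per_type[imm[length(imm)]] <- 40L
  }
  if (length(cells_per_type) == 1L) {
    cells_per_type <- rep(cells_per_type, n_types)
  }
  if (length(libsize_mean) == 1L) libsize_mean <- rep(libsize_mean, n_types)

  cfg <- list(
    n_types = n_types, type_names = type_names, type_classes = type_classes,
    n_genes = n_genes, markers_per_type = markers_per_type,
    cells_per_type = as.integer(cells_per_type), n_subjects = n_subjects,
    marker_fold = marker_fold, nb_dispersion = nb_dispersion,
    libsize_mean = libsize_mean, libsize_cv = libsize_cv,
    mito_fraction_range = mito_fraction_range, n_mito = n_mito,
    subject_sd = subject_sd, gene_baseline_sdlog = gene_baseline_sdlog,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_scalar_number(cfg$n_types, "n_types", lower = 2, integerish = TRUE)
  check_scalar_number(cfg$n_genes, "n_genes", lower = 10, integerish = TRUE)
  check_scalar_number(cfg$markers_per_type, "markers_per_type", lower = 1,
                      integerish = TRUE)
  check_scalar_number(cfg$n_subjects, "n_subjects", lower = 1,
                      integerish = TRUE)
  check_scalar_number(cfg$marker_fold, "marker_fold", lower = 1)
  check_scalar_number(cfg$nb_dispersion, "nb_dispersion", lower = 0)
  check_scalar_number(cfg$subject_sd, "subject_sd", lower = 0)
  if (cfg$markers_per_type * cfg$n_types + cfg$n_mito > cfg$n_genes) {
    stop_pitdeconv(
      "`markers_per_type` x `n_types` plus `n_mito` exceeds `n_genes`.",
      "pitdeconv_config_error"
    )
  }
  if (any(cfg$cells_per_type < 1) || any(cfg$libsize_mean <= 0)) {
    stop_pitdeconv(
      "`cells_per_type` and `libsize_mean` must be positive.",
      "pitdeconv_config_error"
    )
  }
  if (length(cfg$mito_fraction_range) != 2 ||
      any(cfg$mito_fraction_range < 0) || any(cfg$mito_fraction_range >= 1) ||
      diff(cfg$mito_fraction_range) < 0) {
    stop_pitdeconv(
      "`mito_fraction_range` must be an increasing pair of fractions in [0, 1).",
      "pitdeconv_config_error"
    )
  }
  cfg
}

#' Annotated single-cell counts container
#'
#' Couples a genes x cells integer count matrix with a per-cell annotation
#' tibble (`cell_id`, `cell_type`, `subject`, `n_features`, `n_counts`,
#' `pct_mito`) and the set of genes treated as mitochondrial.
#'
#' @param counts Genes x cells matrix with gene rownames and cell colnames.
#' @param annotation Tibble with one row per column of `counts`.
#' @param mito_genes Character vector of mitochondrial gene ids (may be empty).
#' @param marker_truth Optional tibble of planted marker genes
#'   (`cell_type`, `gene`), carried by the synthetic generator.
#'
#' @return An `annotated_counts` object.
#' @export
annotated_counts <- function(counts, annotation, mito_genes = character(),
                             marker_truth = NULL) {
  counts <- check_expression_matrix(counts, "counts")
  annotation <- as_tibble(annotation)
  required <- c("cell_id", "cell_type", "subject")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols) > 0) {
    stop_pitdeconv(
      paste0("annotation is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "pitdeconv_input_error"
    )
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- annotation$cell_id
  }
  if (!identical(colnames(counts) %||% character(),
                 as.character(annotation$cell_id))) {
    stop_pitdeconv("annotation rows must match count columns one-to-one.",
                   "pitdeconv_input_error")
  }
  annotation <- recompute_qc_metrics(counts, annotation, mito_genes)
  structure(
    list(counts = counts, annotation = annotation,
         mito_genes = mito_genes, marker_truth = marker_truth),
    class = "annotated_counts"
  )
}

recompute_qc_metrics <- function(counts, annotation, mito_genes) {
  annotation$n_counts <- unname(colSums(counts))
  annotation$n_features <- unname(colSums(counts > 0))
  mito <- intersect(mito_genes, rownames(counts))
  pm <- if (length(mito) > 0) {
    colSums(counts[mito, , drop = FALSE]) / pmax(annotation$n_counts, 1)
  } else {
    rep(0, ncol(counts))
  }
  annotation$pct_mito <- unname(pm)
  annotation
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf(
    "<annotated_counts> %d genes x %d cells, %d cell types, %d subjects\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$annotation$cell_type)),
    length(unique(x$annotation$subject))
  ))
  invisible(x)
}

#' @export
dim.annotated_counts <- function(x) dim(x$counts)

#' Generate a synthetic single-nucleus reference
#'
#' Draws an annotated genes x cells count matrix under the model described in
#' [sim_config()]: gene baselines are log-normal; each type's marker block is
#' enriched `marker_fold`-fold; each donor carries a per-gene log-normal
#' multiplicative effect shared by all of that donor's cells; counts are
#' negative-binomial around a per-cell log-normal library size; a designated
#' gene set is mitochondrial with a per-cell expected fraction drawn from
#' `mito_fraction_range`. Output is byte-deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An [annotated_counts()] object; `marker_truth` records the planted
#'   marker block of each type.
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(n_types = 3, n_genes = 200,
#'   markers_per_type = 20, cells_per_type = 30, seed = 7))
#' ref
simulate_reference <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(cfg) {
  n_marker_genes <- cfg$markers_per_type * cfg$n_types
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes - cfg$n_mito))
  mito_ids <- sprintf("MT-%02d", seq_len(cfg$n_mito))
  genes <- c(gene_ids, mito_ids)

  marker_truth <- tibble(
    cell_type = rep(cfg$type_names, each = cfg$markers_per_type),
    gene = gene_ids[seq_len(n_marker_genes)]
  )

  baseline <- stats::rlnorm(cfg$n_genes, meanlog = 0,
                            sdlog = cfg$gene_baseline_sdlog)
  names(baseline) <- genes

  # genes x types expected relative expression (before donor effects)
  mean_mat <- matrix(baseline, nrow = cfg$n_genes, ncol = cfg$n_types,
                     dimnames = list(genes, cfg$type_names))
  for (k in seq_len(cfg$n_types)) {
    idx <- marker_truth$gene[marker_truth$cell_type == cfg$type_names[k]]
    mean_mat[idx, k] <- mean_mat[idx, k] * cfg$marker_fold
  }

  subjects <- sprintf("donor%02d", seq_len(cfg$n_subjects))
  # per-subject, per-gene multiplicative effect shared across the subject's cells
  donor_fx <- matrix(
    exp(rnorm(cfg$n_genes * cfg$n_subjects, 0, cfg$subject_sd)),
    nrow = cfg$n_genes,
    dimnames = list(genes, subjects)
  )

  is_mito <- genes %in% mito_ids
  n_cells <- sum(cfg$cells_per_type)
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_cells,
                   dimnames = list(genes, NULL))
  ann <- vector("list", cfg$n_types)
  col <- 0L
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  sdlog_ls <- sqrt(log(1 + cfg$libsize_cv^2))

  for (k in seq_len(cfg$n_types)) {
    nk <- cfg$cells_per_type[k]
    subj_k <- subjects[1 + (seq_len(nk) - 1L) %% cfg$n_subjects]
    libs <- stats::rlnorm(
      nk, meanlog = log(cfg$libsize_mean[k]) - sdlog_ls^2 / 2, sdlog = sdlog_ls
    )
    mito_target <- runif(nk, cfg$mito_fraction_range[1],
                         cfg$mito_fraction_range[2])
    for (j in seq_len(nk)) {
      w <- mean_mat[, k] * donor_fx[, subj_k[j]]
      w_nm <- w * !is_mito
      w_mt <- w * is_mito
      p <- (1 - mito_target[j]) * w_nm / sum(w_nm) +
        mito_target[j] * w_mt / sum(w_mt)
      mu <- libs[j] * p
      cnt <- if (is.finite(size)) {
        rnbinom(cfg$n_genes, mu = mu, size = size)
      } else {
        stats::rpois(cfg$n_genes, lambda = mu)
      }
      col <- col + 1L
      counts[, col] <- cnt
    }
    ann[[k]] <- tibble(
      cell_type = cfg$type_names[k],
      subject = subj_k
    )
  }

  annotation <- list_rbind(ann)
  annotation$cell_id <- sprintf("cell%05d", seq_len(n_cells))
  colnames(counts) <- annotation$cell_id
  annotation <- annotation[, c("cell_id", "cell_type", "subject")]

  annotated_counts(counts, annotation, mito_genes = mito_ids,
                   marker_truth = marker_truth)
}

#' Simulate a bulk tumor cohort with planted normal-tissue residue
#'
#' Each sample is a count mixture of one dominant tumor cell type and a
#' planted fraction of residual normal pituitary tissue: the expected profile
#' is `(1 - f) * tumor profile + f * residue profile`, where the residue is
#' spread over endocrine types from pituitary lineages other than the tumor's
#' (configurable via `residue_weights`), then sampled to `reads_per_sample`
#' total counts by multinomial draw. Type profiles are the reference's
#' aggregate (RNA-mass) relative expression per type.
#'
#' @param reference An [annotated_counts()] reference.
#' @param tumor_type Cell-type label of the tumor population.
#' @param contamination_fractions Numeric vector in `[0, 1)`; one bulk sample
#'   is generated per entry.
#' @param reads_per_sample Total counts per bulk sample.
#' @param seed Integer seed.
#' @param residue_weights Optional named non-negative weights over reference
#'   cell types receiving the residue; defaults to equal weights on endocrine
#'   types outside the tumor's lineage.
#' @param map A [lineage_map()] used to pick the default residue types and to
#'   attach the cohort's histotype.
#'
#' @return A list of class `bulk_cohort`: `counts` (genes x samples),
#'   `truth` (tibble: `sample`, `histotype`, `true_contamination`), and the
#'   residue weights used.
#' @export
simulate_bulk_cohort <- function(reference, tumor_type,
                                 contamination_fractions,
                                 reads_per_sample = 5e6,
                                 seed = 1L,
                                 residue_weights = NULL,
                                 map = default_lineage_map()) {
  stopifnot(inherits(reference, "annotated_counts"))
  types <- unique(reference$annotation$cell_type)
  if (!tumor_type %in% types) {
    stop_pitdeconv(
      sprintf("tumor_type '%s' is not a cell type of the reference.",
              tumor_type),
      "pitdeconv_input_error"
    )
  }
  f <- as.numeric(contamination_fractions)
  if (any(f < 0 | f >= 1)) {
    stop_pitdeconv("contamination fractions must lie in [0, 1).",
                   "pitdeconv_input_error")
  }
  check_scalar_number(reads_per_sample, "reads_per_sample", lower = 1,
                      integerish = TRUE)

  profiles <- type_mass_profiles(reference)

  if (is.null(residue_weights)) {
    lin <- map$types[types]
    tumor_lineage <- unname(map$types[tumor_type])
    residue_types <- types[
      types %in% names(map$types) &
        lin %in% c("PIT1", "TPIT", "SF1") &
        lin != tumor_lineage
    ]
    if (length(residue_types) == 0) {
      stop_pitdeconv("no endocrine types outside the tumor lineage available for residue.",
                     "pitdeconv_input_error")
    }
    residue_weights <- setNames(rep(1, length(residue_types)), residue_types)
  }
  residue_weights <- residue_weights[residue_weights > 0]
  unknown <- setdiff(names(residue_weights), types)
  if (length(unknown) > 0) {
    stop_pitdeconv(
      paste0("residue_weights name unknown type(s): ",
             paste(unknown, collapse = ", ")),
      "pitdeconv_input_error"
    )
  }
  rw <- residue_weights / sum(residue_weights)
  residue_profile <- as.vector(
    profiles[, names(rw), drop = FALSE] %*% rw
  )

  histotype <- histotype_for(tumor_type, map)

  S <- length(f)
  counts <- withr::with_seed(as.integer(seed), {
    out <- matrix(0L, nrow = nrow(profiles), ncol = S,
                  dimnames = list(rownames(profiles),
                                  sprintf("bulk%03d", seq_len(S))))
    for (s in seq_len(S)) {
      p <- (1 - f[s]) * profiles[, tumor_type] + f[s] * residue_profile
      out[, s] <- as.integer(rmultinom(1, size = reads_per_sample, prob = p))
    }
    out
  })

  structure(
    list(
      counts = counts,
      truth = tibble(
        sample = colnames(counts),
        histotype = histotype,
        true_contamination = f
      ),
      residue_weights = rw,
      tumor_type = tumor_type
    ),
    class = "bulk_cohort"
  )
}

# Aggregate relative (RNA-mass) expression profile per cell type:
# summed counts over the type's cells, normalized to sum 1.
type_mass_profiles <- function(reference) {
  types <- unique(reference$annotation$cell_type)
  prof <- vapply(types, function(tp) {
    cols <- reference$annotation$cell_id[reference$annotation$cell_type == tp]
    s <- rowSums(reference$counts[, cols, drop = FALSE])
    s / sum(s)
  }, numeric(nrow(reference$counts)))
  rownames(prof) <- rownames(reference$counts)
  prof
}

histotype_for <- function(tumor_type, map) {
  hit <- vapply(map$histotypes$tumor_types,
                function(tt) tumor_type %in% tt, logical(1))
  if (any(hit)) map$histotypes$histotype[which(hit)[1]] else tumor_type
}
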