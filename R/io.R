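#' Read an expression matrix from disk
#'
#' Supported formats: dense TSV/CSV (first column gene id, one column per
#' sample/cell) and an MTX directory containing `matrix.mtx`, `genes.tsv`
#' and `barcodes.tsv`. Duplicate gene ids are summed with a warning.
#'
#' @param path File (dense) or directory (MTX triple).
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`.
#' @return Genes x columns numeric matrix.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_pitdeconv(sprintf("path does not exist: %s", path),
                   "pitdeconv_io_error")
  }
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "mtx"
    } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      "csv"
    } else {
      "tsv"
    }
  }

  if (format == "mtx") {
    needed <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    missing_files <- needed[!file.exists(needed)]
    if (length(missing_files) > 0) {
      stop_pitdeconv(
        paste0("MTX directory is missing: ",
               paste(basename(missing_files), collapse = ", ")),
        "pitdeconv_io_error"
      )
    }
    m <- as.matrix(Matrix::readMM(needed[1]))
    genes <- readr::read_tsv(needed[2], col_names = FALSE,
                             show_col_types = FALSE)[[1]]
    barcodes <- readr::read_tsv(needed[3], col_names = FALSE,
                                show_col_types = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      stop_pitdeconv("MTX dimensions do not match genes/barcodes files.",
                     "pitdeconv_io_error")
    }
    dimnames(m) <- list(genes, barcodes)
    return(dedupe_genes(m))
  }

  df <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (ncol(df) < 2) {
    stop_pitdeconv(sprintf("malformed expression table (%s): need a gene column plus data columns.",
                           path),
                   "pitdeconv_io_error")
  }
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop_pitdeconv(sprintf("malformed expression table (%s): non-numeric data columns.",
                           path),
                   "pitdeconv_io_error")
  }
  rownames(m) <- genes
  dedupe_genes(m)
}

dedupe_genes <- function(m) {
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    warn(sprintf("%d duplicated gene id(s) summed (e.g. %s).",
                 length(dups), paste(head(dups, 3), collapse = ", ")))
    m <- rowsum(m, group = rownames(m), reorder = FALSE)
  }
  m
}

#' Write an expression matrix
#'
#' @param mat Genes x columns matrix.
#' @param path Output file (dense TSV/CSV) or directory (MTX triple).
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  mat <- check_expression_matrix(mat, "mat")
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(gene = rownames(mat)),
                     file.path(path, "genes.tsv"), col_names = FALSE)
    readr::write_tsv(tibble(barcode = colnames(mat)),
                     file.path(path, "barcodes.tsv"), col_names = FALSE)
    return(invisible(path))
  }
  df <- as_tibble(mat, rownames = "gene")
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Write / read a signature matrix as TSV plus a JSON sidecar
#'
#' The TSV holds the gene x type CPM values (first column `gene`); the JSON
#' sidecar (`<path>.members.json`) records the per-type member gene sets,
#' the GES size and the id.
#'
#' @param sig A [signature_matrix()].
#' @param path TSV path.
#' @return `write_signature()`: `path`, invisibly. `read_signature()`: a
#'   [signature_matrix()].
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  write_expression(sig$values, path, format = "tsv")
  jsonlite::write_json(
    list(id = sig$id, n = sig$n, members = sig$members),
    paste0(path, ".members.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  values <- read_expression(path, format = "tsv")
  sidecar <- paste0(path, ".members.json")
  if (!file.exists(sidecar)) {
    stop_pitdeconv(sprintf("missing signature sidecar: %s", sidecar),
                   "pitdeconv_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  members <- map(meta$members, as.character)
  signature_matrix(values, members, n = meta$n, id = meta$id)
}

#' Write the per-cell annotation table
#'
#' @param data An [annotated_counts()] object.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(data, path) {
  stopifnot(inherits(data, "annotated_counts"))
  readr::write_tsv(
    data$annotation[, c("cell_id", "cell_type", "subject", "n_features",
                        "n_counts", "pct_mito")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All randomness downstream
#' flows from the single `seed`.
#'
#' @param sim A [sim_config()] for the synthetic reference.
#' @param qc A [qc_thresholds()].
#' @param svr An [svr_config()].
#' @param ges_sizes GES sizes to build for the marker-based route.
#' @param n_samples,cells_per_sample Pseudobulk simulation scenario
#'   (defaults 150 x 500).
#' @param r_threshold,p_threshold Validation rule bounds (defaults 0.70,
#'   0.05).
#' @param bulk_tumor_type,bulk_fractions,bulk_reads Bulk-cohort scenario for
#'   the contamination stage.
#' @param flag_threshold Contamination flag threshold (default 0.20).
#' @param hvg_n,cluster_k Clustering-stage parameters.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_thresholds(),
                            svr = svr_config(n_permutations = 0),
                            ges_sizes = c(50, 100, 150, 200, 300),
                            n_samples = 150,
                            cells_per_sample = 500,
                            r_threshold = 0.70,
                            p_threshold = 0.05,
                            bulk_tumor_type = "somatotroph",
                            bulk_fractions = rep(c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                                                 each = 5),
                            bulk_reads = 5e6,
                            flag_threshold = 0.20,
                            hvg_n = 500,
                            cluster_k = 6,
                            seed = 1L) {
  check_scalar_number(r_threshold, "r_threshold", lower = -1, upper = 1)
  check_scalar_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  structure(
    list(sim = sim, qc = qc, svr = svr, ges_sizes = ges_sizes,
         n_samples = n_samples, cells_per_sample = cells_per_sample,
         r_threshold = r_threshold, p_threshold = p_threshold,
         bulk_tumor_type = bulk_tumor_type, bulk_fractions = bulk_fractions,
         bulk_reads = bulk_reads, flag_threshold = flag_threshold,
         hvg_n = hvg_n, cluster_k = cluster_k, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `sim`, `qc`
#' and `svr` are nested maps passed to their constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$qc)) args$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$svr)) args$svr <- do.call(svr_config, y$svr)
  scalar_keys <- setdiff(names(y), c("sim", "qc", "svr"))
  args <- c(args, y[scalar_keys])
  do.call(pipeline_config, args)
}

#' Run the full deconvolution pipeline
#'
#' Executes the whole workflow on the synthetic reference: generate and
#' QC-filter the reference, build the single-cell-mode signature and the
#' multi-subject profiles, simulate pseudobulk mixtures, deconvolve with
#' both engines, validate against ground truth, then generate a bulk tumor
#' cohort with planted contamination, score residual normal tissue and flag
#' discordant samples by clustering. Every stage's output is written as TSV
#' under `out_dir`, together with the effective configuration (seed
#' included) as YAML; two runs with the same configuration produce
#' byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) inform(sprintf("[pitdeconv] stage: %s", name))

  seeds <- derive_seeds(config$seed)

  stage("reference")
  config$sim$seed <- seeds["reference"]
  ref <- simulate_reference(config$sim)
  write_annotation(ref, file.path(out_dir, "reference_annotation.tsv"))

  stage("qc")
  ref <- qc_filter(ref, config$qc)

  stage("signature")
  sig <- build_signature_from_cells(ref)
  write_signature(sig, file.path(out_dir, "signature_sc.tsv"))
  prof <- subject_profiles(ref)

  stage("pseudobulk")
  mix <- simulate_pseudobulk(ref, n_samples = config$n_samples,
                             cells_per_sample = config$cells_per_sample,
                             seed = seeds["pseudobulk"])
  write_expression(mix$mixtures, file.path(out_dir, "pseudobulk_cpm.tsv"))
  readr::write_tsv(as_tibble(mix$true_proportions, rownames = "sample"),
                   file.path(out_dir, "pseudobulk_truth.tsv"),
                   progress = FALSE)

  stage("deconvolve + evaluate")
  bench <- benchmark_engines(
    mix,
    runs = list(
      svr_sc = list(engine = "svr", signature = sig, cfg = config$svr,
                    seed = seeds["svr"]),
      wnnls_sc = list(engine = "wnnls", profiles = prof)
    ),
    r_threshold = config$r_threshold, p_threshold = config$p_threshold
  )
  readr::write_tsv(bench, file.path(out_dir, "benchmark_report.tsv"),
                   progress = FALSE)

  stage("bulk contamination")
  cohort <- simulate_bulk_cohort(
    ref, tumor_type = config$bulk_tumor_type,
    contamination_fractions = config$bulk_fractions,
    reads_per_sample = config$bulk_reads, seed = seeds["bulk"]
  )
  bulk_cpm_mat <- bulk_cpm(cohort$counts)
  dec <- svr_deconvolve(bulk_cpm_mat, sig, cfg = config$svr,
                        seed = seeds["bulk_svr"])
  contam <- contamination_score(dec, histotype = cohort$truth$histotype,
                                flag_threshold = config$flag_threshold)
  contam$true_contamination <- cohort$truth$true_contamination
  readr::write_tsv(contam, file.path(out_dir, "contamination_report.tsv"),
                   progress = FALSE)

  stage("cluster flags")
  logb <- log_transform(bulk_cpm_mat, base = "10")
  hvg <- hvg_select(logb, n = min(config$hvg_n, nrow(logb)))
  hc <- hclust_samples(logb, genes = hvg)
  map_lin <- default_lineage_map()
  lineages <- setNames(
    map_lin$histotypes$lineage[
      match(cohort$truth$histotype, map_lin$histotypes$histotype)
    ],
    cohort$truth$sample
  )
  flags <- flag_discordant(hc, lineages,
                           k = min(config$cluster_k, ncol(bulk_cpm_mat)))
  readr::write_tsv(flags, file.path(out_dir, "cluster_flags.tsv"),
                   progress = FALSE)

  write_effective_config(config, file.path(out_dir, "effective_config.yaml"))
  inform("[pitdeconv] pipeline complete")

  invisible(list(
    reference = ref, signature = sig, profiles = prof, mixtures = mix,
    benchmark = bench, cohort = cohort, deconvolution = dec,
    contamination = contam, flags = flags, config = config
  ))
}

# fixed offsets keep all stage seeds below 2^31 and decoupled
derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  c(reference = base * 101L + 1L,
    pseudobulk = base * 101L + 2L,
    svr = base * 101L + 3L,
    bulk = base * 101L + 4L,
    bulk_svr = base * 101L + 5L)
}

write_effective_config <- function(config, path) {
  plain <- rapply(unclass(config), unlist, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}
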