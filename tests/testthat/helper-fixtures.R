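# Shared fixtures, generated in code. The small reference keeps every module
# exercisable in seconds; the default reference (sim_config()) is reserved
# for the acceptance tests.

small_sim_config <- function(seed = 7, ...) {
  sim_config(
    n_types = 4,
    type_names = c("somatotroph", "gonadotroph", "corticotroph", "t_cell"),
    type_classes = c("endocrine", "endocrine", "endocrine", "immune"),
    n_genes = 400,
    markers_per_type = 25,
    cells_per_type = 60,
    n_subjects = 3,
    seed = seed,
    ...
  )
}

small_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(qc_filter(
        simulate_reference(small_sim_config()),
        qc_thresholds(min_features = 0, max_features = Inf,
                      min_counts = 0, max_mito = 1)
      ))
    }
    cache
  }
})

# The full-scale synthetic atlas (13 types, 3 donors, 2000 genes, 120
# markers per type at 8-fold enrichment), QC-filtered with the standard
# thresholds; cached because several acceptance checks share it.
default_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(qc_filter(
        simulate_reference(sim_config(seed = 11))
      ))
    }
    cache
  }
})

default_sc_signature <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(build_signature_from_cells(
        default_reference()
      ))
    }
    cache
  }
})

# Marker table with a controlled per-type supply of significant markers.
make_marker_fixture <- function(supply_a = 400, supply_b = 40) {
  genes_a <- sprintf("a%04d", seq_len(supply_a))
  genes_b <- sprintf("b%04d", seq_len(supply_b))
  markers <- tibble::tibble(
    cell_type = c(rep("A", supply_a), rep("B", supply_b)),
    gene = c(genes_a, genes_b),
    p_value = 1e-10,
    adj_p = 1e-8,
    logFC = 2,
    pct_in = 1, pct_out = 0.05,
    mean_cpm_in = c(rev(seq_len(supply_a)) * 10, rev(seq_len(supply_b)) * 10)
  )
  genes <- c(genes_a, genes_b)
  profiles <- matrix(5, length(genes), 2,
                     dimnames = list(genes, c("A", "B")))
  profiles[genes_a, "A"] <- markers$mean_cpm_in[seq_len(supply_a)]
  profiles[genes_b, "B"] <- markers$mean_cpm_in[supply_a + seq_len(supply_b)]
  list(markers = markers, profiles = profiles)
}

# Hand-built annotated counts with fully controlled metrics.
manual_counts <- function(mat, types, subjects = "s1", mito = character()) {
  n <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%03d", seq_len(n))
  annotated_counts(
    mat,
    tibble::tibble(
      cell_id = colnames(mat),
      cell_type = rep_len(types, n),
      subject = rep_len(subjects, n)
    ),
    mito_genes = mito
  )
}

# Two cell types with disjoint expressed marker blocks. Heights vary across
# genes (as real marker blocks do) so the gene rows are affinely diverse and
# the mixing coefficients are identifiable; asymmetric levels keep mixtures
# non-constant at any proportion.
orthogonal_signature <- function(n_genes = 60, high = c(200, 320)) {
  g <- sprintf("g%03d", seq_len(n_genes))
  half <- n_genes / 2
  high <- rep_len(high, 2)
  X <- matrix(2, n_genes, 2, dimnames = list(g, c("typeA", "typeB")))
  X[seq_len(half), 1] <- seq(0.5 * high[1], 1.5 * high[1],
                             length.out = half)
  X[(half + 1):n_genes, 2] <- seq(0.5 * high[2], 1.5 * high[2],
                                  length.out = half)
  X
}
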