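make_qc_fixture <- function() {
  # 3500 genes so the standard feature bounds are exercised exactly
  n_genes <- 3500
  g <- sprintf("g%04d", seq_len(n_genes))
  cells <- c("borderline", "good", "high_mito", "low_counts")
  m <- matrix(0, n_genes, length(cells), dimnames = list(g, cells))
  m[seq_len(999), "borderline"] <- 2              # exactly 999 features
  m[seq_len(3000), "good"] <- 1
  m[1:1000, "good"] <- 2
  m[3500, "good"] <- 100                          # mito gene; 3001 features
  m[seq_len(1500), "high_mito"] <- 2
  m[3500, "high_mito"] <- 400                     # >5% mito
  m[seq_len(1100), "low_counts"] <- 0
  m[seq_len(1100), "low_counts"] <- rep(0, 1100)
  m[1:150, "low_counts"] <- 1                     # 150 counts only
  manual_counts(m, types = "A", mito = "g3500")
}

test_that("qc_filter applies the strict feature/count/mito bounds", {
  fx <- make_qc_fixture()
  # 'good': 3001 features, 4100 total counts, 100/4100 = 2.4% mito
  expect_equal(fx$annotation$n_features[2], 3001)
  out <- suppressMessages(suppressWarnings(qc_filter(fx)))
  expect_identical(out$annotation$cell_id, "good")

  # boundary: exactly 1000 features must still be excluded (strict bound)
  m <- fx$counts[, "borderline", drop = FALSE]
  m[1000, 1] <- 2
  fx2 <- manual_counts(m, types = "A", mito = "g3500")
  expect_equal(fx2$annotation$n_features[1], 1000)
  out2 <- suppressMessages(suppressWarnings(qc_filter(fx2)))
  expect_equal(ncol(out2$counts), 0)
})

test_that("qc_filter is idempotent and vacuous thresholds are identity", {
  ref <- simulate_reference(small_sim_config(seed = 31))
  thr <- qc_thresholds(min_features = 10, max_features = 5000,
                       min_counts = 20, max_mito = 0.5)
  once <- suppressMessages(qc_filter(ref, thr))
  twice <- suppressMessages(qc_filter(once, thr))
  expect_identical(once$counts, twice$counts)
  expect_identical(once$annotation, twice$annotation)

  vac <- qc_thresholds(min_features = 0, max_features = Inf,
                       min_counts = 0, max_mito = 1)
  all_in <- suppressMessages(qc_filter(ref, vac))
  expect_identical(all_in$counts, ref$counts)
})

test_that("an empty QC result warns instead of crashing", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), NULL))
  fx <- manual_counts(m, types = "A")
  expect_warning(
    suppressMessages(qc_filter(fx, qc_thresholds(min_features = 100,
                                                 max_features = 200))),
    "every cell"
  )
})

test_that("cpm_normalize scales columns to one million", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(cpm_normalize(m)[, 1]), c(250000, 250000, 500000))

  already <- matrix(c(4e5, 6e5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(cpm_normalize(already), already)

  two <- cbind(already, already * 7)
  colnames(two) <- c("s1", "s2")
  res <- cpm_normalize(two)
  expect_equal(unname(res[, 1]), unname(res[, 2]))

  zero <- matrix(c(1, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  zero[, 2] <- 0
  expect_error(cpm_normalize(zero), "s2")
})

test_that("cpm_normalize agrees with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(1)
  m <- matrix(rpois(200, 20), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  expect_equal(unname(cpm_normalize(m)),
               unname(as.matrix(edgeR::cpm(m))), tolerance = 1e-12)
})

test_that("log_transform handles both bases and rejects negatives", {
  m <- matrix(c(0, exp(1) - 1, 999999), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  nat <- log_transform(m, base = "e")
  expect_equal(unname(nat[, 1]), c(0, 1, log(1e6)))
  ten <- log_transform(m, base = "10")
  expect_equal(unname(ten[3, 1]), 6)
  m[1, 1] <- -1
  expect_error(log_transform(m), "non-negative")
})

test_that("find_markers p-values are near-uniform under the null", {
  set.seed(42)
  n_genes <- 1000; n <- 200
  # identical zero-inflated lognormal expression in both groups
  counts <- matrix(rpois(n_genes * n, lambda = rep(exp(rnorm(n_genes)), n)),
                   n_genes, n, dimnames = list(sprintf("g%04d", 1:n_genes),
                                               sprintf("c%03d", 1:n)))
  cpm <- cpm_normalize(counts + 0)
  labels <- rep(c("A", "B"), each = n / 2)
  mk <- suppressMessages(find_markers(cpm, labels, min_cells = 10))
  expect_gt(mean(mk$p_value), 0.35)
  expect_lt(mean(mk$p_value < 0.05), 0.12)
  # and the marker filter fires (essentially) never
  expect_lte(sum(mk$adj_p <= 0.05 & mk$logFC > 1), 2)
})

test_that("planted markers are detected with high power", {
  ref <- small_reference()
  cpm <- cpm_normalize(ref$counts)
  mk <- suppressMessages(find_markers(cpm, ref$annotation$cell_type,
                                      min_cells = 20))
  sig <- mk[mk$adj_p <= 0.05 & mk$logFC > 1, ]
  for (tp in unique(ref$annotation$cell_type)) {
    planted <- ref$marker_truth$gene[ref$marker_truth$cell_type == tp]
    hit <- mean(planted %in% sig$gene[sig$cell_type == tp])
    expect_gte(hit, 0.9)
  }
})

test_that("genes under the detection floor are not tested", {
  set.seed(8)
  g <- c("rare", "common")
  m <- matrix(0, 2, 40, dimnames = list(g, sprintf("c%02d", 1:40)))
  m["common", ] <- 50
  m["rare", sample(40, 4)] <- 5   # 10% detection in both groups
  cpm <- cpm_normalize(m)
  mk <- suppressMessages(find_markers(cpm, rep(c("A", "B"), 20),
                                      min_pct = 0.25, min_cells = 5))
  expect_false("rare" %in% mk$gene)
  expect_true("common" %in% mk$gene)
})

test_that("the bimodal LRT matches the upstream single-cell implementation", {
  skip_if_not_installed("Seurat")
  set.seed(99)
  n <- 60
  x <- c(rep(0, 20), rlnorm(n - 20))
  y <- c(rep(0, 5), rlnorm(n - 5, meanlog = 1))
  upstream <- getFromNamespace("DifferentialLRT", "Seurat")(x, y)

  lik <- pitdeconv:::bimod_loglik
  lr <- 2 * (lik(matrix(x, 1)) + lik(matrix(y, 1)) -
               lik(matrix(c(x, y), 1)))
  ours <- pchisq(lr, df = 3, lower.tail = FALSE)
  expect_equal(unname(ours), unname(upstream), tolerance = 1e-10)
})

test_that("build_ges takes exactly min(N, supply) members per type", {
  fx <- make_marker_fixture(400, 40)
  g300 <- build_ges(fx$markers, fx$profiles, n = 300)
  expect_length(g300$members$A, 300)
  expect_length(g300$members$B, 40)
  g50 <- build_ges(fx$markers, fx$profiles, n = 50)
  expect_length(g50$members$A, 50)
  expect_length(g50$members$B, 40)
})

test_that("GES member sets are nested across N", {
  fx <- make_marker_fixture(400, 40)
  sizes <- c(50, 100, 150, 200, 300)
  sigs <- lapply(sizes, function(n) build_ges(fx$markers, fx$profiles, n))
  for (i in seq_len(length(sizes) - 1)) {
    for (tp in c("A", "B")) {
      expect_true(all(sigs[[i]]$members[[tp]] %in%
                        sigs[[i + 1]]$members[[tp]]))
    }
  }
})

test_that("the significance filter excludes near-miss markers", {
  fx <- make_marker_fixture(10, 10)
  fx$markers$adj_p[1] <- 0.04
  fx$markers$logFC[1] <- 0.9     # fails logFC > 1
  fx$markers$adj_p[11] <- 0.06   # fails adj_p <= 0.05
  g <- build_ges(fx$markers, fx$profiles, n = 50)
  expect_false(fx$markers$gene[1] %in% g$members$A)
  expect_false(fx$markers$gene[11] %in% g$members$B)
})

test_that("low-expression genes are dropped and empty types warned about", {
  fx <- make_marker_fixture(10, 10)
  # one marker gene never exceeds 1 CPM anywhere
  low <- fx$markers$gene[1]
  fx$profiles[low, ] <- c(0.5, 0.2)
  g <- build_ges(fx$markers, fx$profiles, n = 50)
  expect_false(low %in% rownames(g$values))
  expect_true(all(apply(g$values, 1, max) > 1))

  fx$markers$adj_p[fx$markers$cell_type == "B"] <- 1
  expect_warning(build_ges(fx$markers, fx$profiles, n = 50),
                 "no significant markers")
})

test_that("top-N ties break by adj_p then gene id", {
  markers <- tibble::tibble(
    cell_type = "A",
    gene = c("g3", "g1", "g2"),
    p_value = 1e-9,
    adj_p = c(1e-4, 1e-6, 1e-4),
    logFC = 2, pct_in = 1, pct_out = 0,
    mean_cpm_in = c(100, 100, 100)
  )
  markers <- rbind(markers,
                   tibble::tibble(cell_type = "B", gene = "g9",
                                  p_value = 1e-9, adj_p = 1e-9, logFC = 2,
                                  pct_in = 1, pct_out = 0,
                                  mean_cpm_in = 50))
  profiles <- matrix(100, 4, 2, dimnames = list(c("g1", "g2", "g3", "g9"),
                                                c("A", "B")))
  g <- build_ges(markers, profiles, n = 2)
  expect_identical(g$members$A, c("g1", "g2"))
})
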