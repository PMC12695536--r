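sig_from_matrix <- function(X, n = 50) {
  members <- lapply(seq_len(ncol(X)), function(k) character())
  names(members) <- colnames(X)
  signature_matrix(X, members, n = n)
}

test_that("svr recovers a pure signature column", {
  X <- orthogonal_signature()
  y <- matrix(X[, 1], dimnames = list(rownames(X), "s1"))
  dec <- svr_deconvolve(y, sig_from_matrix(X),
                        cfg = svr_config(n_permutations = 0))
  expect_gte(dec$proportions[1, "typeA"], 0.99)
  expect_lte(dec$proportions[1, "typeB"], 0.01)
})

test_that("svr matches the grid-search oracle on a 50/50 mixture", {
  X <- orthogonal_signature()
  y <- matrix(0.5 * X[, 1] + 0.5 * X[, 2],
              dimnames = list(rownames(X), "s1"))
  oracle <- simplex_grid_oracle(X, y[, 1])
  expect_equal(unname(oracle), c(0.5, 0.5))
  dec <- svr_deconvolve(y, sig_from_matrix(X),
                        cfg = svr_config(n_permutations = 0))
  expect_lt(max(abs(dec$proportions[1, ] - c(0.5, 0.5))), 0.02)
})

test_that("svr permutation p-values behave", {
  X <- orthogonal_signature()
  y <- matrix(X %*% c(0.6, 0.4), dimnames = list(rownames(X), "s1"))
  dec0 <- svr_deconvolve(y, sig_from_matrix(X),
                         cfg = svr_config(n_permutations = 0))
  expect_true(is.na(dec0$stats$p_value[1]))

  cfg <- svr_config(n_permutations = 50)
  dec1 <- svr_deconvolve(y, sig_from_matrix(X), cfg = cfg, seed = 1)
  expect_lt(dec1$stats$p_value[1], 0.05)
  expect_equal(dec1$proportions, dec0$proportions)
  # p is seed-stable in expectation
  dec2 <- svr_deconvolve(y, sig_from_matrix(X), cfg = cfg, seed = 2)
  expect_lte(abs(dec1$stats$p_value[1] - dec2$stats$p_value[1]), 0.1)
})

test_that("identically permuting gene order leaves both engines unchanged", {
  ref <- small_reference()
  prof <- subject_profiles(ref, min_cells = 20)
  sig <- suppressMessages(build_signature_from_cells(ref, min_cells = 20))
  mix <- simulate_pseudobulk(ref, 3, 200, seed = 6)

  perm <- withr::with_seed(1, sample(nrow(mix$mixtures)))
  mix_p <- mix
  mix_p$mixtures <- mix$mixtures[perm, ]
  sig_p <- sig
  sig_p$values <- sig$values[withr::with_seed(2, sample(nrow(sig$values))), ]

  a <- svr_deconvolve(mix, sig, cfg = svr_config(n_permutations = 0))
  b <- svr_deconvolve(mix_p, sig_p, cfg = svr_config(n_permutations = 0))
  # libsvm's working-set heuristics are order-sensitive at its own
  # convergence tolerance; the estimates must agree to well below that
  expect_lt(max(abs(a$proportions - b$proportions)), 0.01)

  aw <- suppressWarnings(wnnls_deconvolve(mix, prof))
  prof_p <- prof
  gperm <- withr::with_seed(3, sample(nrow(prof$mean_profiles)))
  prof_p$mean_profiles <- prof$mean_profiles[gperm, ]
  prof_p$subject_means <- lapply(prof$subject_means, function(m) m[gperm, ])
  prof_p$var <- prof$var[gperm, ]
  bw <- suppressWarnings(wnnls_deconvolve(mix_p, prof_p))
  expect_equal(aw$proportions, bw$proportions, tolerance = 1e-6)
})

test_that("errors are labelled: shared genes, zero samples, bad signature", {
  X <- orthogonal_signature()
  y <- matrix(1, 2, 1, dimnames = list(c("zz1", "zz2"), "s1"))
  expect_error(svr_deconvolve(y, sig_from_matrix(X)), "shared")
  y2 <- matrix(0, nrow(X), 1, dimnames = list(rownames(X), "s1"))
  expect_error(svr_deconvolve(y2, sig_from_matrix(X)), "all-zero|zero")
})

test_that("single-cell signature mode captures planted markers of every type", {
  ref <- small_reference()
  sig <- suppressMessages(build_signature_from_cells(ref, min_cells = 20))
  for (tp in unique(ref$annotation$cell_type)) {
    planted <- ref$marker_truth$gene[ref$marker_truth$cell_type == tp]
    overlap <- mean(planted %in% sig$members[[tp]])
    expect_gte(overlap, 0.8)
  }
  # invariants: no duplicate genes, >1 CPM somewhere
  expect_false(anyDuplicated(rownames(sig$values)) > 0)
  expect_true(all(apply(sig$values, 1, max) > 1))
})

test_that("collinear type profiles make signature construction fail", {
  g <- sprintf("g%03d", 1:50)
  m <- matrix(rpois(50 * 40, 20), 50, 40, dimnames = list(g, NULL))
  m <- cbind(m, m)  # second type identical to the first
  colnames(m) <- sprintf("c%03d", 1:80)
  fx <- manual_counts(m, types = rep(c("A", "B"), each = 40))
  expect_error(
    suppressMessages(build_signature_from_cells(fx, g_range = c(5, 10),
                                                min_cells = 10)),
    "singular|collinear"
  )
})

test_that("wnnls recovers noiseless single-subject mixtures", {
  X <- orthogonal_signature(n_genes = 40, high = 500)
  counts <- round(cbind(X[, 1] %o% rep(1, 6), X[, 2] %o% rep(1, 6)) * 10)
  colnames(counts) <- sprintf("c%02d", 1:12)
  fx <- manual_counts(counts, types = rep(c("typeA", "typeB"), each = 6))
  prof <- subject_profiles(fx, min_cells = 3)

  sf <- prof$size_factors
  D <- sweep(prof$mean_profiles, 2, sf, "*")
  y <- matrix(D %*% c(0.7, 0.3), dimnames = list(rownames(D), "s1"))
  expect_warning(dec <- wnnls_deconvolve(y, prof), "single subject")
  expect_lt(max(abs(dec$proportions[1, ] - c(0.7, 0.3))), 0.01)
  oracle <- simplex_grid_oracle(D, y[, 1])
  expect_lt(sqrt(sum((dec$proportions[1, ] - oracle)^2)), 0.03)
})

test_that("zero cross-subject variance reduces wnnls to plain NNLS", {
  X <- orthogonal_signature(n_genes = 40, high = 500)
  counts <- round(cbind(X[, 1] %o% rep(1, 8), X[, 2] %o% rep(1, 8)) * 10)
  colnames(counts) <- sprintf("c%02d", 1:16)
  # two subjects with identical cells: cross-subject variance is exactly 0
  fx <- manual_counts(counts, types = rep(c("typeA", "typeB"), each = 8),
                      subjects = rep(c("d1", "d2"), 8))
  prof <- subject_profiles(fx, min_cells = 3)
  expect_true(all(prof$var == 0))

  D <- sweep(prof$mean_profiles, 2, prof$size_factors, "*")
  y <- matrix(D %*% c(0.25, 0.75), dimnames = list(rownames(D), "s1"))
  dec <- wnnls_deconvolve(y, prof)
  plain <- pracma::lsqnonneg(D, y[, 1])$x
  expect_equal(unname(dec$proportions[1, ]),
               plain / sum(plain), tolerance = 1e-8)
  expect_true(all(dec$stats$converged))
})

test_that("wnnls proportions are simplex-valid on real mixtures", {
  ref <- small_reference()
  prof <- subject_profiles(ref, min_cells = 20)
  mix <- simulate_pseudobulk(ref, 6, 300, seed = 8)
  dec <- suppressWarnings(wnnls_deconvolve(mix, prof))
  expect_true(all(dec$proportions >= 0))
  expect_equal(unname(rowSums(dec$proportions)), rep(1, 6))
})

test_that("recovery degrades monotonically with additive noise", {
  ref <- small_reference()
  sig <- suppressMessages(build_signature_from_cells(ref, min_cells = 20))
  mix <- simulate_pseudobulk(ref, 25, 300, seed = 10)
  noise_sd <- c(0, 200, 800, 3200, 12800)
  mean_r <- vapply(seq_along(noise_sd), function(i) {
    noisy <- mix
    noisy$mixtures <- withr::with_seed(100 + i, {
      pmax(mix$mixtures + matrix(rnorm(length(mix$mixtures),
                                       sd = noise_sd[i]),
                                 nrow(mix$mixtures)), 0)
    })
    dec <- svr_deconvolve(noisy, sig, cfg = svr_config(n_permutations = 0))
    rep <- suppressWarnings(evaluate_deconv(mix, dec))
    mean(rep$pearson_r, na.rm = TRUE)
  }, numeric(1))
  # non-increasing within simulation error, and clearly lower at the extreme
  expect_true(all(diff(mean_r) < 0.05))
  expect_lt(mean_r[5], mean_r[1] - 0.1)
})
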