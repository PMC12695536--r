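test_that("bulk_cpm shares the CPM contract", {
  m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(bulk_cpm(m)[, 1]), c(250000, 750000))
  prop <- cbind(m, m * 3)
  colnames(prop) <- c("s1", "s2")
  cpm <- bulk_cpm(prop)
  expect_equal(unname(cpm[, 1]), unname(cpm[, 2]))
  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_error(bulk_cpm(zero), "zero-sum")
})

test_that("contamination_score partitions proportions per the lineage map", {
  p <- matrix(c(somatotroph = 0.6, lactotroph = 0.1, gonadotroph = 0.2,
                t_cell = 0.1), 1,
              dimnames = list("s1", c("somatotroph", "lactotroph",
                                      "gonadotroph", "t_cell")))
  cs <- contamination_score(p, histotype = "GH")
  expect_equal(cs$tumor_fraction, 0.6)
  expect_equal(cs$same_lineage_fraction, 0.1)
  expect_equal(cs$residual_normal_fraction, 0.2)
  expect_equal(cs$tme_fraction, 0.1)
  expect_equal(cs$tumor_fraction + cs$same_lineage_fraction +
                 cs$residual_normal_fraction + cs$tme_fraction, 1,
               tolerance = 1e-6)
  expect_true(cs$contaminated)  # 0.2 >= default threshold 0.2

  pure <- matrix(1, 1, dimnames = list("s1", "somatotroph"))
  cs2 <- contamination_score(pure, "GH")
  expect_equal(cs2$residual_normal_fraction, 0)
  expect_false(cs2$contaminated)
})

test_that("stem/progenitor signal follows the PIT1 convention", {
  p <- matrix(c(0.7, 0.2, 0.1), 1,
              dimnames = list("s1", c("somatotroph", "pro_pit1",
                                      "gonadotroph")))
  default <- contamination_score(p, "GH")
  expect_equal(default$same_lineage_fraction, 0.2)
  expect_equal(default$residual_normal_fraction, 0.1)

  strict <- contamination_score(
    p, "GH", map = default_lineage_map(stem_as_same_lineage_pit1 = FALSE)
  )
  expect_equal(strict$residual_normal_fraction, 0.3, tolerance = 1e-12)

  # for a non-PIT1 tumor, stem signal is residue either way
  p2 <- matrix(c(0.7, 0.2, 0.1), 1,
               dimnames = list("s1", c("corticotroph", "pro_pit1",
                                       "somatotroph")))
  acth <- contamination_score(p2, "ACTH")
  expect_equal(acth$residual_normal_fraction, 0.3, tolerance = 1e-12)
})

test_that("unknown labels are labelled errors", {
  p <- matrix(1, 1, dimnames = list("s1", "somatotroph"))
  expect_error(contamination_score(p, "XX"), "histotype")
  p2 <- matrix(c(0.5, 0.5), 1,
               dimnames = list("s1", c("somatotroph", "mystery")))
  expect_error(contamination_score(p2, "GH"), "lineage map")
})

test_that("cohort glance summarizes flagged samples", {
  p <- matrix(c(0.9, 0.1, 0, 0.6, 0.4, 0, 0.5, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("somatotroph", "gonadotroph", "t_cell")))
  cs <- contamination_score(p, "GH", flag_threshold = 0.2)
  g <- glance(cs)
  expect_equal(g$n_contaminated, 2)
  expect_equal(g$mean_contamination, mean(c(0.4, 0.5)))
  expect_equal(g$sd_contamination, sd(c(0.4, 0.5)))
})

test_that("batch_adjust aligns per-gene batch means", {
  set.seed(3)
  g <- sprintf("g%02d", 1:30)
  a <- matrix(rnorm(30 * 6, 5), 30, 6,
              dimnames = list(g, sprintf("a%d", 1:6)))
  shift <- rnorm(30, 2)
  b <- a[, 1:6] + shift
  colnames(b) <- sprintf("b%d", 1:6)

  merged <- batch_adjust(list(a, b), c("A", "B"))
  mean_a <- rowMeans(merged[, 1:6])
  mean_b <- rowMeans(merged[, 7:12])
  expect_equal(mean_a, mean_b, tolerance = 1e-9)

  # single batch: identity
  solo <- batch_adjust(list(a), "A")
  expect_equal(solo, a)

  # genes missing in one dataset are dropped with a message
  b_short <- b[1:20, ]
  expect_message(merged2 <- batch_adjust(list(a, b_short), c("A", "B")),
                 "dropped")
  expect_equal(nrow(merged2), 20)

  # batch of one sample: centered only, with warning
  b1 <- b[, 1, drop = FALSE]
  expect_warning(batch_adjust(list(a, b1), c("A", "B")), "single sample")
})

test_that("hvg_select ranks by variance with lexicographic ties", {
  g <- c("flat1", "flat2", "var1", "var2")
  m <- rbind(rep(5, 6), rep(3, 6), c(1, 9, 1, 9, 1, 9), c(0, 10, 0, 10, 0, 10))
  dimnames(m) <- list(g, sprintf("s%d", 1:6))
  expect_setequal(hvg_select(m, 2), c("var1", "var2"))
  expect_equal(hvg_select(m, 4), c("var2", "var1", "flat1", "flat2"))

  ref <- small_reference()
  logm <- log_transform(cpm_normalize(ref$counts), "10")
  expect_equal(hvg_select(logm, nrow(logm)) |> sort(),
               rownames(logm) |> sort())
})

test_that("complete-linkage merges match the hand computation", {
  # samples at coordinates 0, 1, 10 on a single gene
  m <- matrix(c(0, 1, 10), 1, 3,
              dimnames = list("g1", c("p0", "p1", "p10")))
  hc <- hclust_samples(m)
  expect_equal(hc$height, c(1, 10))
  first <- cutree(hc, k = 2)
  expect_equal(unname(first[c("p0", "p1")]), c(1, 1))
  expect_equal(unname(first["p10"]), 2)

  dup <- cbind(m, p0b = m[, "p0", drop = FALSE])
  colnames(dup) <- c("p0", "p1", "p10", "p0b")
  hc2 <- hclust_samples(dup)
  expect_equal(min(hc2$height), 0)  # duplicates merge first at height 0
})

test_that("cluster assignments are invariant to sample order", {
  ref <- small_reference()
  coh <- simulate_bulk_cohort(ref, "somatotroph", rep(c(0, 0.5), each = 4),
                              reads_per_sample = 1e6, seed = 17)
  logm <- log_transform(bulk_cpm(coh$counts), "10")
  hc <- hclust_samples(logm)
  perm <- withr::with_seed(5, sample(ncol(logm)))
  hc_p <- hclust_samples(logm[, perm])
  cl <- cutree(hc, 2)
  cl_p <- cutree(hc_p, 2)[names(cl)]
  # same partition up to label swapping
  expect_equal(length(unique(paste(cl, cl_p))), 2)
})

test_that("flag_discordant applies the majority-lineage rule", {
  # three tight lineage blocks, one sample sitting in the wrong block
  set.seed(11)
  g <- sprintf("g%02d", 1:40)
  block <- function(center, n, label) {
    m <- matrix(rnorm(40 * n, center, 0.1), 40, n)
    colnames(m) <- paste0(label, seq_len(n))
    m
  }
  m <- cbind(block(c(rep(10, 20), rep(0, 20)), 5, "pit"),
             block(c(rep(0, 20), rep(10, 20)), 5, "tpit"),
             block(rep(5, 40), 5, "sf"))
  rownames(m) <- g
  lineages <- setNames(rep(c("PIT1", "TPIT", "SF1"), each = 5), colnames(m))
  hc <- hclust_samples(m)
  flags <- flag_discordant(hc, lineages, k = 3)
  expect_false(any(flags$flagged))

  # move one TPIT sample into the PIT1 block: it must be flagged
  lineages2 <- lineages
  lineages2["pit3"] <- "TPIT"
  flags2 <- flag_discordant(hc, lineages2, k = 3)
  expect_true(flags2$flagged[flags2$sample == "pit3"])
  expect_equal(sum(flags2$flagged), 1)

  # all samples identical: one cluster, flags only when lineages mix
  same <- matrix(7, 40, 6,
                 dimnames = list(g, sprintf("s%d", 1:6)))
  hc_same <- hclust_samples(same)
  f_same <- flag_discordant(hc_same, setNames(rep("PIT1", 6),
                                              colnames(same)), k = 1)
  expect_false(any(f_same$flagged))
})
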