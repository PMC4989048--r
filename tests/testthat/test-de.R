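test_that("median-of-ratios size factors match direct evaluation", {
  m <- matrix(c(2, 4, 8, 16), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors_median_of_ratios(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-3)

  # identical columns give unit factors
  m2 <- cbind(s1 = c(5, 10, 3), s2 = c(5, 10, 3))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors_median_of_ratios(m2)), c(1, 1))

  # scaling one sample scales its factor, up to the shared reference
  m3 <- matrix(rpois(60, 50) + 1, nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sf3 <- size_factors_median_of_ratios(m3)
  m3b <- m3; m3b[, 2] <- m3[, 2] * 4
  sf3b <- size_factors_median_of_ratios(m3b)
  expect_equal(unname(sf3b[2] / sf3[2]), unname(4 * (sf3b[1] / sf3[1])),
               tolerance = 1e-9)

  expect_error(size_factors_median_of_ratios(
    matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))),
    class = "unestimable_factor")
})

test_that("low-expression filter keeps genes at or above the threshold", {
  set.seed(1)
  m <- matrix(rpois(40, 20), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
  m[3, ] <- 0                      # all-zero gene
  m[c(5, 7, 9), ] <- c(0, 1, 0, 1) # low genes
  meta <- data.frame(sample = paste0("s", 1:4), patient = c("p1", "p1", "p2", "p2"),
                     site = c("DMC", "PLC", "DMC", "PLC"))
  cm <- count_matrix(m, meta)
  expect_equal(nrow(filter_low_expression(cm, 0)$counts), 10)  # identity
  f <- filter_low_expression(cm, 2)
  expect_false("g03" %in% rownames(f$counts))
  expect_equal(nrow(f$counts), 6)
  expect_equal(rownames(f$counts), sort(rownames(f$counts)))  # order preserved
  expect_error(filter_low_expression(cm, -1), class = "invalid_parameter")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.37, 5)), rep(0.37, 5))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "invalid_parameter")
})

test_that("control-gene selection drops the most significant genes deterministically", {
  de <- data.frame(gene = sprintf("g%02d", 1:10),
                   pvalue = c(0.5, 0.01, 0.3, 0.01, 0.9, 0.2, 0.05, NA, 0.7, 0.6))
  class(de) <- c("de_result", "data.frame")
  ctrl <- select_control_genes(de, 3)
  expect_equal(length(ctrl), 7)
  # ties at p = 0.01 broken by gene id: g02 then g04 excluded, then g07
  expect_false(any(c("g02", "g04", "g07") %in% ctrl))
  expect_true("g08" %in% ctrl)  # NA p ranks last, stays a control
  expect_equal(select_control_genes(de, 0), sort(de$gene))
  expect_error(select_control_genes(de, 10), class = "invalid_parameter")
})

test_that("unwanted-variation factors recover a planted rank-1 batch pattern", {
  set.seed(11)
  n_g <- 60; n_s <- 8
  pattern <- c(rep(1, 4), rep(-1, 4))
  loading <- runif(n_g, 0.5, 2)
  z <- outer(loading, pattern)              # exact rank-1 log-scale structure
  counts <- round(2^(z + 7))
  dimnames(counts) <- list(sprintf("g%02d", 1:n_g), paste0("s", 1:n_s))
  meta <- data.frame(sample = paste0("s", 1:n_s),
                     patient = rep(paste0("p", 1:4), each = 2),
                     site = rep(c("DMC", "PLC"), 4))
  cm <- count_matrix(counts, meta)
  uf <- estimate_unwanted_factors(cm, rownames(counts), k = 2)
  expect_gt(abs(cor(uf$w[, 1], pattern)), 0.99)
  # rank-1 structure: second singular value is negligible
  expect_lt(uf$singular_values[2] / uf$singular_values[1], 0.05)

  # constant control counts give zero factor scores after centring
  cm2 <- count_matrix(matrix(20, n_g, n_s,
                             dimnames = dimnames(counts)), meta)
  uf2 <- estimate_unwanted_factors(cm2, rownames(counts), k = 1)
  expect_equal(max(abs(uf2$w)), 0, tolerance = 1e-12)

  expect_error(estimate_unwanted_factors(cm, rownames(counts), k = 100),
               class = "invalid_parameter")
  expect_error(estimate_unwanted_factors(cm, character(0), k = 1),
               class = "invalid_parameter")
})

test_that("paired NB Wald fit: no-signal genes are null, library scaling is absorbed", {
  cm <- noiseless_counts()
  de <- nb_wald_paired_test(cm)
  # genes with identical site patterns: log2FC ~ 0, p large
  expect_equal(de$log2FoldChange[de$gene == "g1"], 0, tolerance = 1e-6)
  expect_gt(de$pvalue[de$gene == "g1"], 0.5)
  # planted exact 2-fold genes are estimated at log2FC = 1
  expect_equal(de$log2FoldChange[de$gene == "g2"], 1, tolerance = 1e-6)

  # multiplying one sample's column leaves log2FC invariant
  cm2 <- cm
  cm2$counts[, 1] <- cm2$counts[, 1] * 3
  de2 <- nb_wald_paired_test(cm2)
  expect_equal(de2$log2FoldChange, de$log2FoldChange, tolerance = 1e-6)

  # non-paired metadata is rejected
  bad_meta <- cm$meta
  bad_meta$site[1] <- "PLC"
  expect_error(count_matrix(cm$counts, bad_meta), class = "design_error")
})

test_that("all-zero genes get missing statistics and padj respects p ordering", {
  cm <- noiseless_counts()
  m <- rbind(cm$counts, gz = 0)
  cm2 <- count_matrix(m, cm$meta)
  de <- nb_wald_paired_test(cm2)
  expect_true(is.na(de$pvalue[de$gene == "gz"]))
  expect_true(is.na(de$log2FoldChange[de$gene == "gz"]))
  ok <- !is.na(de$pvalue)
  expect_true(all(de$padj[ok] >= de$pvalue[ok] - 1e-12))
})

test_that("DEG calling uses inclusive fold-change and adjusted-p bounds", {
  de <- data.frame(
    gene = paste0("g", 1:6),
    baseMean = 100,
    log2FoldChange = c(log2(1.5), 1, -1, -log2(1.5), 0.1, 2),
    stat = 0,
    pvalue = 0.01,
    padj = c(0.1, 0.05, 0.05, 0.1, 0.01, 0.5))
  class(de) <- c("de_result", "data.frame")
  cl <- call_degs(de, 1.5, 0.1)
  expect_equal(sort(cl$up), c("g1", "g2"))   # g1: exactly FC 1.5, padj 0.1
  expect_equal(sort(cl$down), c("g3", "g4")) # g4: boundary included
  expect_equal(length(intersect(cl$up, cl$down)), 0)
  # empty input
  cl0 <- call_degs(de[0, ], 1.5, 0.1)
  expect_equal(lengths(cl0), c(up = 0L, down = 0L))
  expect_error(call_degs(de, 0.9, 0.1), class = "invalid_parameter")
})

test_that("DEG summary reproduces the headline arithmetic", {
  s <- deg_summary(830, 745, 17160)
  expect_equal(s$n_total, 1575)
  expect_equal(s$pct_up, 4.8)
  expect_equal(s$pct_down, 4.3)
  s2 <- deg_summary(character(0), character(0), 100)
  expect_equal(c(s2$n_total, s2$pct_up, s2$pct_down), c(0, 0, 0))
  s3 <- deg_summary(5, 5, 100)
  expect_equal(c(s3$n_total, s3$pct_up, s3$pct_down), c(10, 5, 5))
  expect_error(deg_summary(5, 5, 0), class = "invalid_parameter")
})

test_that("FPKM follows the per-kilobase per-million definition", {
  m <- matrix(c(100, 1e6 - 100, 0, 1e6), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- fpkm(m, c(1000, 50000))
  expect_equal(f["g1", "s1"], 100)                  # 1 kb gene, 1 M library
  expect_equal(f["g2", "s1"], (1e6 - 100) / 50 / 1)
  expect_equal(f["g1", "s2"], 0)                    # zero count stays zero
  # doubling the library (extra reads on another gene) halves FPKM
  m3 <- rbind(m, filler = colSums(m))
  f3 <- fpkm(m3, c(1000, 50000, 1000))
  expect_equal(unname(f3["g1", "s1"]), unname(f["g1", "s1"]) / 2)
  expect_error(fpkm(m, c(0, 100)), class = "invalid_input")
})

test_that("2^-ddCt relative expression matches hand evaluation", {
  expect_equal(ddct_relative_expression(c(20, 20), c(18, 19), c(18, 19))$relative_expression, 1)
  # one cycle earlier in damaged with constant references doubles expression
  expect_equal(ddct_relative_expression(c(19, 20), c(18, 18), c(18, 18))$relative_expression, 2)
  # averaged reference pair: target 24/25, refs (20,22)/(20,22) -> ddCt = -1
  r <- ddct_relative_expression(c(damaged = 24, intact = 25),
                                c(20, 22), c(20, 22))
  expect_equal(r$ddct, -1)
  expect_equal(r$relative_expression, 2)
  expect_error(ddct_relative_expression(c(20, NA), 18, 18), class = "invalid_input")
})

test_that("unwanted-factor correction reduces batch-driven p-value inflation", {
  # batch confounded with half the genes; patients split across batches
  cfg <- sim_config(n_patients = 8, n_genes = 600, de_fraction = 0,
                    batch_gene_fraction = 0.5, batch_log2_shift = 2, seed = 19)
  sim <- simulate_paired_counts(cfg)
  # corrupt pairing of batch with a hidden sample-level factor: scale half
  # the DMC samples to mimic an unmodelled technical shift on batch genes
  m <- sim$counts$counts
  bg <- sim$truth$gene[sim$truth$is_batch_affected]
  odd_dmc <- sim$counts$meta$sample[sim$counts$meta$site == "DMC"][c(1, 3, 5, 7)]
  m[bg, odd_dmc] <- round(m[bg, odd_dmc] * 4)
  cm <- count_matrix(m, sim$counts$meta)
  plain <- nb_wald_paired_test(cm)
  ctrl <- select_control_genes(plain, 150)
  uf <- estimate_unwanted_factors(cm, ctrl, k = 1)
  corrected <- nb_wald_paired_test(cm, uf = uf)
  frac_plain <- mean(plain$pvalue < 0.05, na.rm = TRUE)
  frac_corr <- mean(corrected$pvalue < 0.05, na.rm = TRUE)
  expect_lt(frac_corr, frac_plain)
})
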