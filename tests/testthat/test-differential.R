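# Size factors, dispersion estimation, the NB GLM interaction, BH, the
# regulation calls and extreme-set selection.

test_that("median-of-ratios size factors behave on constructed matrices", {
  samples <- tibble::tibble(
    sample_id = c("RNA_a", "RNA_b", "RPF_a", "RPF_b"),
    assay = c("RNA", "RNA", "RPF", "RPF")
  )
  base <- c(10, 100, 1000, 50, 500)
  counts <- tibble::tibble(
    feature_id = sprintf("f%d", 1:5),
    RNA_a = base, RNA_b = base, RPF_a = base, RPF_b = base
  )
  sf <- size_factors(counts, samples)
  expect_equal(sf$size_factor, rep(1, 4))

  # doubling one column doubles its factor
  counts2 <- dplyr::mutate(counts, RNA_b = RNA_b * 2)
  sf2 <- size_factors(counts2, samples)
  expect_equal(sf2$size_factor[sf2$sample_id == "RNA_b"] /
                 sf2$size_factor[sf2$sample_id == "RNA_a"], 2)

  # all-zero rows do not perturb the factors
  counts3 <- dplyr::bind_rows(counts, tibble::tibble(feature_id = "z",
                                                     RNA_a = 0, RNA_b = 0,
                                                     RPF_a = 0, RPF_b = 0))
  expect_equal(size_factors(counts3, samples)$size_factor,
               sf$size_factor)

  # no all-positive feature: total-count fallback with a warning
  counts4 <- tibble::tibble(feature_id = c("f1", "f2"),
                            RNA_a = c(0, 10), RNA_b = c(10, 0),
                            RPF_a = c(5, 5), RPF_b = c(5, 5))
  expect_warning(size_factors(counts4, samples), "total-count")
})

test_that("the GLM interaction recovers the ratio of ratios", {
  assay <- rep(c("RNA", "RNA", "RPF", "RPF"), 2)
  condition <- rep(c("A", "B"), each = 4)
  sf <- rep(1, 8)

  # symmetric counts: interaction is numerically zero
  fit0 <- fit_nb_glm(rep(500, 8), assay, condition, sf, alpha = 0,
                     reference = "A")
  expect_lt(abs(fit0$log2_dte), 1e-6)

  # RPF x4 in condition B only: interaction -> log2(4) = 2 exactly in the
  # saturated 2x2 design (MLE matches the ratio of ratios)
  y <- c(1000, 1000, 1000, 1000, 1000, 1000, 4000, 4000)
  fit4 <- fit_nb_glm(y, assay, condition, sf, alpha = 1e-8, reference = "A")
  expect_equal(fit4$log2_dte, 2, tolerance = 1e-6)

  # swapping assay labels negates the interaction
  swapped <- ifelse(assay == "RNA", "RPF", "RNA")
  fit_sw <- fit_nb_glm(y, swapped, condition, sf, alpha = 1e-8,
                       reference = "A")
  expect_equal(fit_sw$log2_dte, -fit4$log2_dte, tolerance = 1e-6)
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  po <- simulate_te_matrix(300, alpha = 0, seed = 31)
  d0 <- estimate_dispersion(po$counts, po$samples)
  expect_lte(median(d0$alpha), 0.01)

  nb <- simulate_te_matrix(300, alpha = 0.1, seed = 32)
  d1 <- estimate_dispersion(nb$counts, nb$samples)
  expect_gte(median(d1$alpha), 0.05)
  expect_lte(median(d1$alpha), 0.2)

  # a single feature falls back to the pooled dispersion with a warning
  one <- po$counts[1, ]
  expect_warning(estimate_dispersion(one, po$samples), "pooled")
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(brute_force_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), brute_force_bh(p))
  }
})

test_that("delta_te_test filters low-count features and rejects bad designs", {
  sim <- simulate_te_matrix(60, mu_range = c(100, 200), seed = 51)
  # force one feature's mRNA counts below the filter (mean 9.5)
  rna_cols <- sim$samples$sample_id[sim$samples$assay == "RNA"]
  sim$counts[1, rna_cols] <- as.list(c(9L, 10L, 9L, 10L))
  fit <- delta_te_test(sim$counts, sim$samples, c("30", "20"))
  expect_equal(fit$results$status[1], "low_count")
  expect_true(is.na(fit$results$wald_p[1]))
  expect_true(all(fit$results$status[-1] == "ok"))
  # q-values reproduce BH on the tested features' p-values
  ok <- fit$results$status == "ok"
  expect_equal(fit$results$q[ok], brute_force_bh(fit$results$wald_p[ok]))

  # a missing assay/condition combination is a hard error
  broken <- dplyr::filter(sim$samples,
                          !(.data$assay == "RPF" & .data$condition == "20"))
  expect_error(delta_te_test(sim$counts, broken, c("30", "20")),
               "missing assay/condition")

  # tidy/glance accessors
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true("contrast" %in% names(td))
  gl <- generics::glance(fit)
  expect_equal(gl$n_features, 60L)
  expect_equal(gl$n_tested + gl$n_low_count + gl$n_outlier, 60L)
})

test_that("the interaction agrees with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_te_matrix(80, mu_range = c(200, 500), alpha = 0.02,
                            effect_log2 = rep(c(0, 1.5), 40), seed = 61)
  fit <- delta_te_test(sim$counts, sim$samples, c("30", "20"))

  m <- as.matrix(sim$counts[, sim$samples$sample_id])
  rownames(m) <- sim$counts$feature_id
  storage.mode(m) <- "integer"
  coldata <- data.frame(
    assay = factor(sim$samples$assay, levels = c("RNA", "RPF")),
    condition = factor(sim$samples$condition, levels = c("30", "20"))
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, ~ assay * condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, name = "assayRPF.condition20")
  ours <- fit$results$log2_dte
  theirs <- res$log2FoldChange
  expect_gt(cor(ours, theirs), 0.99)
  expect_lt(median(abs(ours - theirs)), 0.1)
})

test_that("regulation calls follow the dual fold + FDR criteria", {
  mk_res <- function(ids, l2, q, type) {
    tibble::tibble(feature_id = ids, feature_type = type, base_mean = 100,
                   log2_dte = l2, se = 0.1, wald_p = q, q = q, status = "ok")
  }
  uorfs <- tibble::tibble(uorf_id = c("u1", "u2", "u3"),
                          transcript_id = c("t1", "t2", "t3"))
  # (dte_uorf, dte_morf, q): (2.5, 1.1, .05) -> activated;
  # (2.5, 1.6, .05) -> unchanged (relative 1.56 < 2); (0.4, 0.9, .02) -> repressed
  ur <- mk_res(c("u1", "u2", "u3"), log2(c(2.5, 2.5, 0.4)),
               c(0.05, 0.05, 0.02), "uorf")
  mr <- mk_res(paste0(c("t1", "t2", "t3"), "_morf"), log2(c(1.1, 1.6, 0.9)),
               c(0.5, 0.5, 0.5), "morf")
  calls <- classify_regulation(ur, mr, uorfs)
  expect_equal(calls$class, c("activated", "unchanged", "repressed"))
  expect_equal(calls$d_relative_te, c(2.5 / 1.1, 2.5 / 1.6, 0.4 / 0.9),
               tolerance = 1e-12)

  # a failed uORF or mORF test propagates low_count
  ur2 <- dplyr::mutate(ur, status = c("low_count", "ok", "ok"))
  calls2 <- classify_regulation(ur2, mr, uorfs)
  expect_equal(calls2$class[1], "low_count")

  # the FDR gate applies to the uORF q only
  ur3 <- dplyr::mutate(ur, q = c(0.2, 0.05, 0.02))
  expect_equal(classify_regulation(ur3, mr, uorfs)$class[1], "unchanged")
})

test_that("extreme sets are disjoint, ordered, and size-checked", {
  set.seed(71)
  res <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:300), feature_type = "uorf",
    base_mean = 100, log2_dte = rnorm(300), se = 0.1,
    wald_p = runif(300), q = runif(300), status = "ok"
  )
  ex <- select_extremes(res, n = 100)
  expect_equal(nrow(ex$te_up), 100)
  expect_equal(nrow(ex$te_down), 100)
  expect_length(intersect(ex$te_up$feature_id, ex$te_down$feature_id), 0)
  expect_gte(min(ex$te_up$log2_dte), max(res$log2_dte[!res$feature_id %in%
    c(ex$te_up$feature_id, ex$te_down$feature_id)]))
  expect_error(select_extremes(res, n = 200), "at least 2n")

  # deterministic tie-breaking: ties resolved by p then id
  tied <- dplyr::mutate(res, log2_dte = rep(1:10, 30),
                        wald_p = rep(seq(0.1, 1, 0.1), each = 30))
  ex1 <- select_extremes(tied, n = 100)
  ex2 <- select_extremes(dplyr::slice_sample(tied, prop = 1), n = 100)
  expect_equal(dplyr::arrange(ex1$te_up, .data$feature_id),
               dplyr::arrange(ex2$te_up, .data$feature_id))
})

test_that("the isoform-confound diagnostic attributes TE changes to RPF", {
  set.seed(81)
  n <- 150
  d_rpf <- rnorm(n)
  d_mrna <- rnorm(n)
  dte <- d_rpf + rnorm(n, sd = 0.2) # TE driven purely by RPF changes
  d_utr5 <- rnorm(n)
  out <- check_utr_isoform_confound(dte, d_rpf, d_mrna, d_utr5)
  expect_gt(out$rho[out$term == "d_rpf"], 0.8)
  expect_lt(abs(out$rho[out$term == "d_mrna"]), 0.2)
  expect_lt(abs(out$rho[out$term == "d_mrna_utr5"]), 0.2)

  ident <- check_utr_isoform_confound(dte, dte, -dte, d_utr5)
  expect_equal(ident$rho[1], 1)
  expect_equal(ident$rho[2], -1)
})
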