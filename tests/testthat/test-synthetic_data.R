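# The synthetic-data generator: determinism, bookkeeping, and the moments of
# its negative-binomial signal model.

test_that("the same seed reproduces the transcriptome byte for byte", {
  cfg <- sim_config(n_transcripts = 20L)
  dir <- withr::local_tempdir()
  paths <- function(tag) {
    list(fa = file.path(dir, paste0(tag, ".fa")),
         gff = file.path(dir, paste0(tag, ".gff3")))
  }
  s1 <- simulate_transcriptome(config = cfg, seed = 99)
  s2 <- simulate_transcriptome(config = cfg, seed = 99)
  p1 <- paths("a"); p2 <- paths("b")
  write_transcriptome(s1$transcripts, p1$fa, p1$gff)
  write_transcriptome(s2$transcripts, p2$fa, p2$gff)
  expect_identical(readLines(p1$fa), readLines(p2$fa))
  expect_identical(readLines(p1$gff), readLines(p2$gff))
  expect_identical(s1$truth, s2$truth)

  sheet <- sim_sample_sheet(cfg)
  c1 <- simulate_counts(s1, sheet, seed = 7)
  c2 <- simulate_counts(s2, sheet, seed = 7)
  expect_identical(c1$tracks, c2$tracks)
  expect_identical(c1$samples, c2$samples)
})

test_that("planted-uORF bookkeeping matches the configured fraction", {
  cfg <- sim_config(n_transcripts = 200L, fraction_with_uorf = 0.5)
  sim <- simulate_transcriptome(config = cfg, seed = 3)
  expect_equal(nrow(sim$transcripts), 200)
  expect_equal(nrow(sim$truth$uorfs), 100)
  # planted uORFs are recovered verbatim by USS enumeration
  uss <- enumerate_uss(sim$transcripts)
  key_uss <- paste(uss$transcript_id, uss$start_pos, uss$end_pos, uss$n_codons)
  key_tru <- paste(sim$truth$uorfs$transcript_id, sim$truth$uorfs$start_pos,
                   sim$truth$uorfs$end_pos, sim$truth$uorfs$n_codons)
  expect_true(all(key_tru %in% key_uss))

  none <- simulate_transcriptome(config = sim_config(n_transcripts = 20L,
                                                     fraction_with_uorf = 0),
                                 seed = 3)
  expect_equal(nrow(none$truth$uorfs), 0)
})

test_that("an infeasible uORF/UTR geometry is rejected", {
  expect_error(
    simulate_transcriptome(config = sim_config(utr5_len_range = c(20L, 30L),
                                               uorf_codons_range = c(10L, 12L)),
                           seed = 1),
    "infeasible"
  )
})

# hand-built single-transcript simulation harness: geometry and truth are
# fixed so the expectations of the generative model are known exactly
manual_sim <- function(L = 12000L, utr5 = 300L, abundance = 2,
                       uorf = NULL, morf_te = 1, uorf_te = 1,
                       alpha = 0.05, conditions = "30", uorf_te_by_cond = NULL) {
  tx <- tibble::tibble(transcript_id = "m1", seq = NA_character_,
                       utr5_len = utr5, cds_start = utr5,
                       cds_end = L - (L - utr5) %% 3L, length = L)
  cfg <- sim_config(alpha = alpha, conditions = conditions,
                    reference_condition = conditions[1])
  uorfs <- if (is.null(uorf)) {
    tibble::tibble(uorf_id = character(), transcript_id = character(),
                   start_pos = integer(), end_pos = integer(),
                   n_codons = integer(), codon = character())
  } else {
    tibble::tibble(uorf_id = "m1_u", transcript_id = "m1",
                   start_pos = uorf[1], end_pos = uorf[2],
                   n_codons = (uorf[2] - uorf[1]) %/% 3L, codon = "AUG")
  }
  te_tbl <- tidyr::expand_grid(uorf_id = uorfs$uorf_id,
                               condition = conditions) |>
    dplyr::mutate(te = if (is.null(uorf_te_by_cond)) uorf_te
                  else uorf_te_by_cond[.data$condition])
  list(transcripts = tx,
       truth = list(
         uorfs = uorfs,
         uorf_te = te_tbl,
         morf_te = tidyr::expand_grid(transcript_id = "m1",
                                      condition = conditions) |>
           dplyr::mutate(te = morf_te),
         abundance = tidyr::expand_grid(transcript_id = "m1",
                                        condition = conditions) |>
           dplyr::mutate(abundance = abundance),
         config = cfg
       ))
}

test_that("simulated RNA counts match the NB mean and variance", {
  sim <- manual_sim(alpha = 0.2, abundance = 5)
  sheet <- tibble::tibble(sample_id = "RNA_30_1", assay = "RNA",
                          condition = "30", replicate = 1L,
                          library_size = 2e6)
  cnt <- simulate_counts(sim, sheet, seed = 11)
  # dense vector over the 5'-UTR + CDS (uniform expectation mu = 5 * 2 = 10)
  v <- numeric(12000)
  v[cnt$tracks$pos + 1] <- cnt$tracks$count
  mu <- 5 * 2
  alpha <- 0.2
  n <- length(v)
  expect_lt(abs(mean(v) - mu), 3 * sqrt((mu + alpha * mu^2) / n))
  # variance within Monte-Carlo error (chi-square-ish spread on 1.2e4 draws)
  expect_lt(abs(var(v) / (mu + alpha * mu^2) - 1), 0.1)
})

test_that("RPF frame fractions over a planted uORF match the frame weights", {
  sim <- manual_sim(alpha = 0, abundance = 400, uorf = c(60L, 120L),
                    uorf_te = 2)
  sheet <- tibble::tibble(sample_id = "RPF_30_1", assay = "RPF",
                          condition = "30", replicate = 1L,
                          library_size = 2e6)
  cnt <- simulate_counts(sim, sheet, seed = 12)
  v <- numeric(12000)
  v[cnt$tracks$pos + 1] <- cnt$tracks$count
  body <- v[61:120]
  fr <- tapply(body, (seq_along(body) - 1) %% 3, sum)
  w_hat <- as.numeric(fr / sum(fr))
  expect_true(all(abs(w_hat - c(0.70, 0.20, 0.10)) < 0.02))
})

test_that("a planted 4-fold TE change shows up as a 4-fold RPF ratio", {
  sim <- manual_sim(alpha = 0, abundance = 100, uorf = c(60L, 120L),
                    conditions = c("A", "B"),
                    uorf_te_by_cond = c(A = 1, B = 4))
  sheet <- tibble::tibble(sample_id = c("RPF_A_1", "RPF_B_1"),
                          assay = "RPF", condition = c("A", "B"),
                          replicate = 1L, library_size = 2e6)
  cnt <- simulate_counts(sim, sheet, seed = 13)
  sums <- cnt$tracks |>
    dplyr::filter(.data$pos >= 60, .data$pos < 120) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = sum(.data$count))
  ratio <- sums$n[sums$sample_id == "RPF_B_1"] /
    sums$n[sums$sample_id == "RPF_A_1"]
  expect_lt(abs(ratio - 4), 0.25)
})

test_that("a zero library size yields empty tracks", {
  sim <- manual_sim()
  sheet <- tibble::tibble(sample_id = "RNA_30_1", assay = "RNA",
                          condition = "30", replicate = 1L, library_size = 0)
  cnt <- simulate_counts(sim, sheet, seed = 1)
  expect_equal(nrow(cnt$tracks), 0)
  expect_equal(cnt$samples$library_size, 0)
})

test_that("unknown assay labels are rejected", {
  sim <- manual_sim()
  sheet <- tibble::tibble(sample_id = "X_1", assay = "CHIP", condition = "30",
                          replicate = 1L, library_size = 1e6)
  expect_error(simulate_counts(sim, sheet, seed = 1), "unknown assay")
})
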