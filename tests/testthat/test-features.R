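# Positional annotation, the context PWM, Spearman correlation, quadrants
# and notched-boxplot summaries.

test_that("positional annotation is simple transcript arithmetic", {
  tx <- tibble::tibble(transcript_id = c("t1", "t2"), seq = "N",
                       utr5_len = c(60L, 40L), cds_start = c(60L, 40L),
                       cds_end = c(120L, 100L), length = c(150L, 130L))
  uorfs <- tibble::tibble(transcript_id = c("t1", "t2"),
                          start_pos = c(10L, 0L), end_pos = c(40L, 12L))
  ann <- annotate_uorfs(uorfs, tx)
  expect_equal(ann$cap_distance, c(10L, 0L))
  expect_equal(ann$maug_distance, c(50L, 40L))
  expect_equal(ann$uorf_len, c(30L, 12L))
  expect_equal(ann$utr5_len, c(60L, 40L))
  # the two distances always partition the 5'-UTR
  expect_equal(ann$cap_distance + ann$maug_distance, ann$utr5_len)

  # round-trip through TSV preserves the annotation
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ann, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(ann))

  expect_error(annotate_uorfs(dplyr::mutate(uorfs, transcript_id = "nope"),
                              tx), "unknown transcript")
})

test_that("the context model learns base frequencies from top-load mORFs", {
  # 25 transcripts whose context window is all A
  mk <- function(i, ctx_base) {
    utr <- strrep(ctx_base, 10)
    tibble::tibble(transcript_id = sprintf("t%02d", i),
                   seq = paste0(utr, "AUG", strrep(ctx_base, 3),
                                strrep("GCA", 3), "UAA"),
                   utr5_len = 10L, cds_start = 10L, cds_end = 25L,
                   length = nchar(utr) + 15L)
  }
  tx <- dplyr::bind_rows(lapply(1:25, mk, ctx_base = "A"))
  load_tbl <- tibble::tibble(transcript_id = tx$transcript_id, load = 1)
  model <- build_context_model(tx, load_tbl, top_fraction = 1)
  expect_gt(min(model$freq["A", ]), 0.85)

  # uniform reference contexts give ~0.25 everywhere; the score of any
  # context under a uniform model is 0
  set.seed(91)
  mk_rand <- function(i) {
    s <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
               collapse = "")
    tibble::tibble(transcript_id = sprintf("r%03d", i), seq = s,
                   utr5_len = 20L, cds_start = 20L, cds_end = 38L,
                   length = 40L)
  }
  txr <- dplyr::bind_rows(lapply(1:400, mk_rand))
  loadr <- tibble::tibble(transcript_id = txr$transcript_id, load = runif(400))
  mr <- build_context_model(txr, loadr, top_fraction = 1)
  expect_true(all(abs(mr$freq - 0.25) < 0.08))

  uniform <- list(freq = matrix(0.25, 4, 9,
                                dimnames = list(c("A", "C", "G", "U"), NULL)))
  expect_equal(context_score("AAAAAAAAA", uniform), 0)
  expect_equal(context_score("NNNNNNNNN", model), 0) # N contributes nothing

  # too small a reference set is rejected
  expect_error(build_context_model(tx[1:5, ], load_tbl[1:5, ],
                                   top_fraction = 1), ">= 20")

  # the top-2% ranking actually selects the highest-load transcripts
  loadx <- dplyr::mutate(loadr, load = as.numeric(readr::parse_number(
    sub("r", "", transcript_id))))
  m_top <- build_context_model(txr, loadx, top_fraction = 0.05)
  expect_equal(m_top$n_reference, 20)
})

test_that("context windows are N-padded at the cap and scored additively", {
  tx <- tibble::tibble(transcript_id = "t1",
                       seq = paste0("ACGUACGUAC", "AUG", "GCAGCA", "UAA"),
                       utr5_len = 10L, cds_start = 10L, cds_end = 22L,
                       length = 22L)
  # start at 2: positions -6..-3 are upstream of the cap -> N
  ctx <- extract_context(tx, "t1", 2L)
  expect_equal(substr(ctx, 1, 4), "NNNN")
  expect_equal(nchar(ctx), 9L)
  # start at the mAUG: full window from the sequence
  # start at the mAUG: -6..-1 = ACGUAC, +4..+6 = GCA (first codon after AUG)
  ctx2 <- extract_context(tx, "t1", 10L)
  expect_equal(ctx2, "ACGUACGCA")
})

test_that("spearman matches the mid-rank Pearson oracle and sign conventions", {
  s1 <- spearman(1:20, (1:20)^2)
  expect_equal(s1$rho, 1)
  expect_lt(s1$p, 1e-6)
  expect_equal(spearman(1:20, -(1:20))$rho, -1)

  # tie handling: rho equals Pearson on mid-ranks
  x <- c(1, 2, 2, 4, 5, 7, 7, 7, 9, 10, 3, 6)
  y <- c(1, 3, 2, 4, 4, 8, 6, 7, 9, 12, 2, 6)
  expect_equal(spearman(x, y)$rho, stats::cor(rank(x), rank(y)))

  # small samples use a seeded permutation p
  s2 <- spearman(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(s2$method, "permutation")
  expect_equal(s2$rho, stats::cor(rank(c(1, 2, 2, 4)), rank(c(1, 3, 2, 4))))
  s2b <- spearman(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_identical(s2$p, s2b$p) # deterministic given the fixed seed

  expect_error(spearman(1:3, 1:3), ">= 4")
})

test_that("quadrants classify sign patterns with an on-axis flag", {
  q <- quadrant(c(0.5, 2, 2, 0.5, 1), c(2, 2, 0.5, 0.5, 2))
  expect_equal(q$quadrant, c("Q1", "Q2", "Q3", "Q4", "Q2"))
  expect_equal(q$on_axis, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # reciprocal folds swap Q1<->Q3 and Q2<->Q4
  set.seed(93)
  lo <- exp(rnorm(200)); hi <- exp(rnorm(200))
  off_axis <- lo != 1 & hi != 1
  q1 <- quadrant(lo, hi)$quadrant[off_axis]
  q2 <- quadrant(1 / lo, 1 / hi)$quadrant[off_axis]
  map <- c(Q1 = "Q3", Q2 = "Q4", Q3 = "Q1", Q4 = "Q2")
  expect_equal(unname(map[q1]), q2)

  expect_error(quadrant(-1, 2), "> 0")
})

test_that("group summaries reproduce the notch formula and quartile oracle", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5), g = "a")
  s <- bin_by_class(d, v, g)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(s$notch, 1.58 * 2 / sqrt(5))

  # quartiles match sort-and-interpolate on random groups
  set.seed(94)
  d2 <- tibble::tibble(v = rnorm(101), g = sample(c("a", "b"), 101, TRUE))
  s2 <- bin_by_class(d2, v, g)
  for (grp in c("a", "b")) {
    vals <- d2$v[d2$g == grp]
    expect_equal(s2$q1[s2$group == grp], brute_force_quartile(vals, 0.25))
    expect_equal(s2$q3[s2$group == grp], brute_force_quartile(vals, 0.75))
  }

  # identical groups get identical summaries; singletons are flagged
  d3 <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  s3 <- bin_by_class(d3, v, g)
  expect_equal(s3$median[1], s3$median[2])
  expect_equal(s3$notch[1], s3$notch[2])
  s4 <- bin_by_class(tibble::tibble(v = 1, g = "solo"), v, g)
  expect_true(s4$degenerate)
})
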