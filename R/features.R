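# uORF feature annotation (positions, lengths, start-codon context), the
# start-context PWM score, Spearman correlation, the temperature-response
# quadrant assignment, and notched-boxplot group summaries.

#' Annotate uORFs with positional and context features
#'
#' Adds cap distance (5' end to start), mAUG distance (start to the main
#' start codon), uORF length and 5'-UTR length; carries through codon and
#' Kozak classes when present; an optional `structure_scores` table (ingested
#' externally, never computed here) is joined by `transcript_id`.
#'
#' @param uorfs USS/uORF tibble (`uorf_id` optional, `transcript_id`,
#'   `start_pos`, `end_pos`).
#' @param transcripts Transcript tibble.
#' @param structure_scores Optional tibble (`transcript_id`,
#'   `structure_score`).
#' @return Annotation tibble with `cap_distance`, `maug_distance`,
#'   `uorf_len`, `utr5_len` and any carried columns.
#' @export
annotate_uorfs <- function(uorfs, transcripts, structure_scores = NULL) {
  if (!"uorf_id" %in% names(uorfs)) {
    uorfs <- dplyr::mutate(uorfs, uorf_id = sprintf("%s_u%d",
                                                    .data$transcript_id,
                                                    .data$start_pos))
  }
  utr5 <- transcripts$utr5_len[match(uorfs$transcript_id,
                                     transcripts$transcript_id)]
  if (anyNA(utr5)) stop("uORF maps to an unknown transcript")
  keep <- intersect(c("codon", "codon_class", "kozak_class",
                      "kozak_truncated"), names(uorfs))
  out <- tibble::tibble(
    uorf_id = uorfs$uorf_id,
    transcript_id = uorfs$transcript_id,
    cap_distance = uorfs$start_pos,
    maug_distance = utr5 - uorfs$start_pos,
    uorf_len = uorfs$end_pos - uorfs$start_pos,
    utr5_len = utr5
  )
  out <- dplyr::bind_cols(out, uorfs[, keep, drop = FALSE])
  if (!is.null(structure_scores)) {
    out <- dplyr::left_join(out, structure_scores, by = "transcript_id")
  }
  out
}

CONTEXT_POSITIONS <- c(-6:-1, 4:6) # relative to the start codon's A = +1

#' Extract the start-codon context window
#'
#' The nucleotides at positions -6..-1 and +4..+6 relative to the start codon
#' (the codon itself excluded), N-padded where the window runs past the 5'
#' end.
#'
#' @param transcripts Transcript tibble.
#' @param transcript_id,start_pos Start-site locations (0-based).
#' @return Character vector of 9-mers over `{A,C,G,U,N}`.
#' @export
extract_context <- function(transcripts, transcript_id, start_pos) {
  seqs <- transcripts$seq[match(transcript_id, transcripts$transcript_id)]
  lens <- nchar(seqs)
  purrr::map_chr(seq_along(seqs), function(i) {
    # 0-based offsets of the window positions
    off <- ifelse(CONTEXT_POSITIONS < 0, start_pos[i] + CONTEXT_POSITIONS,
                  start_pos[i] + CONTEXT_POSITIONS - 1L)
    ch <- ifelse(off >= 0 & off < lens[i],
                 substring(seqs[i], off + 1L, off + 1L), "N")
    paste(ch, collapse = "")
  })
}

#' Build a start-context model from high-ribosome-load mORFs
#'
#' Position-specific base frequencies (pseudocount-smoothed) over the context
#' window, learned from the mORF AUG contexts of the top fraction of
#' transcripts ranked by a ribosome-load metric (in synthetic mode: mORF RPF
#' rpm density).
#'
#' @param transcripts Transcript tibble.
#' @param ribosome_load Tibble (`transcript_id`, `load`).
#' @param top_fraction Fraction of transcripts to use (default 0.02).
#' @param pseudocount Added to every base count (default 1).
#' @return A list of class `context_model`: `freq` (4 x 9 matrix, rows
#'   A/C/G/U, columns the window positions), `n_reference`.
#' @export
build_context_model <- function(transcripts, ribosome_load,
                                top_fraction = 0.02, pseudocount = 1) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  ranked <- dplyr::arrange(ribosome_load, dplyr::desc(.data$load))
  n_top <- max(ceiling(top_fraction * nrow(ranked)), 1L)
  ids <- ranked$transcript_id[seq_len(n_top)]
  ids <- intersect(ids, transcripts$transcript_id)
  if (length(ids) < 20) {
    stop("need >= 20 reference contexts (have ", length(ids), ")")
  }
  tx <- transcripts[match(ids, transcripts$transcript_id), ]
  contexts <- extract_context(tx, tx$transcript_id, tx$cds_start)

  bases <- c("A", "C", "G", "U")
  freq <- matrix(pseudocount, nrow = 4, ncol = length(CONTEXT_POSITIONS),
                 dimnames = list(bases, as.character(CONTEXT_POSITIONS)))
  for (ctx in contexts) {
    ch <- strsplit(ctx, "")[[1]]
    for (j in seq_along(ch)) {
      if (ch[j] %in% bases) freq[ch[j], j] <- freq[ch[j], j] + 1
    }
  }
  freq <- sweep(freq, 2, colSums(freq), "/")
  structure(list(freq = freq, n_reference = length(contexts)),
            class = "context_model")
}

#' Context adaptation score of a start-codon context
#'
#' `sum over positions of log2(f_model(base, pos) / 0.25)`; higher means more
#' similar to the high-load consensus. An `N` (padding) contributes 0.
#'
#' @param context Character vector of 9-mer windows from
#'   [extract_context()].
#' @param model A `context_model` from [build_context_model()].
#' @return Numeric score vector.
#' @export
context_score <- function(context, model) {
  purrr::map_dbl(context, function(ctx) {
    ch <- strsplit(ctx, "")[[1]]
    stopifnot(length(ch) == ncol(model$freq))
    s <- 0
    for (j in seq_along(ch)) {
      if (ch[j] %in% rownames(model$freq)) {
        s <- s + log2(model$freq[ch[j], j] / 0.25)
      }
    }
    s
  })
}

#' Tie-corrected Spearman correlation with p-value
#'
#' The rank correlation computed as Pearson correlation of mid-ranks. For
#' `n >= 10` the p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` df; for smaller samples a
#' seeded permutation test (`n_perm` permutations of `y`) is used instead.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param n_perm Permutations for the small-sample p (default 1e4).
#' @param perm_seed Seed for the permutation p (default 1).
#' @return A list: `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y, n_perm = 1e4, perm_seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need >= 4 complete pairs")
  rho <- stats::cor(rank(x), rank(y))
  if (n >= 10) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    method <- "t-approximation"
  } else {
    rx <- rank(x)
    ry <- rank(y)
    obs <- abs(stats::cor(rx, ry))
    set.seed(perm_seed)
    perm <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    method <- "permutation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Temperature-response quadrant of a uORF
#'
#' Classifies the pair of TE fold changes (low temperature vs reference, high
#' temperature vs reference): Q1 repressed-then-activated, Q2 activated at
#' both, Q3 activated-then-repressed, Q4 repressed at both. A fold change of
#' exactly 1 sits on an axis; it is counted on the activation side and
#' flagged.
#'
#' @param dte_low,dte_high Positive fold changes (e.g. at 20 and 37 vs 30).
#' @return Tibble `quadrant` (`"Q1".."Q4"`) and `on_axis` (logical).
#' @export
quadrant <- function(dte_low, dte_high) {
  stopifnot(all(dte_low > 0), all(dte_high > 0))
  up_low <- dte_low >= 1
  up_high <- dte_high >= 1
  q <- dplyr::case_when(
    !up_low & up_high ~ "Q1",
    up_low & up_high ~ "Q2",
    up_low & !up_high ~ "Q3",
    TRUE ~ "Q4"
  )
  tibble::tibble(quadrant = q, on_axis = dte_low == 1 | dte_high == 1)
}

#' Group summaries for notched boxplots
#'
#' Per group: n, median, quartiles (linear interpolation), IQR, and the notch
#' half-width `1.58 IQR / sqrt(n)` (non-overlapping notches give roughly 95%
#' confidence that two medians differ). Single-element groups are flagged as
#' degenerate.
#'
#' @param data A tibble.
#' @param value Column with the values (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return Tibble `group`, `n`, `median`, `q1`, `q3`, `iqr`, `notch`,
#'   `degenerate`.
#' @export
bin_by_class <- function(data, value, group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median({{ value }}),
      q1 = stats::quantile({{ value }}, 0.25, names = FALSE),
      q3 = stats::quantile({{ value }}, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      notch = 1.58 * .data$iqr / sqrt(.data$n),
      degenerate = .data$n < 2
    )
}
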