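# Two-step translated-uORF identification.
#
# Step 1 (candidate detection) works on raw RPF counts of a combined track:
# a start-codon peak (ratio of counts on the start codon to the 3 nt
# immediately 5' of it > r), a minimum combined count (>= c), a minimum
# fraction of body reads in frame 0 (>= z), and a minimum length in
# sense codons. Step 2 (validation) scores 3-nt periodicity
# (frame-0 fraction f0) and read uniformity across codons (normalized Shannon
# entropy U) and converts them to a translating probability through a fixed
# two-feature logistic; a uORF is called translated when P exceeds the
# probability threshold (strictly).

.as_combined_track <- function(track) {
  if (is.list(track) && !is.data.frame(track) && !is.null(track$track)) {
    track$track
  } else {
    track
  }
}

# dense count vectors per transcript from a sparse combined track
.dense_counts <- function(track, transcripts) {
  track <- .as_combined_track(track)
  lens <- stats::setNames(transcripts$length, transcripts$transcript_id)
  out <- lapply(lens, function(L) integer(L))
  if (nrow(track)) {
    track <- dplyr::filter(track, .data$transcript_id %in% names(lens))
    split_idx <- split(seq_len(nrow(track)), track$transcript_id)
    for (id in names(split_idx)) {
      i <- split_idx[[id]]
      out[[id]][track$pos[i] + 1L] <- out[[id]][track$pos[i] + 1L] +
        as.integer(track$count[i])
    }
  }
  out
}

.window_sum <- function(v, start, end) {
  # [start, end) 0-based on a dense vector; empty window -> 0
  if (end <= start) return(0L)
  sum(v[(start + 1L):end])
}

#' Detect candidate uORFs by start-codon peak and frame criteria
#'
#' Applies the raw-count detection rule to every upstream start site:
#' `plus1 / max(minus1, 1) > r`, `plus1 + minus1 >= c`,
#' `n0 / (n0 + n1 + n2) >= z`, and `n_codons >= min_codons`, where `plus1`
#' is the RPF count on the start codon's three positions, `minus1` the count
#' on the three positions immediately 5' of it (truncated at the cap and
#' flagged when fewer than 3 nt are available), and `n0, n1, n2` the counts
#' downstream of the start codon (positions `start+3 .. end`) by frame
#' relative to the start. Thresholds act on raw counts of the combined
#' track, so detection depends on sequencing depth, not on library-size
#' normalization.
#'
#' @param combined Combined RPF track: either the list from
#'   [combine_tracks()] or a tibble (`transcript_id`, `pos`, `count`).
#' @param uss USS tibble from [enumerate_uss()].
#' @param transcripts Transcript tibble.
#' @param r,c,z,min_codons Detection thresholds (defaults 4, 15, 0.5, 3).
#' @return The `uss` tibble with added columns `plus1`, `minus1`,
#'   `minus1_truncated`, `n0`, `n1`, `n2`, `pass_detection`.
#' @export
detect_candidates <- function(combined, uss, transcripts,
                              r = 4, c = 15, z = 0.5, min_codons = 3L) {
  dense <- .dense_counts(combined, transcripts)
  n <- nrow(uss)
  plus1 <- minus1 <- n0 <- n1 <- n2 <- integer(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    v <- dense[[uss$transcript_id[i]]]
    s <- uss$start_pos[i]
    e <- uss$end_pos[i]
    plus1[i] <- .window_sum(v, s, s + 3L)
    m_start <- max(s - 3L, 0L)
    truncated[i] <- s < 3L
    minus1[i] <- .window_sum(v, m_start, s)
    body <- if (e > s + 3L) v[(s + 4L):e] else integer(0)
    frame <- ((seq_along(body) - 1L) %% 3L)
    n0[i] <- sum(body[frame == 0L])
    n1[i] <- sum(body[frame == 1L])
    n2[i] <- sum(body[frame == 2L])
  }
  tot <- n0 + n1 + n2
  f0 <- ifelse(tot > 0, n0 / tot, 0)
  uss |>
    dplyr::mutate(
      plus1 = plus1, minus1 = minus1, minus1_truncated = truncated,
      n0 = n0, n1 = n1, n2 = n2,
      pass_detection = (plus1 / pmax(minus1, 1) > r) &
        (plus1 + minus1 >= c) &
        (f0 >= z) &
        (.data$n_codons >= min_codons)
    )
}

#' Periodicity and uniformity features of a uORF body
#'
#' For each record, `f0` is the fraction of body RPF reads in frame 0
#' relative to the start, and `uniformity` is the Shannon entropy of
#' per-codon read totals normalized by its maximum `log(n_codons)` — 1 for
#' perfectly even coverage, 0 for a point mass. Records with no body reads
#' get (0, 0).
#'
#' @param combined Combined RPF track (list or tibble).
#' @param uss USS/candidate tibble (`transcript_id`, `start_pos`, `end_pos`,
#'   `n_codons`).
#' @param transcripts Transcript tibble.
#' @return A tibble with columns `f0`, `uniformity`.
#' @export
periodicity_features <- function(combined, uss, transcripts) {
  dense <- .dense_counts(combined, transcripts)
  res <- purrr::pmap(
    list(uss$transcript_id, uss$start_pos, uss$end_pos, uss$n_codons),
    function(id, s, e, nc) {
      body <- dense[[id]][(s + 1L):e]
      frame <- ((seq_along(body) - 1L) %% 3L)
      tot <- sum(body)
      if (tot == 0) return(c(f0 = 0, uniformity = 0))
      f0 <- sum(body[frame == 0L]) / tot
      codon_tot <- tapply(body, (seq_along(body) - 1L) %/% 3L, sum)
      p <- codon_tot[codon_tot > 0] / tot
      H <- -sum(p * log(p))
      U <- if (nc > 1) H / log(nc) else 1
      c(f0 = f0, uniformity = min(U, 1))
    }
  )
  tibble::tibble(
    f0 = purrr::map_dbl(res, "f0"),
    uniformity = purrr::map_dbl(res, "uniformity")
  )
}

#' Translating probability from periodicity features
#'
#' A fixed two-feature logistic `P = plogis(b0 + b1 f0 + b2 U)` mapping the
#' frame-0 fraction and the uniformity to a probability in (0, 1), monotone
#' increasing in both features. The default coefficients (-6, 9, 3) place the
#' aperiodic-but-uniform point (f0 = 1/3, U = 1) exactly at P = 0.5, so a
#' signal with no frame preference never exceeds the default threshold.
#' Coefficients can be recalibrated on labeled data with
#' [fit_probability_coeffs()].
#'
#' @param f0,uniformity Numeric vectors in `[0, 1]`.
#' @param coeffs Numeric length-3 vector `(b0, b1, b2)`.
#' @return Numeric vector of probabilities.
#' @export
translating_probability <- function(f0, uniformity, coeffs = c(-6, 9, 3)) {
  stopifnot(length(coeffs) == 3, all(f0 >= 0 & f0 <= 1),
            all(uniformity >= 0 & uniformity <= 1))
  stats::plogis(coeffs[1] + coeffs[2] * f0 + coeffs[3] * uniformity)
}

#' Recalibrate the translating-probability coefficients
#'
#' Fits the logistic decision surface by binomial regression of known
#' translation labels on `(f0, uniformity)`.
#'
#' @param features Tibble with `f0` and `uniformity`.
#' @param labels Logical vector: truly translated or not.
#' @return Numeric length-3 coefficient vector `(b0, b1, b2)`.
#' @export
fit_probability_coeffs <- function(features, labels) {
  fit <- stats::glm(labels ~ f0 + uniformity, data = features,
                    family = stats::binomial())
  unname(stats::coef(fit))
}

#' Validate candidate uORFs by translating probability
#'
#' Scores every candidate that passed detection with
#' [periodicity_features()] and [translating_probability()] on the combined
#' RPF track; `translated` is `P > threshold` (strict).
#'
#' @param candidates Output of [detect_candidates()].
#' @param combined Combined RPF track (list or tibble).
#' @param transcripts Transcript tibble.
#' @param threshold Probability cutoff (default 0.5).
#' @param coeffs Logistic coefficients, see [translating_probability()].
#' @return The detected candidates with added `f0`, `uniformity`,
#'   `probability`, `translated`.
#' @export
validate_uorfs <- function(candidates, combined, transcripts,
                           threshold = 0.5, coeffs = c(-6, 9, 3)) {
  cand <- dplyr::filter(candidates, .data$pass_detection)
  if (nrow(cand) == 0) {
    return(dplyr::mutate(cand, f0 = numeric(0), uniformity = numeric(0),
                         probability = numeric(0), translated = logical(0)))
  }
  feats <- periodicity_features(combined, cand, transcripts)
  cand |>
    dplyr::mutate(
      f0 = feats$f0, uniformity = feats$uniformity,
      probability = translating_probability(feats$f0, feats$uniformity,
                                            coeffs),
      translated = .data$probability > threshold
    )
}

#' Full two-step uORF discovery on a set of tracks
#'
#' Convenience wrapper: combines the RPF samples (all of them by default, as
#' discovery pools every replicate and condition), enumerates USSs if not
#' supplied, then runs detection and validation.
#'
#' @param tracks Long track tibble.
#' @param samples Sample sheet (`sample_id`, `assay`, ...).
#' @param transcripts Transcript tibble.
#' @param uss Optional precomputed USS tibble.
#' @param sample_ids RPF samples to combine (default: all RPF samples).
#' @param r,c,z,min_codons,threshold,coeffs Detection/validation parameters.
#' @return Tibble of scored candidates (one row per candidate passing
#'   detection), with `translated` marking the final calls.
#' @export
discover_uorfs <- function(tracks, samples, transcripts, uss = NULL,
                           sample_ids = NULL,
                           r = 4, c = 15, z = 0.5, min_codons = 3L,
                           threshold = 0.5, coeffs = c(-6, 9, 3)) {
  if (is.null(sample_ids)) {
    sample_ids <- samples$sample_id[samples$assay == "RPF"]
  }
  if (length(sample_ids) == 0) stop("no RPF samples to combine")
  combined <- combine_tracks(tracks, samples, sample_ids)
  if (is.null(uss)) uss <- enumerate_uss(transcripts, min_codons = min_codons)
  detect_candidates(combined, uss, transcripts,
                    r = r, c = c, z = z, min_codons = min_codons) |>
    validate_uorfs(combined, transcripts, threshold = threshold,
                   coeffs = coeffs)
}
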