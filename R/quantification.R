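# Region densities (rpm), translational efficiency (TE), relative TE and
# relative ribosome occupancy (RRO) for arbitrary transcript regions.
#
# TE of an mRNA is RPF read density over mRNA read density. TE of a uORF
# divides the uORF's RPF density by the mRNA density of its *downstream mORF*
# (the mORF mRNA signal is less noisy than the short uORF window);
# relative-TE_uORF = TE_uORF / TE_mORF isolates uORF-specific regulation from
# transcript-wide changes.

#' Region read density in rpm
#'
#' `sum(counts[start:end)) / library_size * 1e6` — reads on the region per
#' million mapped reads in the library.
#'
#' @param track Combined track (list from [combine_tracks()] or tibble) or a
#'   per-sample track filtered to one sample.
#' @param transcript_id,start,end Vectors defining regions (0-based,
#'   half-open).
#' @param library_size Total mapped reads of the library/combination
#'   (taken from a [combine_tracks()] list when not given).
#' @return Numeric vector of rpm densities.
#' @export
region_density <- function(track, transcript_id, start, end,
                           library_size = NULL) {
  if (is.null(library_size) && is.list(track) && !is.data.frame(track)) {
    library_size <- track$library_size
  }
  if (is.null(library_size)) stop("library_size required")
  if (any(end <= start)) stop("empty region: end must exceed start")
  tt <- .as_combined_track(track)
  n <- length(transcript_id)
  counts <- numeric(n)
  for (i in seq_len(n)) {
    counts[i] <- sum(tt$count[tt$transcript_id == transcript_id[i] &
                                tt$pos >= start[i] & tt$pos < end[i]])
  }
  counts / library_size * 1e6
}

#' Translational efficiency of a uORF
#'
#' `TE_uORF = rpf_density_uORF / mrna_density_mORF`; the mRNA density of the
#' downstream mORF is mandatory. Features with zero mORF mRNA density are
#' excluded (TE is `NA` with reason `"zero_mrna"`).
#'
#' @param rpf_density_uorf,mrna_density_morf Numeric rpm densities.
#' @return A tibble with `te` and `excluded_reason` (`NA` when defined).
#' @export
te_uorf <- function(rpf_density_uorf, mrna_density_morf) {
  ok <- mrna_density_morf > 0
  tibble::tibble(
    te = ifelse(ok, rpf_density_uorf / mrna_density_morf, NA_real_),
    excluded_reason = ifelse(ok, NA_character_, "zero_mrna")
  )
}

#' Relative TE of a uORF
#'
#' `relative-TE_uORF = TE_uORF / TE_mORF` at a given condition.
#'
#' @param te_uorf,te_morf Numeric TE values (`te_morf > 0`).
#' @return Numeric ratio.
#' @export
relative_te <- function(te_uorf, te_morf) {
  ifelse(te_morf > 0, te_uorf / te_morf, NA_real_)
}

#' Relative ribosome occupancy (RRO)
#'
#' Length-normalized RPF density of the uORF over that of its mORF:
#' `(rpf_uORF / len_uORF) / (rpf_mORF / len_mORF)`.
#'
#' @param rpf_counts_uorf,len_uorf,rpf_counts_morf,len_morf Raw (or rpm)
#'   counts and region lengths in nt.
#' @return Numeric ratio (`NA` when the mORF occupancy is 0).
#' @export
rro <- function(rpf_counts_uorf, len_uorf, rpf_counts_morf, len_morf) {
  stopifnot(all(len_uorf > 0), all(len_morf > 0))
  morf_ro <- rpf_counts_morf / len_morf
  ifelse(morf_ro > 0, (rpf_counts_uorf / len_uorf) / morf_ro, NA_real_)
}

#' Bin RRO values into the standard occupancy classes
#'
#' @param rro Numeric RRO values.
#' @param breaks Bin edges (default `c(0.1, 0.5)` giving classes `<0.1`,
#'   `0.1-0.5`, `>0.5`).
#' @return Factor of bin labels.
#' @export
rro_bins <- function(rro, breaks = c(0.1, 0.5)) {
  cut(rro, breaks = c(-Inf, breaks, Inf),
      labels = c(paste0("<", breaks[1]),
                 paste0(breaks[1], "-", breaks[2]),
                 paste0(">", breaks[2])))
}

#' Per-condition TE table for uORFs and their mORFs
#'
#' Computes, per replicate, the rpm densities of each uORF (RPF over the uORF
#' body) and of its downstream mORF (RPF and mRNA over the CDS), forms
#' per-replicate TEs (uORF RPF density over *mORF* mRNA density; mORF RPF
#' density over mORF mRNA density), and averages replicates within condition.
#' RRO is computed from replicate-summed counts at the reference condition.
#' These are descriptive quantities; inferential Delta-TE comes from
#' [delta_te_test()].
#'
#' @param tracks Long track tibble.
#' @param samples Sample sheet with realized `library_size`.
#' @param uorfs Tibble with `uorf_id` (or `transcript_id`/`start_pos` to form
#'   one), `transcript_id`, `start_pos`, `end_pos`.
#' @param transcripts Transcript tibble.
#' @param reference_condition Condition whose combined counts define RRO
#'   (default the first condition in `samples`).
#' @return A tibble: `uorf_id`, `transcript_id`, `condition`, `rpf_rpm_uorf`,
#'   `mrna_rpm_morf`, `rpf_rpm_morf`, `te_uorf`, `te_morf`, `relative_te`,
#'   `rro` (reference condition only, repeated per row), `excluded_reason`.
#' @export
quantify_uorfs <- function(tracks, samples, uorfs, transcripts,
                           reference_condition = samples$condition[1]) {
  if (!"uorf_id" %in% names(uorfs)) {
    uorfs <- dplyr::mutate(uorfs, uorf_id = sprintf("%s_u%d",
                                                    .data$transcript_id,
                                                    .data$start_pos))
  }
  tx <- transcripts[match(uorfs$transcript_id, transcripts$transcript_id), ]

  per_sample <- purrr::map(seq_len(nrow(samples)), function(s) {
    smp <- samples[s, ]
    tr <- dplyr::filter(tracks, .data$sample_id == smp$sample_id)
    ls <- max(smp$library_size, 1)
    tibble::tibble(
      uorf_id = uorfs$uorf_id,
      transcript_id = uorfs$transcript_id,
      sample_id = smp$sample_id, assay = smp$assay,
      condition = smp$condition, replicate = smp$replicate,
      uorf_rpm = region_density(tr, uorfs$transcript_id, uorfs$start_pos,
                                uorfs$end_pos, library_size = ls),
      morf_rpm = region_density(tr, uorfs$transcript_id, tx$cds_start,
                                tx$cds_end, library_size = ls),
      uorf_raw = region_density(tr, uorfs$transcript_id, uorfs$start_pos,
                                uorfs$end_pos, library_size = 1e6),
      morf_raw = region_density(tr, uorfs$transcript_id, tx$cds_start,
                                tx$cds_end, library_size = 1e6)
    )
  }) |> dplyr::bind_rows()

  # per-replicate TEs: pair RPF and RNA libraries by condition + replicate
  wide <- per_sample |>
    tidyr::pivot_wider(
      id_cols = c("uorf_id", "transcript_id", "condition", "replicate"),
      names_from = "assay",
      values_from = c("uorf_rpm", "morf_rpm", "uorf_raw", "morf_raw")
    ) |>
    dplyr::mutate(
      te_uorf = ifelse(.data$morf_rpm_RNA > 0,
                       .data$uorf_rpm_RPF / .data$morf_rpm_RNA, NA_real_),
      te_morf = ifelse(.data$morf_rpm_RNA > 0,
                       .data$morf_rpm_RPF / .data$morf_rpm_RNA, NA_real_)
    )

  by_cond <- wide |>
    dplyr::group_by(.data$uorf_id, .data$transcript_id, .data$condition) |>
    dplyr::summarise(
      rpf_rpm_uorf = mean(.data$uorf_rpm_RPF),
      mrna_rpm_morf = mean(.data$morf_rpm_RNA),
      rpf_rpm_morf = mean(.data$morf_rpm_RPF),
      te_uorf = mean(.data$te_uorf),
      te_morf = mean(.data$te_morf),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      relative_te = relative_te(.data$te_uorf, .data$te_morf),
      excluded_reason = ifelse(is.na(.data$te_uorf), "zero_mrna",
                               NA_character_)
    )

  # RRO from replicate-summed RPF counts at the reference condition
  ref <- per_sample |>
    dplyr::filter(.data$assay == "RPF",
                  .data$condition == reference_condition) |>
    dplyr::group_by(.data$uorf_id) |>
    dplyr::summarise(uorf_raw = sum(.data$uorf_raw),
                     morf_raw = sum(.data$morf_raw), .groups = "drop")
  len_u <- uorfs$end_pos - uorfs$start_pos
  len_m <- tx$cds_end - tx$cds_start
  ref$rro <- rro(ref$uorf_raw, len_u[match(ref$uorf_id, uorfs$uorf_id)],
                 ref$morf_raw, len_m[match(ref$uorf_id, uorfs$uorf_id)])

  dplyr::left_join(by_cond, ref[, c("uorf_id", "rro")], by = "uorf_id")
}
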