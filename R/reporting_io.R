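# Wiggle-track export (rpm and TE-scaled modes), tabular I/O, and the
# end-to-end pipeline driver.

#' Export combined tracks as variableStep wiggle files
#'
#' Replicates of one assay are combined per condition by summing counts and
#' library sizes; values are written as rpm (`count * 1e6 / combined library
#' size`), zero positions omitted. In `te_scaled` mode the rpm values of each
#' transcript are additionally multiplied by the ratio of the reference
#' condition's mRNA density to this condition's mRNA density (whole-transcript
#' RNA rpm), so peak heights reflect TE changes rather than mRNA-level
#' changes; the reference condition's track is unchanged. Chromosome names
#' are transcript ids (transcript-space coordinates, 1-based positions).
#'
#' @param tracks Long track tibble.
#' @param samples Sample sheet with realized `library_size`.
#' @param out_dir Output directory (created if needed).
#' @param assay Assay to export (`"RPF"` or `"RNA"`); mixing assays in one
#'   track is an error, so each call exports one assay.
#' @param mode `"rpm"` or `"te_scaled"`.
#' @param reference_condition Required for `te_scaled`.
#' @param transcripts Transcript tibble (required for `te_scaled`).
#' @return Invisibly, a tibble of the written files (`condition`, `path`).
#' @export
export_wiggle <- function(tracks, samples, out_dir, assay = "RPF",
                          mode = c("rpm", "te_scaled"),
                          reference_condition = NULL, transcripts = NULL) {
  mode <- match.arg(mode)
  if (length(unique(assay)) != 1 || !assay %in% c("RNA", "RPF")) {
    stop("export one assay at a time (RNA or RPF)")
  }
  if (mode == "te_scaled" && (is.null(reference_condition) ||
                              is.null(transcripts))) {
    stop("te_scaled mode needs reference_condition and transcripts")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  mrna_density <- NULL
  if (mode == "te_scaled") {
    rna <- dplyr::filter(samples, .data$assay == "RNA")
    mrna_density <- purrr::map(
      stats::setNames(unique(rna$condition), unique(rna$condition)),
      function(cond) {
        comb <- combine_tracks(tracks, samples,
                               rna$sample_id[rna$condition == cond])
        comb$track |>
          dplyr::count(.data$transcript_id, wt = .data$count, name = "n") |>
          dplyr::mutate(rpm = .data$n / max(comb$library_size, 1) * 1e6)
      }
    )
  }

  smp <- dplyr::filter(samples, .data$assay == !!assay)
  written <- purrr::map(unique(smp$condition), function(cond) {
    comb <- combine_tracks(tracks, samples,
                           smp$sample_id[smp$condition == cond])
    tt <- comb$track |>
      dplyr::mutate(value = .data$count / max(comb$library_size, 1) * 1e6)
    if (mode == "te_scaled" && cond != reference_condition) {
      ref_d <- mrna_density[[reference_condition]]
      cond_d <- mrna_density[[cond]]
      fac <- tibble::tibble(transcript_id = transcripts$transcript_id) |>
        dplyr::left_join(ref_d[, c("transcript_id", "rpm")],
                         by = "transcript_id") |>
        dplyr::left_join(cond_d[, c("transcript_id", "rpm")],
                         by = "transcript_id", suffix = c("_ref", "_cond")) |>
        dplyr::mutate(factor = ifelse(
          !is.na(.data$rpm_ref) & !is.na(.data$rpm_cond) &
            .data$rpm_cond > 0,
          .data$rpm_ref / .data$rpm_cond, 1))
      tt <- tt |>
        dplyr::left_join(fac[, c("transcript_id", "factor")],
                         by = "transcript_id") |>
        dplyr::mutate(value = .data$value * .data$factor)
    }
    path <- file.path(out_dir, sprintf("%s_%s_%s.wig", assay, cond, mode))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=wiggle_0 name=\"%s %s (%s)\"",
                       assay, cond, mode), con)
    tt <- dplyr::arrange(tt, .data$transcript_id, .data$pos)
    for (id in unique(tt$transcript_id)) {
      sub <- tt[tt$transcript_id == id & tt$value > 0, ]
      if (nrow(sub) == 0) next
      writeLines(sprintf("variableStep chrom=%s span=1", id), con)
      writeLines(sprintf("%d\t%s", sub$pos + 1L,
                         formatC(sub$value, digits = 10, format = "g")), con)
    }
    tibble::tibble(condition = cond, path = path)
  })
  invisible(dplyr::bind_rows(written))
}

#' Read a variableStep wiggle file back into a track tibble
#'
#' @param path Wiggle file written by [export_wiggle()].
#' @return Tibble `transcript_id`, `pos` (0-based), `value`.
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  out <- list()
  current <- NULL
  for (ln in lines) {
    if (startsWith(ln, "track")) next
    if (startsWith(ln, "variableStep")) {
      current <- sub(".*chrom=([^ ]+).*", "\\1", ln)
      next
    }
    parts <- strsplit(ln, "\t")[[1]]
    out[[length(out) + 1L]] <- tibble::tibble(
      transcript_id = current,
      pos = as.integer(parts[1]) - 1L,
      value = as.numeric(parts[2])
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(transcript_id = character(), pos = integer(),
                          value = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Run the full pipeline on simulated data
#'
#' simulate -> discover -> quantify -> test -> annotate -> classify, writing
#' the documented TSV interfaces to `out_dir`: `uss.tsv` (all upstream start
#' sites), `discovery.tsv` (scored candidates), `te.tsv` (per-condition TE
#' table), `results_<cond>.tsv` (Delta-TE tests per non-reference condition),
#' `calls.tsv` (regulation calls), `annotations.tsv`, plus the simulated
#' inputs (`transcriptome.fa`, `transcriptome.gff3`, `tracks.tsv`,
#' `samples.csv`, `truth_uorfs.tsv`) and `config.json` recording seeds and
#' thresholds. Outputs are deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every random draw.
#' @param config A [sim_config()].
#' @param fold,fdr,min_mean_mrna Regulation-call and filter thresholds.
#' @return Invisibly, a list with the in-memory objects (`sim`, `counts`,
#'   `discovery`, `te`, `fits`, `calls`, `annotations`) and `files`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = sim_config(),
                         fold = 2, fdr = 0.1, min_mean_mrna = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  sim <- simulate_transcriptome(config = config, seed = seed)
  cnt <- simulate_counts(sim, sim_sample_sheet(config), seed = seed + 1L)
  write_transcriptome(sim$transcripts, p("transcriptome.fa"),
                      p("transcriptome.gff3"))
  readr::write_tsv(cnt$tracks, p("tracks.tsv"))
  readr::write_csv(cnt$samples, p("samples.csv"))
  readr::write_tsv(sim$truth$uorfs, p("truth_uorfs.tsv"))

  uss <- enumerate_uss(sim$transcripts)
  readr::write_tsv(uss, p("uss.tsv"))
  disc <- discover_uorfs(cnt$tracks, cnt$samples, sim$transcripts, uss = uss)
  readr::write_tsv(disc, p("discovery.tsv"))

  called <- dplyr::filter(disc, .data$translated) |>
    dplyr::mutate(uorf_id = sprintf("%s_u%d", .data$transcript_id,
                                    .data$start_pos))
  ref <- config$reference_condition
  te <- quantify_uorfs(cnt$tracks, cnt$samples, called, sim$transcripts,
                       reference_condition = ref)
  readr::write_tsv(te, p("te.tsv"))

  ann <- annotate_uorfs(called, sim$transcripts)
  readr::write_tsv(ann, p("annotations.tsv"))

  counts <- build_count_matrix(cnt$tracks, cnt$samples, called,
                               sim$transcripts)
  fits <- list()
  calls <- list()
  for (cond in setdiff(config$conditions, ref)) {
    smp <- dplyr::filter(cnt$samples, .data$condition %in% c(ref, cond))
    fit_u <- delta_te_test(dplyr::filter(counts, .data$feature_type == "uorf"),
                           smp, c(ref, cond), min_mean_mrna = min_mean_mrna)
    fit_m <- delta_te_test(dplyr::filter(counts, .data$feature_type == "morf"),
                           smp, c(ref, cond), min_mean_mrna = min_mean_mrna)
    fits[[cond]] <- list(uorf = fit_u, morf = fit_m)
    readr::write_tsv(fit_u$results, p(sprintf("results_uorf_%s.tsv", cond)))
    readr::write_tsv(fit_m$results, p(sprintf("results_morf_%s.tsv", cond)))
    calls[[cond]] <- classify_regulation(fit_u, fit_m, called,
                                         fold = fold, fdr = fdr) |>
      dplyr::mutate(contrast = paste0(cond, "_vs_", ref), .before = 1)
  }
  calls_tbl <- dplyr::bind_rows(calls)
  readr::write_tsv(calls_tbl, p("calls.tsv"))

  jsonlite::write_json(
    list(seed = seed, fold = fold, fdr = fdr, min_mean_mrna = min_mean_mrna,
         n_transcripts = config$n_transcripts,
         conditions = config$conditions, reference = ref,
         detection = list(r = 4, c = 15, z = 0.5, min_codons = 3,
                          probability_threshold = 0.5)),
    p("config.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sim = sim, counts = cnt, uss = uss, discovery = disc,
                 te = te, fits = fits, calls = calls_tbl, annotations = ann,
                 files = list.files(out_dir, full.names = TRUE)))
}
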