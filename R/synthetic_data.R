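# Synthetic transcriptomes and per-position RPF/RNA count tracks with planted,
# known uORF/mORF translational efficiencies. The generator encodes the signal
# model the discovery stage relies on: RPF reads over translated ORFs show 3-nt
# periodicity (frame weights cycling from the ORF start) and a peak at the
# start codon; RNA reads are positionally uniform; replicate noise is negative
# binomial (variance = mu + alpha * mu^2); library sizes differ per sample.

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                    c("A", "C", "G", "U")), 1, paste, collapse = ""),
  c("UAA", "UAG", "UGA")
)

#' Simulation configuration
#'
#' Defaults emulate a yeast-scale ribosome-profiling study: two biological
#' replicates at three growth temperatures (20, 30, 37; reference 30), 3-nt
#' frame weights (0.70, 0.20, 0.10), an 8-fold ribosome-density peak on the
#' start codon, negative-binomial dispersion 0.05, and 2 million mapped reads
#' per library. `abundance_meanlog`/`abundance_sdlog` set the lognormal
#' transcript abundance in expected RNA reads per nt per million mapped reads.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param utr5_len_range,cds_codons_range,utr3_len Geometry of the simulated
#'   transcripts (nt, codons incl. start and stop, nt).
#' @param fraction_with_uorf Fraction of transcripts carrying one planted
#'   translated uORF.
#' @param uorf_codons_range Planted uORF length range in sense codons.
#' @param codon_mix Named start-codon probabilities over AUG and the nine
#'   near-cognates (defaults echo the usage spectrum seen in yeast, with
#'   first-base changes the most common NCC class).
#' @param conditions,reference_condition,n_replicates Study design.
#' @param library_size Expected mapped reads per library.
#' @param alpha Negative-binomial dispersion (variance = mu + alpha mu^2).
#' @param frame_weights Frame weights (w0, w1, w2), summing to 1.
#' @param start_peak Multiplier applied to the start codon's three positions
#'   of each translated ORF (RPF only).
#' @param abundance_meanlog,abundance_sdlog Lognormal mRNA abundance
#'   parameters (reads/nt per million mapped).
#' @param morf_te_sdlog,uorf_te_meanlog,uorf_te_sdlog Lognormal TE spread for
#'   mORFs (median 1) and planted uORFs.
#' @param regulated_fraction Fraction of planted uORFs given a TE change in
#'   each non-reference condition.
#' @param effect_log2 Magnitude of planted uORF TE changes (log2; sign drawn
#'   at random per uORF and condition).
#' @param rpf_background Untranslated background RPF rate as a fraction of
#'   transcript abundance (uniform across positions, i.e. frame weights
#'   1/3, 1/3, 1/3).
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200L,
                       utr5_len_range = c(90L, 250L),
                       cds_codons_range = c(100L, 300L),
                       utr3_len = 30L,
                       fraction_with_uorf = 0.5,
                       uorf_codons_range = c(4L, 12L),
                       codon_mix = c(AUG = 0.10, UUG = 0.25, CUG = 0.13,
                                     GUG = 0.12, AAG = 0.01, ACG = 0.06,
                                     AGG = 0.01, AUC = 0.10, AUA = 0.12,
                                     AUU = 0.10),
                       conditions = c("20", "30", "37"),
                       reference_condition = "30",
                       n_replicates = 2L,
                       library_size = 2e6,
                       alpha = 0.05,
                       frame_weights = c(0.70, 0.20, 0.10),
                       start_peak = 8,
                       abundance_meanlog = log(0.5),
                       abundance_sdlog = 0.6,
                       morf_te_sdlog = 0.3,
                       uorf_te_meanlog = log(0.8),
                       uorf_te_sdlog = 0.4,
                       regulated_fraction = 0.2,
                       effect_log2 = 2,
                       rpf_background = 0.02) {
  stopifnot(abs(sum(frame_weights) - 1) < 1e-8, length(frame_weights) == 3,
            alpha >= 0, all(codon_mix >= 0),
            reference_condition %in% conditions)
  cfg <- as.list(environment())
  cfg$codon_mix <- codon_mix / sum(codon_mix)
  structure(cfg, class = "sim_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome with planted uORFs
#'
#' Builds random transcript sequences (so decoy near-cognate start sites arise
#' at their natural density), embeds one planted uORF — start codon, non-stop
#' body codons, terminal stop — in the 5'-UTR of a configured fraction of
#' transcripts, and records the ground truth: per-condition mRNA abundance,
#' mORF TE, and planted uORF TE with any condition-specific changes.
#'
#' @param n_transcripts Number of transcripts (overrides the config value).
#' @param config A [sim_config()] list.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `transcripts` (tibble as from [load_transcriptome()])
#'   and `truth`, itself a list of tibbles: `uorfs` (planted positions),
#'   `uorf_te` (uorf, condition, te, regulated, log2_effect), `morf_te`,
#'   `abundance`, plus the `config`.
#' @export
simulate_transcriptome <- function(n_transcripts = NULL,
                                   config = sim_config(),
                                   seed = 1L) {
  if (!is.null(n_transcripts)) config$n_transcripts <- n_transcripts
  n <- config$n_transcripts
  if (3L * (max(config$uorf_codons_range) + 1L) > min(config$utr5_len_range)) {
    stop("infeasible config: planted uORF cannot fit in the shortest 5'-UTR")
  }
  set.seed(seed)

  ids <- sprintf("tx%04d", seq_len(n))
  utr5_len <- sample(config$utr5_len_range[1]:config$utr5_len_range[2], n,
                     replace = TRUE)
  cds_codons <- sample(config$cds_codons_range[1]:config$cds_codons_range[2],
                       n, replace = TRUE)
  has_uorf <- seq_len(n) %in%
    sample(n, round(config$fraction_with_uorf * n))

  uorf_rows <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    utr <- .random_seq(utr5_len[i])
    if (has_uorf[i]) {
      nc <- sample(config$uorf_codons_range[1]:config$uorf_codons_range[2], 1)
      span <- 3L * (nc + 1L) # sense codons + stop
      start <- sample(0:(utr5_len[i] - span), 1)
      codon <- sample(names(config$codon_mix), 1, prob = config$codon_mix)
      body <- sample(NON_STOP_CODONS, nc - 1L, replace = TRUE)
      stopc <- sample(STOP_CODONS, 1)
      planted <- paste0(codon, paste(body, collapse = ""), stopc)
      substr(utr, start + 1L, start + span) <- planted
      uorf_rows[[i]] <- tibble::tibble(
        uorf_id = sprintf("%s_u%d", ids[i], start),
        transcript_id = ids[i], start_pos = start,
        end_pos = start + 3L * nc, n_codons = nc, codon = codon
      )
    }
    cds <- paste0("AUG",
                  paste(sample(NON_STOP_CODONS, cds_codons[i] - 2L,
                               replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1))
    seqs[i] <- paste0(utr, cds, .random_seq(config$utr3_len))
  }

  transcripts <- tibble::tibble(
    transcript_id = ids, seq = seqs, utr5_len = utr5_len,
    cds_start = utr5_len, cds_end = utr5_len + 3L * cds_codons,
    length = nchar(seqs)
  )
  uorfs <- dplyr::bind_rows(uorf_rows)

  conds <- config$conditions
  abundance <- tidyr::expand_grid(transcript_id = ids, condition = conds) |>
    dplyr::left_join(
      tibble::tibble(transcript_id = ids,
                     abundance = stats::rlnorm(n, config$abundance_meanlog,
                                               config$abundance_sdlog)),
      by = "transcript_id"
    )
  morf_te <- tidyr::expand_grid(transcript_id = ids, condition = conds) |>
    dplyr::left_join(
      tibble::tibble(transcript_id = ids,
                     te = stats::rlnorm(n, 0, config$morf_te_sdlog)),
      by = "transcript_id"
    )

  if (is.null(uorfs) || nrow(uorfs) == 0) {
    uorfs <- tibble::tibble(uorf_id = character(), transcript_id = character(),
                            start_pos = integer(), end_pos = integer(),
                            n_codons = integer(), codon = character())
  }
  nu <- nrow(uorfs)
  base_te <- stats::rlnorm(nu, config$uorf_te_meanlog, config$uorf_te_sdlog)
  uorf_te <- tidyr::expand_grid(uorf_id = uorfs$uorf_id, condition = conds) |>
    dplyr::left_join(tibble::tibble(uorf_id = uorfs$uorf_id, te = base_te),
                     by = "uorf_id") |>
    dplyr::mutate(regulated = FALSE, log2_effect = 0)
  for (cond in setdiff(conds, config$reference_condition)) {
    reg <- stats::runif(nu) < config$regulated_fraction
    sign <- sample(c(-1, 1), nu, replace = TRUE)
    idx <- uorf_te$condition == cond
    eff <- ifelse(reg, sign * config$effect_log2, 0)
    uorf_te$log2_effect[idx] <- eff
    uorf_te$regulated[idx] <- reg
    uorf_te$te[idx] <- uorf_te$te[idx] * 2^eff
  }

  list(
    transcripts = transcripts,
    truth = list(uorfs = uorfs, uorf_te = uorf_te, morf_te = morf_te,
                 abundance = abundance, config = config)
  )
}

#' Sample sheet for a simulated study
#'
#' One row per library: both assays (RNA, RPF) for every condition and
#' replicate, with the configured expected library size.
#'
#' @param config A [sim_config()].
#' @return A tibble with `sample_id`, `assay`, `condition`, `replicate`,
#'   `library_size`.
#' @export
sim_sample_sheet <- function(config = sim_config()) {
  tidyr::expand_grid(
    assay = c("RNA", "RPF"),
    condition = config$conditions,
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = paste(.data$assay, .data$condition, .data$replicate,
                        sep = "_"),
      library_size = config$library_size
    ) |>
    dplyr::select("sample_id", "assay", "condition", "replicate",
                  "library_size")
}

# expected per-position RPF/RNA rates for one transcript at library size 1e6
.expected_rates <- function(tx, uorfs_tx, abundance, morf_te, uorf_te_tx,
                            config) {
  L <- tx$length
  w <- config$frame_weights
  rna <- rep(abundance, L)
  rpf <- rep(config$rpf_background * abundance, L)
  add_orf <- function(rpf, start, end, te) {
    pos <- start:(end - 1L)
    wt <- 3 * w[((pos - start) %% 3L) + 1L]
    wt[1:3] <- wt[1:3] * config$start_peak
    rpf[pos + 1L] <- rpf[pos + 1L] + abundance * te * wt
    rpf
  }
  rpf <- add_orf(rpf, tx$cds_start, tx$cds_end - 3L, morf_te)
  if (!is.null(uorfs_tx) && nrow(uorfs_tx) > 0) {
    for (j in seq_len(nrow(uorfs_tx))) {
      rpf <- add_orf(rpf, uorfs_tx$start_pos[j], uorfs_tx$end_pos[j],
                     uorf_te_tx$te[match(uorfs_tx$uorf_id[j],
                                         uorf_te_tx$uorf_id)])
    }
  }
  list(RNA = rna, RPF = rpf)
}

#' Simulate per-position count tracks for a study design
#'
#' Draws negative-binomial counts (variance = mu + alpha mu^2; Poisson when
#' alpha = 0) at every transcript position of every library. RNA expectations
#' are positionally uniform and proportional to abundance x library size;
#' RPF expectations over each translated ORF are proportional to
#' abundance x TE x library size, spread across positions by the frame weights
#' cycling from the ORF start, with the start codon's three positions
#' multiplied by the start-peak factor; untranslated positions carry uniform
#' background. The reported per-sample `library_size` is the realized total of
#' simulated mapped reads (the configured size sets the expectations).
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param samples Sample sheet, e.g. [sim_sample_sheet()]; `library_size`
#'   gives the expected mapped reads per library.
#' @param seed Integer seed.
#' @return A list with `tracks` (tibble `sample_id`, `transcript_id`, `pos`
#'   0-based, `count` > 0; zero positions omitted) and `samples` (the sheet
#'   with realized `library_size`).
#' @export
simulate_counts <- function(sim, samples, seed = 1L) {
  if (!all(samples$assay %in% c("RNA", "RPF"))) {
    stop("unknown assay label: ",
         paste(setdiff(unique(samples$assay), c("RNA", "RPF")), collapse = ", "))
  }
  config <- sim$truth$config
  set.seed(seed)

  tx_tbl <- sim$transcripts
  uorfs <- sim$truth$uorfs
  out <- vector("list", nrow(samples))
  realized <- numeric(nrow(samples))

  # per (condition, transcript) expected rates at 1e6 mapped reads, reused
  # across replicates and assays
  rate_cache <- list()
  for (s in seq_len(nrow(samples))) {
    smp <- samples[s, ]
    scale <- smp$library_size / 1e6
    per_tx <- vector("list", nrow(tx_tbl))
    for (i in seq_len(nrow(tx_tbl))) {
      tx <- tx_tbl[i, ]
      key <- paste(smp$condition, tx$transcript_id)
      if (is.null(rate_cache[[key]])) {
        ab <- sim$truth$abundance$abundance[
          sim$truth$abundance$transcript_id == tx$transcript_id &
            sim$truth$abundance$condition == smp$condition]
        mte <- sim$truth$morf_te$te[
          sim$truth$morf_te$transcript_id == tx$transcript_id &
            sim$truth$morf_te$condition == smp$condition]
        ute <- dplyr::filter(sim$truth$uorf_te,
                             .data$condition == smp$condition)
        utx <- if (nrow(uorfs)) {
          dplyr::filter(uorfs, .data$transcript_id == tx$transcript_id)
        } else NULL
        rate_cache[[key]] <- .expected_rates(tx, utx, ab, mte, ute, config)
      }
      mu <- rate_cache[[key]][[smp$assay]] * scale
      counts <- if (config$alpha == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$alpha)
      }
      nz <- which(counts > 0)
      per_tx[[i]] <- if (length(nz)) {
        tibble::tibble(transcript_id = tx$transcript_id, pos = nz - 1L,
                       count = counts[nz])
      } else NULL
    }
    tt <- dplyr::bind_rows(per_tx)
    realized[s] <- if (nrow(tt)) sum(tt$count) else 0
    out[[s]] <- if (nrow(tt)) {
      dplyr::mutate(tt, sample_id = smp$sample_id, .before = 1)
    } else NULL
  }

  samples$library_size <- realized
  list(tracks = dplyr::bind_rows(out), samples = samples)
}

#' Combine tracks across samples
#'
#' Sums per-position counts over the chosen samples and their library sizes —
#' the combined-replicate track used for uORF discovery and wiggle export.
#'
#' @param tracks Long track tibble (`sample_id`, `transcript_id`, `pos`,
#'   `count`).
#' @param samples Sample sheet with realized `library_size`.
#' @param sample_ids Samples to combine; default all in `samples`.
#' @return A list with `track` (tibble `transcript_id`, `pos`, `count`) and
#'   `library_size` (summed).
#' @export
combine_tracks <- function(tracks, samples, sample_ids = samples$sample_id) {
  stopifnot(all(sample_ids %in% samples$sample_id))
  track <- tracks |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::count(.data$transcript_id, .data$pos, wt = .data$count,
                 name = "count")
  list(track = track,
       library_size = sum(samples$library_size[samples$sample_id %in%
                                                 sample_ids]))
}
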