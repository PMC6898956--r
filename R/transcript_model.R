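# Transcript model: transcriptome loading, upstream start-site (USS)
# enumeration over 5'-UTRs, start-codon and Kozak-context classification.
#
# Coordinate convention (used package-wide): 0-based, half-open, transcript
# space, 5'->3'. utr5_len == cds_start (first nt of the mAUG); cds_end is the
# half-open end of the stop codon. Sequences are held in the RNA alphabet
# (U internally; T accepted on input).

STOP_CODONS <- c("UAA", "UAG", "UGA")

# the 9 near-cognate codons plus AUG, keyed by mismatch position
NEAR_COGNATE <- c(
  AUG = "AUG",
  UUG = "first", CUG = "first", GUG = "first",
  AAG = "second", ACG = "second", AGG = "second",
  AUC = "third", AUA = "third", AUU = "third"
)

#' Normalize a nucleotide sequence to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside `A`, `C`, `G`, `U`, `N`
#' raise an error.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector over `{A,C,G,U,N}`.
#' @export
normalize_seq <- function(seq) {
  out <- chartr("T", "U", toupper(seq))
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T/U,N}: ",
         paste(utils::head(unique(unlist(strsplit(gsub("[ACGUN]", "", out[bad]), ""))), 5),
               collapse = ", "))
  }
  out
}

#' Load a transcriptome from FASTA + GFF3 in transcript coordinates
#'
#' Reads transcript sequences from `fasta_path` and `five_prime_UTR` / `CDS`
#' features from `gff_path`. Features are expected in transcript coordinates:
#' the GFF3 `seqid` of each feature is the transcript id, and each transcript
#' carries exactly one CDS span. Transcripts failing validation (CDS length
#' not a multiple of 3, sequence shorter than the CDS end, 5'-UTR not abutting
#' the CDS) are dropped with a warning; a transcript present in the GFF but
#' absent from the FASTA is a hard error.
#'
#' @param fasta_path Path to a FASTA file of transcript sequences.
#' @param gff_path Path to a GFF3 file with `five_prime_UTR` and `CDS`
#'   features whose seqids match the FASTA ids.
#' @return A tibble with columns `transcript_id`, `seq` (RNA alphabet),
#'   `utr5_len`, `cds_start`, `cds_end`, `length`.
#' @examples
#' td <- simulate_transcriptome(n_transcripts = 4, seed = 1)
#' fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
#' write_transcriptome(td$transcripts, fa, gff)
#' load_transcriptome(fa, gff)
#' @export
load_transcriptome <- function(fasta_path, gff_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path, format = "gff3")

  feat <- tibble::tibble(
    transcript_id = as.character(GenomicRanges::seqnames(gff)),
    type = as.character(gff$type),
    # GFF3 is 1-based closed; convert to 0-based half-open
    start0 = GenomicRanges::start(gff) - 1L,
    end0 = GenomicRanges::end(gff)
  ) |>
    dplyr::filter(.data$type %in% c("five_prime_UTR", "CDS"))

  missing <- setdiff(unique(feat$transcript_id), names(seqs))
  if (length(missing) > 0) {
    stop("transcripts in GFF absent from FASTA: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }

  cds <- dplyr::filter(feat, .data$type == "CDS")
  if (anyDuplicated(cds$transcript_id)) {
    stop("multiple CDS spans for transcript(s): ",
         paste(utils::head(unique(cds$transcript_id[duplicated(cds$transcript_id)]), 5),
               collapse = ", "))
  }
  utr <- dplyr::filter(feat, .data$type == "five_prime_UTR")

  tx <- cds |>
    dplyr::transmute(
      transcript_id = .data$transcript_id,
      cds_start = .data$start0,
      cds_end = .data$end0
    ) |>
    dplyr::left_join(
      dplyr::transmute(utr, transcript_id = .data$transcript_id,
                       utr_start = .data$start0, utr_end = .data$end0),
      by = "transcript_id"
    ) |>
    dplyr::mutate(
      utr5_len = dplyr::coalesce(.data$utr_end - .data$utr_start, 0L),
      seq = unname(normalize_seq(as.character(seqs[.data$transcript_id]))),
      length = nchar(.data$seq)
    )

  ok <- rep(TRUE, nrow(tx))
  bad_cds <- (tx$cds_end - tx$cds_start) %% 3L != 0L
  bad_len <- tx$length < tx$cds_end
  bad_utr <- tx$utr5_len != tx$cds_start |
    (!is.na(tx$utr_start) & tx$utr_start != 0L)
  for (flag in list(bad_cds, bad_len, bad_utr)) ok <- ok & !flag
  if (any(!ok)) {
    warning(sum(!ok), " transcript(s) failed validation and were skipped: ",
            paste(utils::head(tx$transcript_id[!ok], 5), collapse = ", "))
  }

  tx |>
    dplyr::filter(ok) |>
    dplyr::select("transcript_id", "seq", "utr5_len", "cds_start",
                  "cds_end", "length")
}

#' Write a transcript table to FASTA + GFF3
#'
#' Inverse of [load_transcriptome()]: emits one FASTA record per transcript
#' (DNA alphabet, U written as T) and `five_prime_UTR` + `CDS` features in
#' transcript coordinates.
#'
#' @param transcripts Transcript tibble as returned by
#'   [load_transcriptome()] or [simulate_transcriptome()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the input `transcripts`.
#' @export
write_transcriptome <- function(transcripts, fasta_path, gff_path) {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", transcripts$seq))
  names(dna) <- transcripts$transcript_id
  Biostrings::writeXStringSet(dna, fasta_path)

  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    if (t$utr5_len > 0) {
      lines <- c(lines, paste(t$transcript_id, "uorfte", "five_prime_UTR",
                              1L, t$utr5_len, ".", "+", ".",
                              paste0("ID=", t$transcript_id, ".utr5"),
                              sep = "\t"))
    }
    lines <- c(lines, paste(t$transcript_id, "uorfte", "CDS",
                            t$cds_start + 1L, t$cds_end, ".", "+", "0",
                            paste0("ID=", t$transcript_id, ".cds"),
                            sep = "\t"))
  }
  writeLines(lines, gff_path)
  invisible(transcripts)
}

#' Classify a start codon relative to AUG
#'
#' `AUG` maps to `"AUG"`; the nine near-cognate codons (one mismatch to AUG)
#' map to `"first"`, `"second"` or `"third"` by mismatch position
#' (UUG/CUG/GUG, AAG/ACG/AGG, AUC/AUA/AUU respectively); anything else is
#' `"none"`.
#'
#' @param codon Character vector of 3-mers over `{A,C,G,U}` (T accepted).
#' @return Character vector in
#'   `c("AUG","first","second","third","none")`.
#' @examples
#' classify_start_codon(c("AUG", "UUG", "ACG", "AUA", "CCG"))
#' @export
classify_start_codon <- function(codon) {
  codon <- normalize_seq(codon)
  if (any(nchar(codon) != 3L)) stop("codons must be 3-mers")
  out <- unname(NEAR_COGNATE[codon])
  out[is.na(out)] <- "none"
  out
}

#' Kozak context class at the -3 position
#'
#' A start site has good context when the base three nucleotides 5' of the
#' start codon is A or G, poor when U or C. Starts within 3 nt of the 5' cap
#' have no -3 base; they are classified poor and flagged as truncated.
#'
#' @param transcripts Transcript tibble.
#' @param transcript_id,start_pos Vectors locating the start sites (0-based).
#' @return A tibble with `kozak_class` (`"good"`/`"poor"`) and
#'   `kozak_truncated` (logical).
#' @export
kozak_context_class <- function(transcripts, transcript_id, start_pos) {
  seqs <- transcripts$seq[match(transcript_id, transcripts$transcript_id)]
  if (anyNA(seqs)) stop("unknown transcript id")
  truncated <- start_pos < 3L
  base <- ifelse(truncated, "N",
                 substr(seqs, start_pos - 2L, start_pos - 2L)) # 1-based substr of pos-3
  tibble::tibble(
    kozak_class = ifelse(!truncated & base %in% c("A", "G"), "good", "poor"),
    kozak_truncated = truncated
  )
}

# walk in-frame codons of one USS; returns end_pos, stopped, n_codons, kind
.walk_uss <- function(seq, start_pos, utr5_len) {
  pos <- start_pos
  stopped <- FALSE
  while (pos + 3L <= utr5_len) {
    codon <- substr(seq, pos + 1L, pos + 3L)
    if (pos > start_pos && codon %in% STOP_CODONS) {
      stopped <- TRUE
      break
    }
    pos <- pos + 3L
  }
  in_frame_with_maug <- (utr5_len - start_pos) %% 3L == 0L
  if (!stopped && in_frame_with_maug) {
    # reaches the mAUG in frame with no intervening stop: N-terminal extension
    list(end_pos = utr5_len, stopped = FALSE,
         n_codons = (utr5_len - start_pos) %/% 3L, kind = "NTE")
  } else {
    list(end_pos = pos, stopped = stopped,
         n_codons = (pos - start_pos) %/% 3L, kind = "uORF")
  }
}

#' Enumerate upstream start sites (USSs) in a 5'-UTR
#'
#' Scans every position of each 5'-UTR for AUG or near-cognate triplets and
#' walks in-frame codons to the first stop codon contained in the 5'-UTR.
#' Without an in-frame stop the ORF is truncated at the UTR end (whole codons
#' only), except when the start is in frame with the mAUG and no stop
#' intervenes, in which case the record is an N-terminal extension (NTE)
#' ending at the mAUG. Records shorter than `min_codons` sense codons
#' (start codon counted, stop codon not) are dropped.
#'
#' @param transcripts Transcript tibble (one or more rows).
#' @param min_codons Minimum ORF length in sense codons (default 3).
#' @return A tibble with one row per retained USS: `transcript_id`,
#'   `start_pos`, `codon`, `codon_class`, `end_pos`, `stopped`, `n_codons`,
#'   `kind`, `kozak_class`, `kozak_truncated`.
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1",
#'   seq = normalize_seq("AAATGCCCGGGTGATTTATGGCCGCCTAA"),
#'   utr5_len = 17L, cds_start = 17L, cds_end = 29L, length = 29L)
#' enumerate_uss(tx)
#' @export
enumerate_uss <- function(transcripts, min_codons = 3L) {
  res <- purrr::pmap(
    transcripts[, c("transcript_id", "seq", "utr5_len")],
    function(transcript_id, seq, utr5_len) {
      if (utr5_len < 3L) return(NULL)
      starts <- 0:(utr5_len - 3L)
      codons <- substring(seq, starts + 1L, starts + 3L)
      keep <- codons %in% names(NEAR_COGNATE)
      if (!any(keep)) return(NULL)
      starts <- starts[keep]
      codons <- codons[keep]
      walked <- purrr::map2(starts, codons, function(s, cod) {
        w <- .walk_uss(seq, s, utr5_len)
        tibble::tibble(start_pos = s, codon = cod,
                       end_pos = w$end_pos, stopped = w$stopped,
                       n_codons = w$n_codons, kind = w$kind)
      })
      dplyr::bind_rows(walked) |>
        dplyr::mutate(transcript_id = transcript_id, .before = 1)
    }
  )
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      transcript_id = character(), start_pos = integer(), codon = character(),
      codon_class = character(), end_pos = integer(), stopped = logical(),
      n_codons = integer(), kind = character(), kozak_class = character(),
      kozak_truncated = logical()
    ))
  }
  out <- dplyr::filter(out, .data$n_codons >= min_codons)
  kz <- kozak_context_class(transcripts, out$transcript_id, out$start_pos)
  out |>
    dplyr::mutate(
      codon_class = classify_start_codon(.data$codon),
      kozak_class = kz$kozak_class,
      kozak_truncated = kz$kozak_truncated
    ) |>
    dplyr::select("transcript_id", "start_pos", "codon", "codon_class",
                  "end_pos", "stopped", "n_codons", "kind", "kozak_class",
                  "kozak_truncated")
}
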