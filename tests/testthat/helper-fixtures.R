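# Fixtures and independent oracles used across the suite. Oracles are written
# as naive brute-force procedures, deliberately independent of the package's
# implementation paths.

# a minimal transcript tibble from a raw sequence (already 5'->3')
toy_transcript <- function(seq, utr5_len, id = "t1") {
  seq <- uorfte::normalize_seq(seq)
  cds_len <- nchar(seq) - utr5_len
  tibble::tibble(
    transcript_id = id, seq = seq, utr5_len = as.integer(utr5_len),
    cds_start = as.integer(utr5_len),
    cds_end = as.integer(utr5_len + cds_len - cds_len %% 3L),
    length = nchar(seq)
  )
}

# random transcript with a clean CDS for property tests
random_transcript <- function(utr5_len, cds_codons = 20L, id = "t1") {
  bases <- c("A", "C", "G", "U")
  utr <- paste(sample(bases, utr5_len, replace = TRUE), collapse = "")
  body <- replicate(cds_codons - 2L, paste(sample(bases, 3, replace = TRUE),
                                           collapse = ""))
  cds <- paste0("AUG", paste(body, collapse = ""), "UAA")
  tibble::tibble(
    transcript_id = id, seq = paste0(utr, cds),
    utr5_len = as.integer(utr5_len), cds_start = as.integer(utr5_len),
    cds_end = as.integer(utr5_len + 3L * cds_codons),
    length = utr5_len + 3L * cds_codons
  )
}

# brute-force USS oracle: test every UTR position against the 10 start
# triplets and walk codon by codon
brute_force_uss <- function(tx, min_codons = 3L) {
  starts10 <- c("AUG", "UUG", "CUG", "GUG", "AAG", "ACG", "AGG",
                "AUC", "AUA", "AUU")
  stops <- c("UAA", "UAG", "UGA")
  out <- list()
  for (i in seq_len(nrow(tx))) {
    seq <- tx$seq[i]
    u <- tx$utr5_len[i]
    if (u < 3) next
    for (s in 0:(u - 3)) {
      codon <- substr(seq, s + 1, s + 3)
      if (!codon %in% starts10) next
      pos <- s + 3
      stopped <- FALSE
      while (pos + 3 <= u) {
        if (substr(seq, pos + 1, pos + 3) %in% stops) { stopped <- TRUE; break }
        pos <- pos + 3
      }
      if (!stopped && (u - s) %% 3 == 0) {
        kind <- "NTE"; end <- u
      } else {
        kind <- "uORF"; end <- pos
      }
      nc <- (end - s) %/% 3
      if (nc >= min_codons) {
        out[[length(out) + 1]] <- data.frame(
          transcript_id = tx$transcript_id[i], start_pos = s, codon = codon,
          end_pos = end, stopped = stopped, n_codons = nc, kind = kind,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

# brute-force BH step-up
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  # step-up: running minimum from the largest rank down
  for (i in n:1) adj[i] <- min(adj[i:n], 1)
  q[o] <- adj
  q
}

# brute-force quartiles by sort-and-interpolate (type 7)
brute_force_quartile <- function(x, prob) {
  x <- sort(x)
  h <- (length(x) - 1) * prob
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

# sparse track tibble from a named list of dense count vectors (one sample)
dense_to_track <- function(dense, sample_id = "S1") {
  rows <- lapply(names(dense), function(id) {
    v <- dense[[id]]
    nz <- which(v > 0)
    if (!length(nz)) return(NULL)
    tibble::tibble(sample_id = sample_id, transcript_id = id,
                   pos = nz - 1L, count = v[nz])
  })
  dplyr::bind_rows(rows)
}

# direct NB count-matrix simulator for the differential tests: features x
# (assay x condition x replicate) with planted TE effects on the RPF side
simulate_te_matrix <- function(n_features, mu_range = c(50, 1000),
                               alpha = 0.05, effect_log2 = numeric(n_features),
                               conditions = c("30", "20"), n_rep = 2,
                               seed = 1) {
  set.seed(seed)
  samples <- tidyr::expand_grid(assay = c("RNA", "RPF"),
                                condition = conditions,
                                replicate = seq_len(n_rep)) |>
    dplyr::mutate(sample_id = paste(assay, condition, replicate, sep = "_"),
                  library_size = 1e6)
  mu <- exp(stats::runif(n_features, log(mu_range[1]), log(mu_range[2])))
  cols <- lapply(seq_len(nrow(samples)), function(s) {
    smp <- samples[s, ]
    eff <- if (smp$assay == "RPF" && smp$condition == conditions[2]) {
      2^effect_log2
    } else rep(1, n_features)
    if (alpha == 0) stats::rpois(n_features, mu * eff)
    else stats::rnbinom(n_features, mu = mu * eff, size = 1 / alpha)
  })
  names(cols) <- samples$sample_id
  counts <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("f%04d", seq_len(n_features))),
    tibble::as_tibble(cols)
  )
  list(counts = counts, samples = samples, mu = mu)
}
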