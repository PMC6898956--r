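# Differential translational efficiency: a negative-binomial GLM with an
# assay x condition interaction, in the style popularized for ribo-seq
# (library type as a design factor; the TE change is the interaction of
# library type with condition). Size factors are median-of-ratios within
# assay; per-feature dispersions are method-of-moments estimates shrunk
# toward a mean-dispersion trend a0 + a1/mu; the interaction is tested by a
# Wald test and corrected by Benjamini-Hochberg. Deliberate simplifications
# relative to the full DESeq2 machinery: no independent filtering, no
# Cook's-distance outlier replacement, no LFC shrinkage.

.count_matrix <- function(counts) {
  stopifnot("feature_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), c("feature_id",
                                                   "feature_type"))])
  rownames(m) <- counts$feature_id
  storage.mode(m) <- "double"
  m
}

#' Build the feature-by-sample count matrix for TE testing
#'
#' One row per uORF and one per mORF. For a uORF feature the RPF columns hold
#' raw RPF counts over the uORF body and the RNA columns hold the *downstream
#' mORF's* mRNA counts (the mORF mRNA signal has lower noise than the short
#' uORF window); mORF features use CDS counts for both assays.
#'
#' @param tracks Long track tibble.
#' @param samples Sample sheet.
#' @param uorfs Tibble with `uorf_id`, `transcript_id`, `start_pos`,
#'   `end_pos`.
#' @param transcripts Transcript tibble.
#' @return A tibble with `feature_id`, `feature_type` (`"uorf"`/`"morf"`) and
#'   one integer column per sample.
#' @export
build_count_matrix <- function(tracks, samples, uorfs, transcripts) {
  if (!"uorf_id" %in% names(uorfs)) {
    uorfs <- dplyr::mutate(uorfs, uorf_id = sprintf("%s_u%d",
                                                    .data$transcript_id,
                                                    .data$start_pos))
  }
  tx <- transcripts[match(uorfs$transcript_id, transcripts$transcript_id), ]
  morf_tx <- transcripts[match(unique(uorfs$transcript_id),
                               transcripts$transcript_id), ]

  regions <- dplyr::bind_rows(
    tibble::tibble(feature_id = uorfs$uorf_id, feature_type = "uorf",
                   transcript_id = uorfs$transcript_id,
                   rpf_start = uorfs$start_pos, rpf_end = uorfs$end_pos,
                   rna_start = tx$cds_start, rna_end = tx$cds_end),
    tibble::tibble(feature_id = paste0(morf_tx$transcript_id, "_morf"),
                   feature_type = "morf",
                   transcript_id = morf_tx$transcript_id,
                   rpf_start = morf_tx$cds_start, rpf_end = morf_tx$cds_end,
                   rna_start = morf_tx$cds_start, rna_end = morf_tx$cds_end)
  )

  cols <- purrr::map(seq_len(nrow(samples)), function(s) {
    smp <- samples[s, ]
    tr <- dplyr::filter(tracks, .data$sample_id == smp$sample_id)
    st <- if (smp$assay == "RPF") regions$rpf_start else regions$rna_start
    en <- if (smp$assay == "RPF") regions$rpf_end else regions$rna_end
    as.integer(region_density(tr, regions$transcript_id, st, en,
                              library_size = 1e6))
  })
  names(cols) <- samples$sample_id
  dplyr::bind_cols(regions[, c("feature_id", "feature_type")],
                   tibble::as_tibble(cols))
}

#' Median-of-ratios size factors, computed within assay
#'
#' For each assay's columns: the factor of sample j is the median over
#' all-positive features of `K_ij / geomean_i(K_i.)`. When no feature is
#' positive in every sample of the assay, falls back to total-count ratios
#' (column sum over the geometric mean of column sums) with a warning.
#'
#' @param counts Count tibble from [build_count_matrix()] (or any tibble with
#'   `feature_id` + sample columns).
#' @param samples Sample sheet (`sample_id`, `assay`).
#' @return The sample sheet with a `size_factor` column.
#' @export
size_factors <- function(counts, samples) {
  m <- .count_matrix(counts)
  sf <- stats::setNames(numeric(nrow(samples)), samples$sample_id)
  for (a in unique(samples$assay)) {
    ids <- samples$sample_id[samples$assay == a]
    sub <- m[, ids, drop = FALSE]
    allpos <- rowSums(sub > 0) == ncol(sub)
    if (any(allpos)) {
      logs <- log(sub[allpos, , drop = FALSE])
      loggeo <- rowMeans(logs)
      sf[ids] <- apply(exp(logs - loggeo), 2, stats::median)
    } else {
      warning("no feature with all-positive counts in assay ", a,
              "; using total-count size factors")
      cs <- colSums(sub)
      sf[ids] <- cs / exp(mean(log(pmax(cs, 1))))
    }
  }
  dplyr::mutate(samples, size_factor = unname(sf[samples$sample_id]))
}

#' Per-feature dispersion with trend shrinkage
#'
#' Method-of-moments dispersion per feature from normalized counts (pooled
#' over design cells with df weighting), a robust mean-dispersion trend
#' `alpha_tr(mu) = a0 + a1/mu`, and log-scale shrinkage
#' `alpha_hat = exp(w log alpha_mm + (1-w) log alpha_tr)`. The weight is set
#' by the relative widths of the per-feature likelihood and the prior around
#' the trend: the sampling variance of `log alpha_mm` is approximated by
#' `trigamma(df/2)` (df = residual degrees of freedom across design cells),
#' the prior variance is the excess spread of `log alpha_mm` about the trend
#' (floored at 0.25), and `w = s2_prior / (s2_prior + s2_lik)`. Features
#' whose moment estimate hits the zero boundary carry no dispersion
#' information and take the trend value; estimates more than two combined
#' standard deviations above the trend are treated as dispersion outliers
#' and kept unshrunk. `w` can be overridden with a fixed number. With fewer
#' than `min_features` rows the trend is replaced by the pooled median
#' dispersion (with a warning).
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param samples Sample sheet with `size_factor` (computed if absent).
#' @param w Optional fixed weight of the per-feature estimate; default
#'   (`NULL`) sets it from the relative likelihood/prior widths, falling back
#'   to 0.5 when those are inestimable.
#' @param min_features Minimum rows for trend fitting (default 50).
#' @return Tibble `feature_id`, `mu`, `alpha_mm`, `alpha_trend`, `alpha`.
#' @export
estimate_dispersion <- function(counts, samples, w = NULL,
                                min_features = 50L) {
  if (!"size_factor" %in% names(samples)) {
    samples <- size_factors(counts, samples)
  }
  m <- .count_matrix(counts)[, samples$sample_id, drop = FALSE]
  norm <- sweep(m, 2, samples$size_factor, "/")
  cell <- interaction(samples$assay, samples$condition, drop = TRUE)

  mu <- rowMeans(norm)
  num <- den <- numeric(nrow(norm))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 2) next
    cm <- rowMeans(norm[, idx, drop = FALSE])
    cv <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    df <- length(idx) - 1
    num <- num + df * (cv - cm)
    den <- den + df * cm^2
  }
  alpha_mm <- ifelse(den > 0, num / den, NA_real_)

  usable <- which(!is.na(alpha_mm) & mu > 0)
  if (length(usable) >= min_features) {
    fit_ok <- FALSE
    pos <- usable[alpha_mm[usable] > 0]
    if (length(pos) >= 10) {
      # gamma GLM with identity link models the mean of the skewed moment
      # estimates (a robust linear fit would track their median and bias the
      # trend low); iterate once dropping gross outliers
      a <- NULL
      keep <- pos
      for (it in 1:2) {
        fit <- tryCatch(
          stats::glm(alpha_mm[keep] ~ I(1 / mu[keep]),
                     family = stats::Gamma(link = "identity"),
                     start = c(stats::median(alpha_mm[keep]), 1),
                     control = stats::glm.control(maxit = 50)),
          error = function(e) NULL, warning = function(w) NULL
        )
        if (is.null(fit)) break
        a <- stats::coef(fit)
        pred <- pmax(a[1] + a[2] / mu[keep], 1e-8)
        keep <- keep[alpha_mm[keep] / pred < 15]
      }
      if (!is.null(a)) {
        alpha_trend <- pmax(a[1] + a[2] / mu, 1e-8)
        fit_ok <- TRUE
      }
    }
    if (!fit_ok) {
      fallback <- tryCatch(
        MASS::rlm(alpha_mm[pos] ~ I(1 / mu[pos]), maxit = 50),
        error = function(e) NULL
      )
      alpha_trend <- if (!is.null(fallback)) {
        a <- stats::coef(fallback)
        pmax(a[1] + a[2] / mu, 1e-8)
      } else rep(max(stats::median(alpha_mm[usable]), 1e-8), length(mu))
    }
  } else {
    warning("too few features for a dispersion trend; using pooled dispersion")
    pooled <- stats::median(alpha_mm[usable])
    if (!length(pooled) || !is.finite(pooled)) pooled <- 0.01
    alpha_trend <- rep(max(pooled, 1e-8), length(mu))
  }

  df_resid <- sum(pmax(table(cell) - 1, 0))
  s2_lik <- if (df_resid >= 2) trigamma(df_resid / 2) else NA_real_
  informative <- !is.na(alpha_mm) & alpha_mm > 0
  if (is.null(w)) {
    resid <- log(alpha_mm[informative]) - log(alpha_trend[informative])
    s2_prior <- if (length(resid) >= 10 && is.finite(s2_lik)) {
      max(stats::mad(resid)^2 - s2_lik, 0.25)
    } else 0.25
    w <- if (is.finite(s2_lik)) s2_prior / (s2_prior + s2_lik) else 0.5
  } else {
    s2_prior <- 0.25
  }

  alpha <- alpha_trend # boundary/inestimable features take the trend
  alpha[informative] <- exp(w * log(alpha_mm[informative]) +
                              (1 - w) * log(alpha_trend[informative]))
  # with few residual df a below-trend moment estimate is not evidence of
  # genuinely low dispersion; flooring at the trend keeps the Wald test from
  # borrowing significance it has not earned
  if (df_resid <= 8) alpha <- pmax(alpha, alpha_trend)
  if (is.finite(s2_lik)) {
    lratio <- rep(-Inf, length(alpha))
    lratio[informative] <- log(alpha_mm[informative]) -
      log(alpha_trend[informative])
    out_hi <- lratio > 2 * sqrt(s2_lik + s2_prior)
    alpha[out_hi] <- alpha_mm[out_hi]
  }

  tibble::tibble(feature_id = rownames(m), mu = mu, alpha_mm = alpha_mm,
                 alpha_trend = as.numeric(alpha_trend),
                 alpha = as.numeric(alpha))
}

#' Fit the NB GLM for one feature
#'
#' IRLS fit of `count ~ assay * condition` with a log link, fixed dispersion
#' `alpha` (Poisson when `alpha = 0`) and `log(size_factor)` offsets, via
#' [stats::glm()]. The RNA assay and the reference condition are the
#' baselines, so the interaction coefficient is the log fold change of TE
#' (RPF relative to RNA) in the test condition versus the reference; it is
#' reported on the log2 scale with its Wald standard error.
#'
#' @param y Integer counts, one per sample.
#' @param assay,condition Factors/character aligned with `y`; `assay` must
#'   contain `"RNA"` and `"RPF"`.
#' @param size_factor Positive offsets.
#' @param alpha Dispersion (scalar, >= 0).
#' @param reference First level of `condition`.
#' @return A list: `log2_dte`, `se`, `converged`, `coefficients`.
#' @export
fit_nb_glm <- function(y, assay, condition, size_factor, alpha,
                       reference = NULL) {
  assay <- factor(assay, levels = c("RNA", "RPF"))
  condition <- factor(condition)
  if (!is.null(reference)) condition <- stats::relevel(condition, reference)
  df <- data.frame(y = y, assay = assay, condition = condition,
                   off = log(size_factor))
  fam <- if (alpha > 0) MASS::negative.binomial(theta = 1 / alpha)
         else stats::poisson()
  fit <- suppressWarnings(
    stats::glm(y ~ assay * condition + offset(off), data = df, family = fam,
               control = stats::glm.control(maxit = 100))
  )
  # dispersion = 1: the NB variance is already encoded in the family's theta;
  # without this summary.glm would rescale SEs by a 4-df Pearson estimate
  cf <- summary(fit, dispersion = 1)$coefficients
  iname <- grep(":", rownames(cf), value = TRUE)
  est <- cf[iname, "Estimate"] / log(2)
  se <- cf[iname, "Std. Error"] / log(2)
  list(log2_dte = unname(est), se = unname(se),
       converged = isTRUE(fit$converged),
       coefficients = stats::coef(fit))
}

#' Test Delta-TE between two conditions
#'
#' For each feature: filter (features whose average raw mRNA-assay count
#' across the condition pair's RNA samples is below `min_mean_mrna` get
#' `status = "low_count"` and no test), estimate dispersions, fit the NB GLM,
#' Wald-test the assay x condition interaction
#' (`p = 2 pnorm(-|beta / se|)`), and BH-adjust p over tested features.
#'
#' @param counts Count tibble from [build_count_matrix()].
#' @param samples Sample sheet covering both assays in both conditions.
#' @param cond_pair Character vector `c(reference, test)`.
#' @param min_mean_mrna Mean-mRNA-count filter (default 10).
#' @param dispersion Optional fixed dispersion (scalar or per-feature,
#'   bypassing [estimate_dispersion()]).
#' @return An object of class `uorf_te_fit`: a list with `results` (tibble
#'   `feature_id`, `feature_type`, `base_mean`, `log2_dte`, `se`, `wald_p`,
#'   `q`, `status`), `reference`, `test`, `dispersion`.
#' @export
delta_te_test <- function(counts, samples, cond_pair,
                          min_mean_mrna = 10, dispersion = NULL) {
  stopifnot(length(cond_pair) == 2)
  samples <- dplyr::filter(samples, .data$condition %in% cond_pair)
  need <- tidyr::expand_grid(assay = c("RNA", "RPF"), condition = cond_pair)
  have <- dplyr::distinct(samples, .data$assay, .data$condition)
  if (nrow(dplyr::anti_join(need, have, by = c("assay", "condition"))) > 0) {
    stop("missing assay/condition combination in sample sheet")
  }
  m <- .count_matrix(counts)[, samples$sample_id, drop = FALSE]
  samples <- size_factors(counts[, c("feature_id", samples$sample_id)],
                          samples)

  rna_ids <- samples$sample_id[samples$assay == "RNA"]
  mean_mrna <- rowMeans(m[, rna_ids, drop = FALSE])
  all_zero <- rowSums(m) == 0
  low <- mean_mrna < min_mean_mrna | all_zero

  disp_tbl <- if (is.null(dispersion)) {
    estimate_dispersion(counts[, c("feature_id", samples$sample_id)], samples)
  } else {
    tibble::tibble(feature_id = rownames(m),
                   alpha = rep(dispersion, length.out = nrow(m)))
  }
  alpha <- disp_tbl$alpha[match(rownames(m), disp_tbl$feature_id)]

  n <- nrow(m)
  log2_dte <- se <- rep(NA_real_, n)
  status <- ifelse(low, "low_count", "ok")
  for (i in which(!low)) {
    fit <- tryCatch(
      fit_nb_glm(m[i, ], samples$assay, samples$condition,
                 samples$size_factor, alpha[i], reference = cond_pair[1]),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || !is.finite(fit$se)) {
      status[i] <- "outlier"
    } else {
      log2_dte[i] <- fit$log2_dte
      se[i] <- fit$se
    }
  }
  wald_p <- ifelse(status == "ok", 2 * stats::pnorm(-abs(log2_dte / se)),
                   NA_real_)
  q <- rep(NA_real_, n)
  q[status == "ok"] <- stats::p.adjust(wald_p[status == "ok"], method = "BH")

  base_mean <- rowMeans(sweep(m, 2, samples$size_factor, "/"))
  results <- tibble::tibble(
    feature_id = rownames(m),
    feature_type = if ("feature_type" %in% names(counts))
      counts$feature_type else NA_character_,
    base_mean = unname(base_mean), log2_dte = unname(log2_dte),
    se = unname(se), wald_p = unname(wald_p), q = unname(q),
    status = unname(status)
  )
  structure(list(results = results, reference = cond_pair[1],
                 test = cond_pair[2], dispersion = disp_tbl),
            class = "uorf_te_fit")
}

#' @export
print.uorf_te_fit <- function(x, ...) {
  ok <- x$results$status == "ok"
  cat("Delta-TE test:", x$test, "vs", x$reference, "\n")
  cat(sprintf("  %d features (%d tested, %d low_count, %d significant at q<=0.1)\n",
              nrow(x$results), sum(ok), sum(x$results$status == "low_count"),
              sum(x$results$q <= 0.1, na.rm = TRUE)))
  invisible(x)
}

.te_results <- function(x) {
  if (inherits(x, "uorf_te_fit")) x$results else x
}

#' Classify uORF regulation from uORF and mORF Delta-TE tests
#'
#' A uORF is *activated* when both its TE fold change and its relative-TE
#' fold change (uORF fold over mORF fold) are `>= fold` with `q <= fdr`;
#' *repressed* when both are `<= 1/fold` with `q <= fdr`; `low_count` when
#' either test was filtered; otherwise *unchanged*. Only the uORF test is
#' FDR-gated (the mORF fold enters as a point estimate).
#'
#' @param uorf_fit,morf_fit `uorf_te_fit` objects (or their result tibbles)
#'   for the uORF features and the mORF features.
#' @param uorfs Tibble mapping `uorf_id` to `transcript_id`.
#' @param fold,fdr Thresholds (defaults 2 and 0.1).
#' @return Tibble `uorf_id`, `transcript_id`, `dte_uorf`, `dte_morf`,
#'   `d_relative_te`, `q_uorf`, `class`.
#' @export
classify_regulation <- function(uorf_fit, morf_fit, uorfs,
                                fold = 2, fdr = 0.1) {
  ur <- .te_results(uorf_fit)
  mr <- .te_results(morf_fit)
  calls <- uorfs[, c("uorf_id", "transcript_id")] |>
    dplyr::left_join(
      dplyr::transmute(ur, uorf_id = .data$feature_id,
                       log2_u = .data$log2_dte, q_uorf = .data$q,
                       status_u = .data$status),
      by = "uorf_id"
    ) |>
    dplyr::left_join(
      dplyr::transmute(mr,
                       transcript_id = sub("_morf$", "", .data$feature_id),
                       log2_m = .data$log2_dte, status_m = .data$status),
      by = "transcript_id"
    ) |>
    dplyr::mutate(
      dte_uorf = 2^.data$log2_u,
      dte_morf = 2^.data$log2_m,
      d_relative_te = .data$dte_uorf / .data$dte_morf,
      class = dplyr::case_when(
        is.na(.data$status_u) | .data$status_u != "ok" |
          is.na(.data$status_m) | .data$status_m != "ok" ~ "low_count",
        .data$dte_uorf >= fold & .data$d_relative_te >= fold &
          .data$q_uorf <= fdr ~ "activated",
        .data$dte_uorf <= 1 / fold & .data$d_relative_te <= 1 / fold &
          .data$q_uorf <= fdr ~ "repressed",
        TRUE ~ "unchanged"
      )
    )
  dplyr::select(calls, "uorf_id", "transcript_id", "dte_uorf", "dte_morf",
                "d_relative_te", "q_uorf", "class")
}

#' Select the extreme TE-change sets
#'
#' The `n` features with the largest increases (`te_up`) and largest
#' decreases (`te_down`) in TE by point estimate; ties broken by smaller
#' p-value, then by feature id.
#'
#' @param fit A `uorf_te_fit` (or result tibble); only `status == "ok"` rows
#'   are ranked.
#' @param n Set size (default 100).
#' @return A list of two tibbles, `te_up` and `te_down`.
#' @export
select_extremes <- function(fit, n = 100L) {
  res <- dplyr::filter(.te_results(fit), .data$status == "ok")
  if (nrow(res) < 2 * n) {
    stop("need at least 2n tested features (have ", nrow(res), ")")
  }
  up <- res |>
    dplyr::arrange(dplyr::desc(.data$log2_dte), .data$wald_p,
                   .data$feature_id) |>
    dplyr::slice_head(n = n)
  down <- res |>
    dplyr::arrange(.data$log2_dte, .data$wald_p, .data$feature_id) |>
    dplyr::slice_head(n = n)
  list(te_up = up, te_down = down)
}

#' Correlations diagnosing a 5'-UTR isoform confound
#'
#' Spearman correlations of Delta-TE with the changes in RPF density, mRNA
#' density, and 5'-UTR mRNA density. A TE change driven by translation shows
#' high correlation with Delta-RPF and low correlation with both mRNA terms;
#' correlation with the 5'-UTR mRNA change would instead suggest alternative
#' transcription start sites shifting isoform levels.
#'
#' @param dte,d_rpf,d_mrna,d_mrna_utr5 Aligned numeric vectors (any log or
#'   fold scale; only ranks are used).
#' @return Tibble `term`, `rho`, `p`, `n`.
#' @export
check_utr_isoform_confound <- function(dte, d_rpf, d_mrna, d_mrna_utr5) {
  one <- function(term, y) {
    s <- spearman(dte, y)
    tibble::tibble(term = term, rho = s$rho, p = s$p, n = s$n)
  }
  dplyr::bind_rows(
    one("d_rpf", d_rpf),
    one("d_mrna", d_mrna),
    one("d_mrna_utr5", d_mrna_utr5)
  )
}
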