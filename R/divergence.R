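# Bootstrap divergence point analysis: per-bin one-sample t-tests against
# 0.50, run-length onset detection, stratified trial-level resampling with
# percentile confidence intervals.

#' Onset criterion
#'
#' The divergence point is the left edge of the first bin starting a run of
#' at least `run_length` consecutive bins whose one-sample t-test against
#' 0.50 is significant at `alpha` (strict inequality), searched within
#' `window` (default verb onset to 1500 ms after; 10 bins of 50 ms = 500 ms
#' of sustained significance).
#'
#' @param alpha Significance level per bin.
#' @param run_length Minimum number of consecutive significant bins.
#' @param window Analysis window in ms relative to verb onset.
#' @param bin_ms Bin width in ms.
#' @return Object of class `onset_criterion`.
#' @export
onset_criterion <- function(alpha = 0.05, run_length = 10,
                            window = c(0, 1500), bin_ms = 50) {
  stopifnot(alpha > 0, alpha < 1, run_length >= 1)
  n_bins <- length(bin_lattice(window, bin_ms))
  if (n_bins < run_length) {
    stop("analysis window holds ", n_bins, " bins, fewer than run_length = ",
         run_length, call. = FALSE)
  }
  structure(list(alpha = alpha, run_length = as.integer(run_length),
                 window = window, bin_ms = bin_ms),
            class = "onset_criterion")
}

#' Bootstrap configuration
#'
#' @param n_boot Number of bootstrap resamples.
#' @param ci_level Confidence level for the percentile interval.
#' @param seed RNG seed; per-replicate sub-seeds are derived up front so
#'   results do not depend on execution order.
#' @param literal_bins If `TRUE`, resample cells of participant x time point
#'   x image type independently (a strictly literal reading of the stratum
#'   definition) instead of whole trials within participant x image type.
#'   Whole-trial resampling is the default because it preserves the
#'   within-trial temporal autocorrelation the bootstrap exists to respect.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 2000, ci_level = 0.95, seed = 1L,
                             literal_bins = FALSE) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), literal_bins = isTRUE(literal_bins)),
            class = "bootstrap_config")
}

#' Per-bin one-sample t-tests against a null proportion
#'
#' Tests the participant means at each bin against `mu0` (two-sided,
#' df = n - 1). Bins with fewer than two defined participant values are
#' untestable and get `NA`. Degenerate bins with zero variance use the
#' convention t = +/-Inf, p = 0 when the mean differs from `mu0`, and
#' t = 0, p = 1 when it equals it.
#'
#' @param curves A [proportion_curves()] object, or a participant x bin
#'   matrix of proportions.
#' @param mu0 Null value (0.50: equal looks to the two sets).
#' @return Tibble: bin_start_ms, mean, t, p, n.
#' @export
pointwise_tests <- function(curves, mu0 = 0.5) {
  if (inherits(curves, "proportion_curves")) {
    P <- curves$P
    bins <- curves$bins
  } else {
    P <- as.matrix(curves)
    bins <- as.integer(colnames(P) %||% seq_len(ncol(P)))
  }
  res <- t_stats(P, mu0)
  if (all(is.na(res$t))) {
    stop("no bin has two or more defined participant values; nothing to test",
         call. = FALSE)
  }
  tibble::tibble(bin_start_ms = bins, mean = res$m, t = res$t, p = res$p,
                 n = res$n)
}

# Vectorised core shared with the bootstrap: column-wise one-sample t.
t_stats <- function(P, mu0 = 0.5) {
  n <- colSums(!is.na(P))
  m <- colMeans(P, na.rm = TRUE)
  # column sds with NA removal, without apply() overhead
  dev <- sweep(P, 2, m)
  ss <- colSums(dev * dev, na.rm = TRUE)
  testable <- n >= 2
  v <- ifelse(testable, ss / pmax(n - 1, 1), NA_real_)
  se <- sqrt(v / n)
  t <- ifelse(testable,
              ifelse(se > 0, (m - mu0) / se,
                     ifelse(m == mu0, 0, sign(m - mu0) * Inf)),
              NA_real_)
  p <- ifelse(is.na(t), NA_real_,
              ifelse(is.finite(t), 2 * pt(-abs(t), df = n - 1),
                     ifelse(t == 0, 1, 0)))
  # zero-variance, mean == mu0 gives t = 0 above with p = 1 via pt; make exact
  p[!is.na(t) & t == 0] <- 1
  list(m = unname(ifelse(n > 0, m, NA_real_)), t = unname(t),
       p = unname(p), n = as.integer(unname(n)))
}

#' Detect the divergence onset from per-bin p values
#'
#' Scans the bins inside the criterion's analysis window for the first run
#' of at least `run_length` consecutive bins with p < alpha and returns the
#' left edge of the run's first bin, or `NA` if no such run exists.
#' Untestable bins (`NA` p) count as not significant.
#'
#' @param tests Tibble from [pointwise_tests()], or a numeric p-value vector
#'   with bins as names.
#' @param criterion An [onset_criterion()].
#' @return Onset in ms (bin left edge) or `NA_real_`.
#' @export
detect_onset <- function(tests, criterion = onset_criterion()) {
  if (is.data.frame(tests)) {
    bins <- tests$bin_start_ms
    p <- tests$p
  } else {
    p <- as.numeric(tests)
    bins <- as.numeric(names(tests))
    if (!length(bins) || anyNA(bins)) {
      stop("p-value vector must carry bin left edges as names", call. = FALSE)
    }
  }
  keep <- bins >= criterion$window[1] & bins < criterion$window[2]
  bins <- bins[keep]
  p <- p[keep]
  if (length(bins) < criterion$run_length) {
    stop("analysis window holds ", length(bins),
         " bins, fewer than run_length = ", criterion$run_length,
         call. = FALSE)
  }
  sig <- !is.na(p) & p < criterion$alpha
  runs <- rle(sig)
  hit <- which(runs$values & runs$lengths >= criterion$run_length)
  if (!length(hit)) return(NA_real_)
  first <- sum(runs$lengths[seq_len(hit[1] - 1)]) + 1
  bins[first]
}

#' Bootstrap distribution of the divergence point
#'
#' The three-step procedure: (1) per-bin one-sample t-tests of the
#' participant proportion curves against 0.50; (2) onset = first of at
#' least `run_length` consecutive significant bins in the analysis window;
#' (3) non-parametric bootstrap -- trials are resampled with replacement
#' within participant x image-type strata, each resampled trial carrying
#' its whole time course; curves, tests and onset are recomputed per
#' resample. The mean divergence point and the percentile CI are taken over
#' the resamples in which an onset was detected; `detection_rate` reports
#' that fraction. A dataset with no detectable divergence returns onset
#' `NA` and detection statistics rather than an error.
#'
#' @param table Binned fixation table already restricted to the analysed
#'   trial subset.
#' @param contrast A [contrast_spec()] or contrast name.
#' @param criterion An [onset_criterion()].
#' @param boot A [bootstrap_config()].
#' @param denominator Passed to the proportion pooling; see
#'   [proportion_curves()].
#' @param window,bin_ms Bin lattice of the table.
#' @return Object of class `divergence_result`; see Details.
#' @export
bootstrap_divergence <- function(table, contrast,
                                 criterion = onset_criterion(),
                                 boot = bootstrap_config(),
                                 denominator = "ab",
                                 window = c(-1000, 1500), bin_ms = 50) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  counts <- contrast_counts(table, contrast, window, bin_ms)

  # observed curves and tests on the full lattice; onset within the window
  pooled <- pool_proportions(counts, denominator)
  obs_tests <- pointwise_tests(
    structure(list(P = pooled$P, bins = counts$bins),
              class = "proportion_curves"))
  observed_onset <- detect_onset(obs_tests, criterion)

  # restrict the replicate computation to the analysis window
  win <- counts$bins >= criterion$window[1] & counts$bins < criterion$window[2]
  bins_w <- counts$bins[win]
  A <- counts$A[, win, drop = FALSE]
  B <- counts$B[, win, drop = FALSE]
  strata <- split(seq_along(counts$stratum), counts$stratum)
  parts <- counts$participants
  pi_of_stratum <- match(
    vapply(strata, function(rows) counts$participant[rows[1]], ""), parts)
  use_all <- denominator == "all"

  set.seed(boot$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, boot$n_boot)
  onsets <- rep(NA_real_, boot$n_boot)
  n_parts <- length(parts)
  nb <- length(bins_w)

  for (r in seq_len(boot$n_boot)) {
    set.seed(rep_seeds[r])
    a_sum <- matrix(0, n_parts, nb)
    d_sum <- matrix(0, n_parts, nb)
    if (boot$literal_bins) {
      for (s in seq_along(strata)) {
        rows <- strata[[s]]
        pi <- pi_of_stratum[s]
        # independent resampling of the trial values at every time point
        for (j in seq_len(nb)) {
          idx <- rows[sample.int(length(rows), length(rows), replace = TRUE)]
          a_sum[pi, j] <- a_sum[pi, j] + sum(A[idx, j])
          d_sum[pi, j] <- d_sum[pi, j] +
            (if (use_all) length(idx) else sum(A[idx, j]) + sum(B[idx, j]))
        }
      }
    } else {
      for (s in seq_along(strata)) {
        rows <- strata[[s]]
        pi <- pi_of_stratum[s]
        idx <- rows[sample.int(length(rows), length(rows), replace = TRUE)]
        a <- colSums(A[idx, , drop = FALSE])
        a_sum[pi, ] <- a_sum[pi, ] + a
        d_sum[pi, ] <- d_sum[pi, ] +
          (if (use_all) length(idx) else a + colSums(B[idx, , drop = FALSE]))
      }
    }
    P <- ifelse(d_sum > 0, a_sum / d_sum, NA_real_)
    st <- t_stats(P, 0.5)
    sig <- !is.na(st$p) & st$p < criterion$alpha
    runs <- rle(sig)
    hit <- which(runs$values & runs$lengths >= criterion$run_length)
    if (length(hit)) {
      onsets[r] <- bins_w[sum(runs$lengths[seq_len(hit[1] - 1)]) + 1]
    }
  }

  detected <- onsets[!is.na(onsets)]
  qs <- c((1 - boot$ci_level) / 2, 1 - (1 - boot$ci_level) / 2)
  structure(
    list(
      contrast = contrast$name,
      bins = obs_tests,
      onset_ms = observed_onset,
      boot_onsets = onsets,
      detection_rate = length(detected) / boot$n_boot,
      mean_divergence_ms = if (length(detected)) mean(detected) else NA_real_,
      ci_low_ms = if (length(detected))
        unname(quantile(detected, qs[1], type = 1)) else NA_real_,
      ci_high_ms = if (length(detected))
        unname(quantile(detected, qs[2], type = 1)) else NA_real_,
      criterion = unclass(criterion),
      boot_config = unclass(boot)
    ),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("<divergence_result> contrast:", x$contrast, "\n")
  if (is.na(x$onset_ms)) {
    cat("  observed onset: none\n")
  } else {
    cat("  observed onset:", x$onset_ms, "ms after verb onset\n")
  }
  if (x$detection_rate > 0) {
    cat(sprintf("  bootstrap mean divergence: %.0f ms, %d%% CI [%g, %g]\n",
                x$mean_divergence_ms, round(100 * x$boot_config$ci_level),
                x$ci_low_ms, x$ci_high_ms))
  }
  cat(sprintf("  detection rate: %.3f over %d resamples\n",
              x$detection_rate, x$boot_config$n_boot))
  invisible(x)
}

#' Run one named contrast end to end
#'
#' Composes [select_trials()], [proportion_curves()], [pointwise_tests()],
#' [detect_onset()] and [bootstrap_divergence()] for a contrast and trial
#' subset named as in the study design.
#'
#' @param table Full binned fixation table.
#' @param contrast_name `"targets_vs_distractors"` or
#'   `"compatible_vs_incompatible"`.
#' @param subset Trial subset for [select_trials()].
#' @param criterion An [onset_criterion()].
#' @param boot A [bootstrap_config()].
#' @param denominator See [proportion_curves()].
#' @param window,bin_ms Bin lattice of the table.
#' @return A `divergence_result` with the subset and retained-trial counts
#'   attached.
#' @export
run_contrast <- function(table, contrast_name, subset,
                         criterion = onset_criterion(),
                         boot = bootstrap_config(),
                         denominator = "ab",
                         window = c(-1000, 1500), bin_ms = 50) {
  sel <- tryCatch(select_trials(table, subset),
                  error = function(e) stop("select_trials: ",
                                           conditionMessage(e), call. = FALSE))
  res <- tryCatch(
    bootstrap_divergence(sel, contrast_name, criterion, boot,
                         denominator, window, bin_ms),
    error = function(e) stop("bootstrap_divergence: ", conditionMessage(e),
                             call. = FALSE))
  res$subset <- subset
  res$n_trials <- attr(sel, "n_trials")
  res
}
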