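#' Two-sided Wilcoxon rank-sum test
#'
#' For combined sample sizes up to 12 the null distribution of the rank
#' sum is enumerated completely (mid-ranks for ties), and the two-sided p
#' is `min(1, 2 * min(P(W <= w), P(W >= w)))`. For larger samples a
#' normal approximation with tie correction and (by default) continuity
#' correction is used. The test is invariant under any strictly
#' increasing transform applied to both samples.
#'
#' @param x,y numeric samples.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation.
#' @param exact_max largest combined size for exact enumeration.
#' @return List with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, continuity = TRUE, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (N <= exact_max) {
    sums <- utils::combn(r, n1, sum)
    ple <- mean(sums <= W + 1e-9)
    pge <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(ple, pge))
    method <- "exact enumeration"
  } else {
    mu <- n1 * (N + 1) / 2
    tie <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = W, p.value = 1,
                               method = "normal approximation"))
    d <- W - mu
    cc <- if (continuity) 0.5 * sign(d) else 0
    z <- (d - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p.value = p, method = method)
}

#' Simulated-cohort rank-sum p-values
#'
#' Draws `n_rep` replicate two-group cohorts from normal distributions
#' with the given group means and SDs and returns the two-sided rank-sum
#' p-value of each replicate. Used to ask whether group summary
#' statistics of a metric imply a detectable difference at given sample
#' sizes.
#'
#' @param n1,mean1,sd1 first group size and distribution.
#' @param n2,mean2,sd2 second group size and distribution.
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return Numeric vector of `n_rep` p-values.
#' @export
simulate_metric_pvalues <- function(n1, mean1, sd1, n2, mean2, sd2,
                                    n_rep = 200L, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      a <- stats::rnorm(n1, mean1, sd1)
      b <- stats::rnorm(n2, mean2, sd2)
      rank_sum_test(a, b)$p.value
    }, 0)
  })
}

.metric_cols <- c("mean_amplitude", "local_sd", "mean_slope",
                  "rel_peak_depth_mm")

#' Per-lesion metrics table from a list of lesion_metrics
#'
#' @param metrics_list list of `lesion_metrics` objects.
#' @return A data frame with one row per lesion.
#' @export
metrics_table <- function(metrics_list) {
  do.call(rbind, lapply(metrics_list, function(m) {
    data.frame(scan_id = m$scan_id,
               group_label = as.character(m$group_label),
               mean_amplitude = m$mean_amplitude,
               local_sd = m$local_sd,
               mean_slope = m$mean_slope,
               rel_peak_depth_mm = m$rel_peak_depth_mm,
               d_N_mm = m$d_N_mm, d_L_mm = m$d_L_mm,
               n_lesion_px = m$n_lesion_px,
               n_normal_px = m$n_normal_px,
               stringsAsFactors = FALSE)
  }))
}

#' Cohort summary: group means, SDs, and rank-sum p-values
#'
#' Summarizes a per-lesion metrics table per group (mean and sample SD;
#' SD is `NA` below two lesions) and compares the two groups per metric
#' with the two-sided rank-sum test. Lesions with an undefined value of a
#' metric are excluded pairwise, with counts reported.
#'
#' @param per_lesion data frame from [metrics_table()] (or [run_cohort()]).
#' @param group_col name of the group column.
#' @param metrics metric column names to summarize.
#' @return An object of class `cohort_result` with `per_lesion`,
#'   `group_summary`, and `p_values` data frames.
#' @export
cohort_summary <- function(per_lesion, group_col = "group_label",
                           metrics = .metric_cols) {
  groups <- sort(unique(per_lesion[[group_col]]))
  gs <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      v <- per_lesion[per_lesion[[group_col]] == g, m]
      v <- v[!is.na(v)]
      data.frame(metric = m, group = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  pv <- do.call(rbind, lapply(metrics, function(m) {
    p <- NA_real_
    if (length(groups) == 2L) {
      a <- per_lesion[per_lesion[[group_col]] == groups[1], m]
      b <- per_lesion[per_lesion[[group_col]] == groups[2], m]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) && length(b)) p <- rank_sum_test(a, b)$p.value
    }
    data.frame(metric = m, p_value = p, stringsAsFactors = FALSE)
  }))
  structure(list(per_lesion = per_lesion, group_summary = gs,
                 p_values = pv),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", nrow(x$per_lesion), "lesions\n")
  print(x$group_summary, row.names = FALSE)
  cat("\nTwo-sided Wilcoxon rank-sum tests (no multiplicity correction):\n")
  print(x$p_values, row.names = FALSE)
  invisible(x)
}

#' Export cohort results as CSV and JSON
#'
#' Writes `per_lesion.csv`, `group_summary.csv`, and `p_values.json`.
#'
#' @param result a `cohort_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(result, dir) {
  stopifnot(inherits(result, "cohort_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$per_lesion, file.path(dir, "per_lesion.csv"),
                   row.names = FALSE)
  utils::write.csv(result$group_summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  pv <- stats::setNames(as.list(result$p_values$p_value),
                        result$p_values$metric)
  jsonlite::write_json(pv, file.path(dir, "p_values.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Histogram summary of a metric's per-pixel distribution
#'
#' Fixed-count equal-width binning over the observed range, for
#' report-style histograms of per-pixel slope, depth, or local-SD values.
#'
#' @param values numeric vector.
#' @param bins number of bins.
#' @return Data frame with `mid`, `count`.
#' @export
metric_histogram <- function(values, bins = 50L) {
  values <- values[is.finite(values)]
  if (!length(values)) return(data.frame(mid = numeric(0), count = integer(0)))
  rg <- range(values)
  if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
  br <- seq(rg[1], rg[2], length.out = bins + 1L)
  h <- graphics::hist(values, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
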