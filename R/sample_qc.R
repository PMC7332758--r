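## Sample-level quality control: detection p-values, low-quality flags,
## outlier detection and the tissue-quality contingency test.

#' Detection p-values from negative-control background
#'
#' For each probe and sample, the probability that the probe's total
#' signal (meth + unmeth) arose from background.  The background is
#' modeled as normal with mean and SD estimated per sample from the
#' negative-control probes of each channel; for Type II probes the two
#' channel means (and SDs) are summed, for Type I probes the single
#' channel's background is doubled.  p = 1 - Phi((total - mu_bg) /
#' sigma_bg).
#'
#' @param ds A `MethylationDataset`.
#' @param annotation Optional probe annotation supplying `design_type`;
#'   when `NULL` all probes are treated as Type II.
#' @return Matrix (probe x sample) of p-values in `[0, 1]`.
#' @export
detection_pvalues <- function(ds, annotation = NULL) {
  neg <- ds$controls[ds$controls$control_type == "negative", ]
  sids <- colnames(ds$meth)
  ng <- as.matrix(neg[neg$channel == "green", sids, drop = FALSE])
  nr <- as.matrix(neg[neg$channel == "red", sids, drop = FALSE])
  if (nrow(ng) < 3 || nrow(nr) < 3)
    stop("need at least 3 negative controls per channel")
  mu_g <- colMeans(ng); sd_g <- apply(ng, 2, sd)
  mu_r <- colMeans(nr); sd_r <- apply(nr, 2, sd)
  np <- nrow(ds$meth)
  if (is.null(annotation)) {
    design <- rep("II", np)
  } else {
    design <- annotation$design_type[match(rownames(ds$meth),
                                           annotation$probe_id)]
  }
  mu_bg <- matrix(NA_real_, np, length(sids))
  sd_bg <- matrix(NA_real_, np, length(sids))
  fill <- function(mask, vals) {
    if (any(mask)) matrix(vals, sum(mask), length(sids), byrow = TRUE)
  }
  type2 <- design == "II"
  g_only <- design == "I-green"
  r_only <- design == "I-red"
  mu_bg[type2, ] <- fill(type2, mu_g + mu_r)
  sd_bg[type2, ] <- fill(type2, sd_g + sd_r)
  mu_bg[g_only, ] <- fill(g_only, 2 * mu_g)
  sd_bg[g_only, ] <- fill(g_only, 2 * sd_g)
  mu_bg[r_only, ] <- fill(r_only, 2 * mu_r)
  sd_bg[r_only, ] <- fill(r_only, 2 * sd_r)
  total <- ds$meth + ds$unmeth
  p <- 1 - pnorm((total - mu_bg) / sd_bg)
  dimnames(p) <- dimnames(ds$meth)
  p
}

## mean bisulfite-conversion control intensity per sample (both channels)
bisulfite_means <- function(ds) {
  bis <- ds$controls[ds$controls$control_type == "bisulfite", ]
  colMeans(as.matrix(bis[, colnames(ds$meth), drop = FALSE]))
}

#' Flag low-quality samples
#'
#' A sample is flagged `low_bisulfite` when its mean bisulfite-conversion
#' control intensity falls more than `sd_mult` standard deviations below
#' the mean over all samples in the batch, and `high_detection_failure`
#' when more than `frac_thresh` of its probes are inadequately detected
#' (detection p > `p_thresh` or fewer than `bead_thresh` beads).
#'
#' @param ds A `MethylationDataset` (one tissue batch).
#' @param detp Detection p-value matrix from [detection_pvalues()].
#' @param p_thresh,bead_thresh Per-probe detection thresholds
#'   (defaults 0.01 and 3).
#' @param frac_thresh Maximum tolerated fraction of poorly detected
#'   probes per sample (default 0.01).
#' @param sd_mult Bisulfite-intensity fence in SD units (default 3).
#' @return A `SampleQCReport` data frame: per-sample metrics, individual
#'   flags, and overall `fail`; thresholds are attached as attributes.
#' @export
flag_low_quality_samples <- function(ds, detp, p_thresh = 0.01,
                                     bead_thresh = 3, frac_thresh = 0.01,
                                     sd_mult = 3) {
  sids <- colnames(ds$meth)
  if (length(sids) < 2)
    stop("bisulfite threshold undefined for a single-sample batch ",
         "(between-sample SD cannot be estimated)")
  bis <- bisulfite_means(ds)
  thr <- mean(bis) - sd_mult * sd(bis)
  poor <- detp > p_thresh | ds$beads < bead_thresh
  frac_poor <- colMeans(poor)
  report <- data.frame(
    sample_id = sids,
    bisulfite_mean_intensity = as.numeric(bis),
    fraction_poor_probes = as.numeric(frac_poor),
    low_bisulfite = as.numeric(bis) < thr,
    high_detection_failure = as.numeric(frac_poor) > frac_thresh,
    stringsAsFactors = FALSE)
  report$fail <- report$low_bisulfite | report$high_detection_failure
  attr(report, "thresholds") <- list(
    bisulfite_threshold = thr, p_thresh = p_thresh,
    bead_thresh = bead_thresh, frac_thresh = frac_thresh,
    sd_mult = sd_mult)
  report
}

#' Flag total-intensity outlier samples
#'
#' A sample is an intensity outlier when its median log2 total intensity
#' (meth + unmeth) falls below the across-sample median by more than
#' `mad_mult` * MAD (scaled, consistent with a normal SD).  The fence is
#' floored at `min_drop` log2 units below the median: in a technically
#' tight cohort the MAD can become arbitrarily small, and a sample whose
#' total intensity is within ~1.4x of the rest is not a failed assay.
#'
#' @param ds A `MethylationDataset`.
#' @param mad_mult Fence multiplier, default 3.
#' @param min_drop Minimum log2 drop below the cohort median for a flag,
#'   default 0.5.
#' @return Named logical vector per sample.
#' @export
flag_intensity_outliers <- function(ds, mad_mult = 3, min_drop = 0.5) {
  if (ncol(ds$meth) < 5)
    stop("need at least 5 samples for outlier detection")
  med <- apply(log2(ds$meth + ds$unmeth + 1), 2, median)
  ## mad() includes the 1.4826 consistency factor
  fence <- median(med) - max(mad_mult * mad(med), min_drop)
  out <- med < fence
  names(out) <- colnames(ds$meth)
  out
}

#' Flag beta-distribution outlier samples
#'
#' Compares each sample's beta-value distribution to the distribution of
#' per-probe median betas (the "typical" profile) by the Kolmogorov-
#' Smirnov distance; samples farther than `ks_thresh` are flagged.
#'
#' @param beta Beta matrix (probe x sample).
#' @param ks_thresh Maximum tolerated KS distance, default 0.15.
#' @return Named logical vector per sample.
#' @export
flag_beta_outliers <- function(beta, ks_thresh = 0.15) {
  if (ncol(beta) < 5)
    stop("need at least 5 samples for outlier detection")
  ref <- apply(beta, 1, median)
  d <- vapply(seq_len(ncol(beta)), function(s)
    ks_distance(beta[, s], ref), numeric(1))
  out <- d > ks_thresh
  names(out) <- colnames(beta)
  out
}

## two-sample KS distance (sup norm of ECDF difference)
ks_distance <- function(x, y) {
  suppressWarnings(unname(ks.test(x, y)$statistic))
}

#' Full sample QC for one tissue batch
#'
#' Combines [flag_low_quality_samples()], [flag_intensity_outliers()] and
#' [flag_beta_outliers()] into one per-sample report.  Fixed-methylation
#' control samples should be excluded from `ds` before calling (their
#' beta distributions are degenerate by design); [run_pipeline()] does
#' this.
#'
#' @inheritParams flag_low_quality_samples
#' @param annotation Optional probe annotation for [detection_pvalues()].
#' @param ks_thresh,mad_mult Outlier thresholds.
#' @return `SampleQCReport` data frame with all four flags and `fail`.
#' @export
sample_qc_report <- function(ds, annotation = NULL, p_thresh = 0.01,
                             bead_thresh = 3, frac_thresh = 0.01,
                             sd_mult = 3, mad_mult = 3,
                             ks_thresh = 0.15) {
  detp <- detection_pvalues(ds, annotation)
  report <- flag_low_quality_samples(ds, detp, p_thresh, bead_thresh,
                                     frac_thresh, sd_mult)
  report$intensity_outlier <- as.logical(flag_intensity_outliers(
    ds, mad_mult))
  beta <- beta_from_intensities(ds$meth, ds$unmeth)
  report$beta_outlier <- as.logical(flag_beta_outliers(beta, ks_thresh))
  report$fail <- report$low_bisulfite | report$high_detection_failure |
    report$intensity_outlier | report$beta_outlier
  report
}

#' Fisher's exact test on sample failure counts of two tissues
#'
#' Two-sided exact test (point-probability rule) of whether the failure
#' rate differs between tissues, as used to compare CSF and blood sample
#' quality.
#'
#' @param n_fail_a,n_total_a Failures and totals in tissue A.
#' @param n_fail_b,n_total_b Failures and totals in tissue B.
#' @return List with `p_value`, `odds_ratio` (conditional MLE) and the
#'   2x2 `table`.
#' @export
tissue_failure_test <- function(n_fail_a, n_total_a, n_fail_b,
                                n_total_b) {
  stopifnot(n_fail_a >= 0, n_fail_b >= 0,
            n_fail_a <= n_total_a, n_fail_b <= n_total_b)
  tab <- matrix(c(n_fail_a, n_total_a - n_fail_a,
                  n_fail_b, n_total_b - n_fail_b),
                nrow = 2,
                dimnames = list(c("fail", "pass"),
                                c("tissue_a", "tissue_b")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_, table = tab))
  ft <- fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       table = tab)
}
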