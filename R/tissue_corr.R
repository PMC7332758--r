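## Blood-vs-CSF concordance: extreme-beta filtering, covariate/SV
## adjustment, within-CpG and within-individual correlations, and
## stratified comparisons across annotation categories.

#' Filter CpGs with uniformly extreme betas in both tissues
#'
#' Removes CpG sites where every individual beta value is above `hi` or
#' every one is below `lo` across both tissues: methylation at such
#' sites has essentially no biological variation, and any correlation
#' there would be uninformative.
#'
#' @param beta_blood,beta_csf Beta matrices (probe x sample) over the
#'   same probe universe.
#' @param lo,hi Extremeness bounds (defaults 0.10 and 0.90).
#' @return Character vector of retained probe IDs.
#' @export
extreme_beta_filter <- function(beta_blood, beta_csf, lo = 0.10,
                                hi = 0.90) {
  stopifnot(identical(rownames(beta_blood), rownames(beta_csf)))
  all_hi <- rowSums(beta_blood <= hi) == 0 & rowSums(beta_csf <= hi) == 0
  all_lo <- rowSums(beta_blood >= lo) == 0 & rowSums(beta_csf >= lo) == 0
  rownames(beta_blood)[!(all_hi | all_lo)]
}

#' Adjust M-values for covariates and surrogate variables
#'
#' Per CpG, removes the least-squares effects of age, sex and the
#' surrogate variables (all centered).  By default the probe-level mean
#' (the fitted intercept) is retained, so adjusted values stay on the M
#' scale and within-individual profile correlations remain meaningful;
#' with `keep_intercept = FALSE` plain residuals (orthogonal to every
#' design column including the intercept) are returned.
#'
#' @param m M-value matrix (probe x sample).
#' @param age Numeric vector per sample.
#' @param sex Character/factor vector per sample.
#' @param svs Optional surrogate-variable matrix (sample x n_sv).
#' @param keep_intercept Keep the per-probe mean? Default `TRUE`.
#' @return Adjusted matrix, same shape as `m`.
#' @export
adjust_mvalues <- function(m, age, sex, svs = NULL,
                           keep_intercept = TRUE) {
  n <- ncol(m)
  df <- data.frame(age = age, sex = sex)
  varying <- vapply(df, function(x)
    length(unique(x[!is.na(x)])) > 1, logical(1))
  df <- df[, varying, drop = FALSE]
  X <- if (ncol(df)) model.matrix(~ ., data = df)
       else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(svs)) X <- cbind(X, as.matrix(svs))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("adjustment design is rank deficient; collinear columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
               collapse = ", "))
  Xc <- X[, -1, drop = FALSE]
  Xc <- scale(Xc, center = TRUE, scale = FALSE)
  if (ncol(Xc) == 0) {
    adj <- if (keep_intercept) m else m - rowMeans(m)
    return(adj)
  }
  B <- m %*% Xc %*% chol2inv(chol(crossprod(Xc)))
  adj <- m - B %*% t(Xc)
  if (!keep_intercept) adj <- adj - rowMeans(adj)
  dimnames(adj) <- dimnames(m)
  adj
}

#' Within-CpG cross-tissue correlation
#'
#' Pearson (or Spearman) correlation, at each CpG, between the paired
#' subjects' blood and CSF adjusted values.  Correlation is used rather
#' than a direct comparison of absolute values because it is invariant
#' to systematic shifts in mean and scale, such as a between-plate batch
#' offset.
#'
#' @param adj_blood,adj_csf Adjusted M matrices (probe x sample).
#' @param subject_pairs Data frame with columns `blood` and `csf` naming
#'   the paired sample IDs (one row per subject).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Named numeric vector of per-CpG correlations (`NA` where a
#'   tissue has zero variance at that CpG).
#' @export
within_cpg_correlation <- function(adj_blood, adj_csf, subject_pairs,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(identical(rownames(adj_blood), rownames(adj_csf)))
  if (nrow(subject_pairs) < 3)
    stop("need at least 3 complete subject pairs")
  xb <- adj_blood[, subject_pairs$blood, drop = FALSE]
  xc <- adj_csf[, subject_pairs$csf, drop = FALSE]
  if (method == "spearman") {
    xb <- t(apply(xb, 1, rank))
    xc <- t(apply(xc, 1, rank))
  }
  xb <- xb - rowMeans(xb)
  xc <- xc - rowMeans(xc)
  num <- rowSums(xb * xc)
  den <- sqrt(rowSums(xb^2) * rowSums(xc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  names(r) <- rownames(adj_blood)
  r
}

#' Within-individual cross-tissue correlation
#'
#' For each paired subject, the correlation between their blood and CSF
#' adjusted profiles across all retained CpGs.
#'
#' @inheritParams within_cpg_correlation
#' @return Named numeric vector, one correlation per subject pair.
#' @export
within_individual_correlation <- function(adj_blood, adj_csf,
                                          subject_pairs,
                                          method = c("pearson",
                                                     "spearman")) {
  method <- match.arg(method)
  if (nrow(adj_blood) < 10)
    stop("need at least 10 retained CpGs")
  r <- vapply(seq_len(nrow(subject_pairs)), function(i)
    cor(adj_blood[, subject_pairs$blood[i]],
        adj_csf[, subject_pairs$csf[i]], method = method),
    numeric(1))
  names(r) <- if (!is.null(subject_pairs$subject_id))
    subject_pairs$subject_id else subject_pairs$blood
  r
}

#' Compare correlations across annotation strata
#'
#' Summarizes per-CpG correlations within each level of an annotation
#' field (genomic region or gene orientation), and tests for
#' between-stratum differences with a Kruskal-Wallis omnibus test and
#' pairwise two-sided Mann-Whitney tests under Bonferroni correction.
#' CpGs with `NA` correlation are excluded (count reported); strata
#' below `min_stratum` CpGs are dropped with a warning.
#'
#' @param r Named per-CpG correlation vector (names = probe IDs).
#' @param annotation Probe annotation table.
#' @param strata_field Annotation column to stratify by (e.g.
#'   `"region"` or `"orientation"`).
#' @param min_stratum Minimum CpGs per stratum (default 10).
#' @return List with `summary` (per-stratum n/mean/median/quartiles),
#'   `omnibus` (Kruskal-Wallis statistic and p), `pairwise`
#'   (Bonferroni-adjusted p-value matrix), `n_na` (excluded CpGs).
#' @export
stratified_comparison <- function(r, annotation, strata_field,
                                  min_stratum = 10) {
  stopifnot(strata_field %in% names(annotation))
  strata <- annotation[[strata_field]][match(names(r),
                                             annotation$probe_id)]
  keep <- !is.na(r) & !is.na(strata)
  n_na <- sum(is.na(r))
  r <- r[keep]; strata <- strata[keep]
  counts <- table(strata)
  small <- names(counts)[counts < min_stratum]
  if (length(small)) {
    warning("dropping strata below ", min_stratum, " CpGs: ",
            paste(small, collapse = ", "))
    keep <- !(strata %in% small)
    r <- r[keep]; strata <- strata[keep]
  }
  if (length(unique(strata)) < 2)
    stop("need at least 2 strata with at least ", min_stratum,
         " CpGs each")
  strata <- factor(strata)
  summary_df <- do.call(rbind, lapply(levels(strata), function(g) {
    x <- r[strata == g]
    data.frame(stratum = g, n = length(x), mean = mean(x),
               median = median(x), q25 = unname(quantile(x, 0.25)),
               q75 = unname(quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  kw <- kruskal.test(r, strata)
  pw <- stats::pairwise.wilcox.test(r, strata, p.adjust.method =
                                      "bonferroni", exact = FALSE)
  list(summary = summary_df,
       omnibus = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value),
       pairwise = pw$p.value,
       n_na = n_na,
       tests = "Kruskal-Wallis omnibus; pairwise Mann-Whitney, Bonferroni")
}

#' Pair blood and CSF samples of the same subjects
#'
#' @param samples Sample sheet.
#' @param blood_ids,csf_ids Candidate sample IDs for each tissue (e.g. a
#'   day subset); each subject contributes at most one pair.
#' @return Data frame with columns `subject_id`, `blood`, `csf`.
#' @export
pair_subjects <- function(samples, blood_ids, csf_ids) {
  b <- samples[samples$sample_id %in% blood_ids, ]
  c_ <- samples[samples$sample_id %in% csf_ids, ]
  shared <- intersect(b$subject_id, c_$subject_id)
  data.frame(
    subject_id = shared,
    blood = b$sample_id[match(shared, b$subject_id)],
    csf = c_$sample_id[match(shared, c_$subject_id)],
    stringsAsFactors = FALSE)
}
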