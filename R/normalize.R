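## Background correction, dye-bias correction, functional normalization
## and the technical-replicate concordance test.

## Channel membership of the meth/unmeth measurements of each probe.
## Type II probes read meth in green and unmeth in red; Type I probes use
## a single color for both.  Without annotation all probes are treated as
## Type II.
probe_channels <- function(ds, annotation = NULL) {
  np <- nrow(ds$meth)
  design <- if (is.null(annotation)) rep("II", np)
            else annotation$design_type[match(rownames(ds$meth),
                                              annotation$probe_id)]
  list(meth_green = design %in% c("I-green", "II"),
       unmeth_green = design == "I-green",
       design = design)
}

#' Normal-exponential background correction
#'
#' Removes non-specific background from the total signal by
#' normal-exponential deconvolution, per sample and channel: the normal
#' background component is estimated from that channel's negative
#' controls, the exponential signal mean from the observed intensities,
#' and each intensity is replaced by the posterior mean of the true
#' signal (always positive).  Control-probe intensities are corrected
#' with the same parameters.  A dataset already tagged as
#' background-corrected is returned unchanged, making the operation
#' idempotent.
#'
#' @param ds A `MethylationDataset`.
#' @param annotation Optional probe annotation (channel assignment);
#'   `NULL` treats all probes as Type II.
#' @return The corrected `MethylationDataset`.
#' @export
background_correct <- function(ds, annotation = NULL) {
  if ("background_corrected" %in% ds$processing) return(ds)
  ch <- probe_channels(ds, annotation)
  neg <- ds$controls[ds$controls$control_type == "negative", ]
  sids <- colnames(ds$meth)
  ctrl_vals <- as.matrix(ds$controls[, sids, drop = FALSE])
  ctrl_green <- ds$controls$channel == "green"
  meth <- ds$meth; unmeth <- ds$unmeth
  for (s in sids) {
    for (channel in c("green", "red")) {
      nc <- neg[neg$channel == channel, s]
      mu <- mean(nc); sigma <- sd(nc)
      in_ch_meth <- if (channel == "green") ch$meth_green else
        !ch$meth_green
      in_ch_unmeth <- if (channel == "green") ch$unmeth_green else
        !ch$unmeth_green
      in_ch_ctrl <- if (channel == "green") ctrl_green else !ctrl_green
      x <- c(meth[in_ch_meth, s], unmeth[in_ch_unmeth, s])
      if (!is.finite(sigma) || sigma <= 0) {
        ## degenerate background: simple subtraction floored at 1
        correct <- function(v) pmax(v - mu, 1)
      } else {
        alpha <- max(mean(x) - mu, 10)
        par <- c(mu, log(sigma), log(alpha))
        correct <- function(v) limma::normexp.signal(par, v)
      }
      meth[in_ch_meth, s] <- correct(meth[in_ch_meth, s])
      unmeth[in_ch_unmeth, s] <- correct(unmeth[in_ch_unmeth, s])
      ctrl_vals[in_ch_ctrl, s] <- correct(ctrl_vals[in_ch_ctrl, s])
    }
  }
  controls <- ds$controls
  controls[, sids] <- ctrl_vals
  methylation_dataset(meth, unmeth, ds$beads, controls, ds$samples,
                      processing = c(ds$processing,
                                     "background_corrected"))
}

#' Dye-bias correction
#'
#' Rescales each sample's green- and red-channel intensities so that the
#' channel means of the normalization control probes both equal their
#' grand mean.  After correction the per-sample red and green control
#' means agree exactly, and re-applying the correction is an identity.
#'
#' @inheritParams background_correct
#' @return The corrected `MethylationDataset`.
#' @export
dye_bias_correct <- function(ds, annotation = NULL) {
  ch <- probe_channels(ds, annotation)
  sids <- colnames(ds$meth)
  grn <- ds$controls[ds$controls$control_type == "norm_grn", sids,
                     drop = FALSE]
  red <- ds$controls[ds$controls$control_type == "norm_red", sids,
                     drop = FALSE]
  g <- colMeans(as.matrix(grn)); r <- colMeans(as.matrix(red))
  if (any(g <= 0) || any(r <= 0))
    stop("zero or negative normalization-control mean; cannot scale")
  target <- (g + r) / 2
  fg <- target / g; fr <- target / r
  meth <- ds$meth; unmeth <- ds$unmeth
  ctrl_vals <- as.matrix(ds$controls[, sids, drop = FALSE])
  ctrl_green <- ds$controls$channel == "green"
  for (i in seq_along(sids)) {
    s <- sids[i]
    meth[, s] <- meth[, s] * ifelse(ch$meth_green, fg[i], fr[i])
    unmeth[, s] <- unmeth[, s] * ifelse(ch$unmeth_green, fg[i], fr[i])
    ctrl_vals[, s] <- ctrl_vals[, s] * ifelse(ctrl_green, fg[i], fr[i])
  }
  controls <- ds$controls
  controls[, sids] <- ctrl_vals
  processing <- union(ds$processing, "dye_bias_corrected")
  methylation_dataset(meth, unmeth, ds$beads, controls, ds$samples,
                      processing = processing)
}

#' Control-probe summaries for functional normalization
#'
#' Mean log2 intensity per (control type x channel) feature, one row per
#' sample, standardized to mean 0 / SD 1 per feature (zero-variance
#' features are set to 0).
#'
#' @param ds A `MethylationDataset`.
#' @return Numeric matrix (sample x control feature).
#' @export
control_summaries <- function(ds) {
  sids <- colnames(ds$meth)
  key <- paste(ds$controls$control_type, ds$controls$channel, sep = ".")
  feats <- sort(unique(key))
  out <- sapply(feats, function(f) {
    v <- as.matrix(ds$controls[key == f, sids, drop = FALSE])
    colMeans(log2(v + 1))
  })
  out <- as.matrix(out)
  rownames(out) <- sids
  out <- scale(out)
  out[, attr(out, "scaled:scale") == 0 | is.na(attr(out, "scaled:scale"))] <- 0
  out[is.na(out)] <- 0
  out[, , drop = FALSE]
}

#' Functional normalization
#'
#' An extension of quantile normalization: within each probe stratum
#' (Type I-green, I-red, II; meth and unmeth separately) each sample's
#' empirical quantiles (log2 scale) are computed, the variation of each
#' quantile level across samples that is explained by the first `k`
#' principal components of the control-probe summaries is regressed out,
#' and each sample's intensities are mapped through monotone
#' interpolation between its raw and adjusted quantiles.  With `k = 0`
#' this reduces to plain within-stratum quantile normalization (all
#' samples share the mean quantile curve).  The stratified anchoring also
#' brings Type I and Type II probes onto comparable scales.
#'
#' @inheritParams background_correct
#' @param k Number of control principal components to regress out
#'   (default 2).
#' @param n_quantiles Number of quantile anchor points (default 500);
#'   endpoints are pinned at the minimum and maximum.
#' @param controls_ds Dataset whose control probes feed the control
#'   summaries (default `ds`).  Passing the raw, uncorrected dataset --
#'   as [normalize_dataset()] does -- keeps the control features clean:
#'   background correction shrinks negative controls toward zero, where
#'   their log-intensities carry noise rather than signal.
#' @return List with `dataset` (normalized intensities, provenance tag
#'   `"functional_normalized"`), `beta` and `m` matrices recomputed from
#'   the normalized intensities.
#' @export
functional_normalize <- function(ds, annotation = NULL, k = 2,
                                 n_quantiles = 500, controls_ds = ds) {
  n_samp <- ncol(ds$meth)
  if (k >= n_samp) stop("k must be smaller than the number of samples")
  if (n_samp < k + 2) stop("need at least k + 2 samples")
  ch <- probe_channels(ds, annotation)
  pr <- seq(0, 1, length.out = n_quantiles)
  Z <- NULL
  if (k > 0) {
    cs <- control_summaries(controls_ds)
    stopifnot(identical(rownames(cs), colnames(ds$meth)))
    pc <- prcomp(cs, center = TRUE, scale. = FALSE)
    k_eff <- min(k, ncol(pc$x))
    Z <- pc$x[, seq_len(k_eff), drop = FALSE]
  }
  normalize_stratum <- function(x) {
    ## x: intensities (probes-in-stratum x samples), returns same shape
    lx <- log2(x + 1)
    Q <- apply(lx, 2, quantile, probs = pr, type = 7, names = FALSE)
    if (is.null(Z) || all(Z == 0)) {
      target <- rowMeans(Q)
      Qadj <- matrix(target, nrow(Q), ncol(Q))
    } else {
      X <- cbind(1, Z)
      B <- solve(crossprod(X), crossprod(X, t(Q)))
      Qadj <- Q - t(Z %*% B[-1, , drop = FALSE])
    }
    Qadj <- apply(Qadj, 2, sort)      # keep mapping monotone
    out <- x
    for (s in seq_len(ncol(x))) {
      y <- approx(Q[, s], Qadj[, s], xout = lx[, s], rule = 2,
                  ties = mean)$y
      out[, s] <- pmax(2^y - 1, 0)
    }
    out
  }
  meth <- ds$meth; unmeth <- ds$unmeth
  for (d in c("I-green", "I-red", "II")) {
    idx <- ch$design == d
    if (!any(idx)) next
    meth[idx, ] <- normalize_stratum(ds$meth[idx, , drop = FALSE])
    unmeth[idx, ] <- normalize_stratum(ds$unmeth[idx, , drop = FALSE])
  }
  out_ds <- methylation_dataset(meth, unmeth, ds$beads, ds$controls,
                                ds$samples,
                                processing = c(ds$processing,
                                               "functional_normalized"))
  bm <- dataset_beta(out_ds)
  list(dataset = out_ds, beta = bm$beta, m = bm$m)
}

#' Run the full normalization chain
#'
#' Background correction, then dye-bias correction, then functional
#' normalization.
#'
#' @inheritParams functional_normalize
#' @return As [functional_normalize()].
#' @export
normalize_dataset <- function(ds, annotation = NULL, k = 2,
                              n_quantiles = 500) {
  raw <- ds
  ds <- background_correct(ds, annotation)
  ds <- dye_bias_correct(ds, annotation)
  functional_normalize(ds, annotation, k = k, n_quantiles = n_quantiles,
                       controls_ds = raw)
}

## expand replicate groups (list or sample sheet) into unordered pairs
replicate_pairs <- function(replicate_groups) {
  if (is.data.frame(replicate_groups)) {
    s <- replicate_groups
    grp <- s$replicate_group
    replicate_groups <- split(s$sample_id[!is.na(grp)], grp[!is.na(grp)])
  }
  pairs <- list()
  for (g in names(replicate_groups)) {
    ids <- replicate_groups[[g]]
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb)))
      pairs[[length(pairs) + 1]] <- c(group = g, a = cmb[1, j],
                                      b = cmb[2, j])
  }
  if (!length(pairs)) stop("need at least one replicate pair")
  as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
}

#' Replicate concordance test, before vs after normalization
#'
#' For every unordered pair of technical replicates, computes the squared
#' difference of the two samples' median M-values before and after
#' normalization, and tests whether normalization reduced these squared
#' differences with a one-sided paired t-test (alternative: after <
#' before).  Replicate groups larger than two contribute all pairwise
#' duplicates.
#'
#' @param m_before,m_after M-value matrices (probe x sample) sharing
#'   sample IDs.
#' @param replicate_groups Either a named list of sample-ID vectors or a
#'   sample sheet with a `replicate_group` column.
#' @return List with `t`, `p_value`, `n_pairs`, and a per-pair data frame
#'   (`d_before`, `d_after`).  When all before/after differences are zero
#'   the test is undefined and `p_value` is `NA` with a `reason`.
#' @export
replicate_concordance_test <- function(m_before, m_after,
                                       replicate_groups) {
  pairs <- replicate_pairs(replicate_groups)
  if (nrow(pairs) < 2) stop("need at least 2 replicate pairs")
  med_b <- apply(m_before, 2, median)
  med_a <- apply(m_after, 2, median)
  d_before <- (med_b[pairs$a] - med_b[pairs$b])^2
  d_after <- (med_a[pairs$a] - med_a[pairs$b])^2
  pairs$d_before <- as.numeric(d_before)
  pairs$d_after <- as.numeric(d_after)
  diffs <- pairs$d_before - pairs$d_after
  if (all(abs(diffs - diffs[1]) < .Machine$double.eps * 100)) {
    return(list(t = NA_real_, p_value = NA_real_, n_pairs = nrow(pairs),
                pairs = pairs,
                reason = "zero variance in paired differences"))
  }
  tt <- t.test(pairs$d_before, pairs$d_after, paired = TRUE,
               alternative = "greater")
  list(t = unname(tt$statistic), p_value = tt$p.value,
       n_pairs = nrow(pairs), pairs = pairs)
}
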