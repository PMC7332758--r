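## Surrogate variable analysis, CSF day subsets, the permuted-trait null
## EWAS and the genomic inflation factor.

#' Group CSF samples into target-day subsets
#'
#' For each subject and target day, picks the exact-day sample when
#' present, otherwise the day-minus-one sample, otherwise the
#' day-plus-one sample (minus-first preference); each subject contributes
#' at most one sample per target and no sample is assigned to two
#' targets.
#'
#' @param samples Sample sheet (CSF rows are selected internally).
#' @param targets Target days, default `c(1, 4, 7, 10, 13)`.
#' @return Named list mapping `"day<target>"` to a character vector of
#'   sample IDs.
#' @export
csf_day_subsets <- function(samples, targets = c(1, 4, 7, 10, 13)) {
  s <- samples[samples$tissue == "csf" & !samples$is_control_sample, ]
  used <- character(0)
  out <- list()
  for (tg in targets) {
    picks <- character(0)
    for (subj in unique(s$subject_id)) {
      d <- s[s$subject_id == subj & !(s$sample_id %in% used), ]
      for (day in c(tg, tg - 1, tg + 1)) {
        hit <- d$sample_id[d$collection_day == day]
        if (length(hit)) { picks <- c(picks, hit[1]); break }
      }
    }
    used <- c(used, picks)
    out[[paste0("day", tg)]] <- picks
  }
  out
}

#' Permute a binary trait
#'
#' Uniform random permutation of the trait vector (class counts
#' preserved), seeded for reproducibility -- the device used to build a
#' null EWAS from an observed DCI-like trait.
#'
#' @param trait Binary (0/1) vector with at least two members per class.
#' @param seed Integer seed.
#' @return Permuted vector of the same length.
#' @export
permute_trait <- function(trait, seed) {
  tab <- table(trait)
  if (length(tab) < 2 || any(tab < 2))
    stop("trait needs at least 2 members of each class")
  withr::with_seed(seed, sample(trait))
}

#' Estimate the number of surrogate variables
#'
#' Permutation parallel analysis (Buja-Eyuboglu): eigenvalues of the
#' residual matrix, after regressing out the covariate model, are
#' compared with their null distribution under row-wise permutation; the
#' count of eigenvalues exceeding the null is returned.
#'
#' @param m M-value matrix (probe x sample).
#' @param mod Model matrix of known covariates (including intercept and
#'   the phenotype of interest).
#' @param n_perm Number of permutations (default 20).
#' @param seed Integer seed.
#' @return Integer count of surrogate variables.
#' @export
estimate_num_sv <- function(m, mod, n_perm = 20, seed = 1) {
  stopifnot(ncol(m) == nrow(mod))
  withr::with_seed(seed,
    sva::num.sv(m, mod, method = "be", B = n_perm, seed = NULL))
}

#' Compute surrogate variables
#'
#' Iteratively re-weighted surrogate variable analysis conditional on the
#' primary model (phenotype + covariates), so the surrogate variables do
#' not absorb phenotype-driven variation.  Columns of the returned
#' matrix are orthonormalized.
#'
#' @param m M-value matrix (probe x sample).
#' @param mod Full primary model matrix (intercept, trait, covariates).
#' @param mod0 Null model matrix (intercept, covariates; no trait).
#' @param n_sv Number of surrogate variables (>= 1).
#' @param n_iter IRW iterations (default 5).
#' @return List with `sv` (sample x n_sv orthonormal matrix), `n_sv`,
#'   `n_iter`.
#' @export
compute_surrogate_variables <- function(m, mod, mod0, n_sv,
                                        n_iter = 5) {
  if (n_sv < 1) stop("n_sv must be >= 1")
  if (n_sv >= ncol(m) - qr(mod)$rank)
    stop("n_sv must be below n_samples - rank(model)")
  fit <- suppressMessages(utils::capture.output(
    res <- sva::sva(m, mod, mod0, n.sv = n_sv, B = n_iter)))
  sv <- as.matrix(res$sv)
  sv <- qr.Q(qr(sv))[, seq_len(ncol(sv)), drop = FALSE]
  rownames(sv) <- colnames(m)
  colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  list(sv = sv, n_sv = ncol(sv), n_iter = n_iter)
}

#' Per-CpG association scan (EWAS)
#'
#' Ordinary least-squares fit of each probe's M-values on the trait plus
#' covariates (and optional surrogate variables); reports the two-sided
#' t-test p-value and effect estimate of the trait coefficient, and
#' attaches the genomic inflation factor of the scan.
#'
#' @param m M-value matrix (probe x sample).
#' @param trait Numeric (0/1) trait vector, one entry per sample.
#' @param covariates Data frame or matrix of covariates (e.g. age, sex);
#'   factors/characters are expanded via [stats::model.matrix()].
#' @param svs Optional surrogate-variable matrix (sample x n_sv).
#' @return An `EwasResult` list: `table` (per-probe `estimate`, `t`,
#'   `p_value`), `lambda`, `model` descriptor.
#' @export
run_ewas <- function(m, trait, covariates = NULL, svs = NULL) {
  n <- ncol(m)
  stopifnot(length(trait) == n)
  X <- cbind(`(Intercept)` = 1, trait = trait)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    varying <- vapply(cv, function(x)
      length(unique(x[!is.na(x)])) > 1, logical(1))
    cv <- cv[, varying, drop = FALSE]
    if (ncol(cv)) {
      mm <- model.matrix(~ ., data = cv)[, -1, drop = FALSE]
      X <- cbind(X, mm)
    }
  }
  if (!is.null(svs)) X <- cbind(X, as.matrix(svs))
  keep <- complete.cases(X) & !is.na(trait)
  X <- X[keep, , drop = FALSE]
  m <- m[, keep, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  B <- m %*% X %*% XtXi                  # probe x p coefficients
  colnames(B) <- colnames(X)
  fitted <- B %*% t(X)
  rss <- rowSums((m - fitted)^2)
  sigma2 <- rss / (n - p)
  se_trait <- sqrt(sigma2 * XtXi["trait", "trait"])
  est <- B[, "trait"]
  tstat <- est / se_trait
  pval <- 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
  probe_ids <- if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
               else rownames(m)
  tab <- data.frame(probe_id = probe_ids, estimate = est, t = tstat,
                    p_value = pval, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, lambda = genomic_inflation(pval),
       model = list(covariates = colnames(X), n_samples = n,
                    n_sv = if (is.null(svs)) 0 else ncol(svs)))
}

#' Genomic inflation factor
#'
#' lambda = median of the observed chi-square (1 df) association
#' statistics divided by the null median (0.4549364).  Values near 1
#' indicate a calibrated scan; lambda > 1 inflation, lambda < 1
#' deflation.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}
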