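## Reference-based cell-type deconvolution and composition outliers.

#' Estimate cell-type proportions by constrained projection
#'
#' Reference-based deconvolution: on the most cell-type-discriminating
#' probes of the reference methylome, each sample's beta profile is
#' projected onto the reference profiles by solving the quadratic
#' program min ||y - X w||^2 subject to w >= 0 and sum(w) = 1, so the
#' estimated proportions always lie on the simplex.
#'
#' @param beta_samples Beta matrix (probe x sample).
#' @param reference Reference beta matrix (probe x cell type), e.g. from
#'   [simulate_reference_methylome()].
#' @param n_discriminating Number of discriminating probes to use,
#'   selected by largest between-cell-type variance in the reference
#'   (default 100).
#' @return List with `proportions` (sample x cell type, rows on the
#'   simplex), `residual_norm` per sample, and `selected_probes`.
#' @export
estimate_cell_proportions <- function(beta_samples, reference,
                                      n_discriminating = 100) {
  shared <- intersect(rownames(beta_samples), rownames(reference))
  if (length(shared) < 2)
    stop("samples and reference share too few probes")
  ref <- reference[shared, , drop = FALSE]
  disc_score <- apply(ref, 1, var)
  n_use <- min(n_discriminating, length(shared))
  sel <- names(sort(disc_score, decreasing = TRUE))[seq_len(n_use)]
  X <- ref[sel, , drop = FALSE]
  XtX <- crossprod(X)
  cn <- kappa(XtX, exact = TRUE)
  if (!is.finite(cn) || cn > 1e10)
    stop("reference cell-type profiles are collinear on the selected ",
         "probes (condition number ", format(cn, digits = 3),
         "); deconvolution is not identifiable")
  k <- ncol(X)
  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  Y <- beta_samples[sel, , drop = FALSE]
  W <- matrix(NA_real_, ncol(Y), k,
              dimnames = list(colnames(Y), colnames(X)))
  res_norm <- setNames(numeric(ncol(Y)), colnames(Y))
  for (s in seq_len(ncol(Y))) {
    sol <- quadprog::solve.QP(Dmat = XtX, dvec = crossprod(X, Y[, s]),
                              Amat = Amat, bvec = bvec, meq = 1)
    w <- sol$solution
    w[w < 0] <- 0            # clip QP round-off
    w <- w / sum(w)
    W[s, ] <- w
    res_norm[s] <- sqrt(sum((Y[, s] - X %*% w)^2))
  }
  list(proportions = W, residual_norm = res_norm,
       selected_probes = sel)
}

#' Flag cell-composition outlier samples
#'
#' Flags samples whose estimated fraction of one cell type exceeds the
#' across-sample median by more than `z_thresh` scaled MADs -- the
#' pattern by which a leukemic B-cell excess reveals itself in blood
#' deconvolution.  When the MAD is zero, samples differing from the
#' median by more than 0.1 in absolute fraction are flagged.
#'
#' @param proportions Sample x cell-type fraction matrix (e.g. from
#'   [estimate_cell_proportions()]).
#' @param cell_type Column to screen (e.g. `"B_cell"`).
#' @param z_thresh Fence in scaled-MAD units, default 4.
#' @return Named logical vector per sample.
#' @export
flag_composition_outliers <- function(proportions, cell_type,
                                      z_thresh = 4) {
  if (nrow(proportions) < 10)
    stop("need at least 10 samples for composition outlier detection")
  if (!cell_type %in% colnames(proportions))
    stop("unknown cell type: ", cell_type)
  x <- proportions[, cell_type]
  med <- median(x)
  m <- mad(x)                 # includes the 1.4826 consistency factor
  out <- if (m == 0) abs(x - med) > 0.1 else x > med + z_thresh * m
  names(out) <- rownames(proportions)
  out
}
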