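## Reference methylomes for cell-type deconvolution and for building
## mixture samples in the generator.

BLOOD_CELL_TYPES <- c("CD4T", "CD8T", "NK", "monocyte", "B_cell",
                      "granulocyte")
## No CSF reference methylome exists in the literature; these four
## compartments are a modeling choice for the generator only (documented
## in the methods vignette).
CSF_CELL_TYPES <- c("lymphocyte", "monocyte", "neutrophil",
                    "erythro_remnant")

#' Simulate a reference methylome
#'
#' Builds a probe x cell-type beta matrix in which a chosen number of
#' "discriminating" probes are nearly unmethylated in a random subset of
#' cell types and nearly fully methylated in the rest, while the remaining
#' probes share one profile across all cell types.  Such probes are what
#' reference-based deconvolution keys on.
#'
#' @param n_probes Number of probes.
#' @param cell_types Character vector of cell-type names (default: the six
#'   blood leukocyte types used for blood deconvolution).
#' @param n_discriminating Number of cell-type discriminating probes.
#' @param seed Optional integer seed (the matrix is reproducible given it).
#' @param base_beta Optional length-`n_probes` vector of shared baseline
#'   betas; drawn from a bimodal methylome-like mixture when `NULL`.
#'   Passing the same baseline to two tissue references gives the tissues
#'   a shared methylation architecture.
#' @param probe_ids Optional probe identifiers (rownames).
#' @return Beta matrix (probe x cell type) with attribute
#'   `"discriminating"` holding the indices of discriminating probes.
#' @export
simulate_reference_methylome <- function(n_probes,
                                         cell_types = BLOOD_CELL_TYPES,
                                         n_discriminating = 100,
                                         seed = NULL,
                                         base_beta = NULL,
                                         probe_ids = NULL) {
  if (n_discriminating > n_probes)
    stop("n_discriminating must not exceed n_probes")
  run <- function() {
    k <- length(cell_types)
    if (is.null(base_beta)) base_beta <- draw_methylome_baseline(n_probes)
    ref <- matrix(rep(base_beta, k), nrow = n_probes, ncol = k)
    disc <- if (n_discriminating > 0)
      sort(sample.int(n_probes, n_discriminating)) else integer()
    for (j in disc) {
      n_low <- sample(seq_len(k - 1), 1)
      low <- sample.int(k, n_low)
      ref[j, low] <- runif(n_low, 0.03, 0.12)
      ref[j, -low] <- runif(k - n_low, 0.88, 0.97)
    }
    dimnames(ref) <- list(
      if (is.null(probe_ids)) sprintf("cg%05d", seq_len(n_probes))
      else probe_ids,
      cell_types)
    attr(ref, "discriminating") <- disc
    ref
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Bimodal methylome-like baseline: mostly hypo- or hyper-methylated
## probes with an intermediate minority, mirroring genome-wide 450K
## beta distributions.
draw_methylome_baseline <- function(n) {
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.35, 0.40, 0.25))
  b <- numeric(n)
  b[comp == 1] <- rbeta(sum(comp == 1), 2, 10)   # hypomethylated
  b[comp == 2] <- rbeta(sum(comp == 2), 10, 2)   # hypermethylated
  b[comp == 3] <- rbeta(sum(comp == 3), 6, 6)    # intermediate
  pmin(pmax(b, 0.01), 0.99)
}

#' Dirichlet draws
#'
#' Samples cell-fraction vectors via normalized gammas; rows sum to one
#' exactly.
#'
#' @param n Number of draws (rows).
#' @param alpha Concentration parameters, optionally named by cell type.
#' @return Matrix (n x length(alpha)) of fractions.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n,
              ncol = k)
  w <- g / rowSums(g)
  colnames(w) <- names(alpha)
  w
}
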