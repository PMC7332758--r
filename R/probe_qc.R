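## Probe-level quality control: sequential filters, multimodal-probe
## detection, and the paired blood-vs-CSF filter-outcome test.

#' Sequential filter bookkeeping
#'
#' Given an initial probe count and the number filtered at each step,
#' returns the running retained counts (the identity used in the
#' sequential-filtering table: retained_after = retained_before -
#' filtered_at_step).
#'
#' @param n_input Initial number of probes.
#' @param filtered Named or unnamed vector of per-step filtered counts.
#' @return Integer vector of retained counts after each step.
#' @export
sequential_filter_bookkeeping <- function(n_input, filtered) {
  retained <- n_input - cumsum(filtered)
  if (any(retained < 0)) stop("filtered counts exceed available probes")
  retained
}

#' Detect probes with multimodal beta distributions
#'
#' Kernel-density estimate of each probe's beta values on `[0, 1]`; a
#' probe is flagged when the density has at least two local maxima whose
#' modes each hold at least `min_mode_frac` of the samples and whose
#' peaks are separated by at least `min_separation`.
#'
#' @param beta Beta matrix (probe x sample).
#' @param min_mode_frac Minimum fraction of samples per mode
#'   (default 0.05).
#' @param min_separation Minimum distance between mode peaks
#'   (default 0.2).
#' @param bandwidth KDE bandwidth on the beta scale (default 0.05).
#' @param min_prominence Minimum ratio of each peak's density to the
#'   valley between the peaks (default 2): distinguishes genuinely
#'   separated modes from undulations of one broad distribution.
#' @return Named logical vector, one flag per probe.
#' @export
detect_multimodal_probes <- function(beta, min_mode_frac = 0.05,
                                     min_separation = 0.2,
                                     bandwidth = 0.05,
                                     min_prominence = 2) {
  n <- ncol(beta)
  if (n < 20)
    warning("fewer than 20 samples; multimodal detection is unreliable")
  flags <- vapply(seq_len(nrow(beta)), function(j) {
    x <- beta[j, ]
    d <- density(x, bw = bandwidth, from = 0, to = 1, n = 256)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1
    if (length(peaks) < 2) return(FALSE)
    ## valleys between peaks partition samples into candidate modes
    ord <- peaks[order(d$x[peaks])]
    valley_idx <- vapply(seq_len(length(ord) - 1), function(i) {
      seg <- seq(ord[i], ord[i + 1])
      seg[which.min(y[seg])]
    }, integer(1))
    bounds <- c(0, d$x[valley_idx], 1)
    frac <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(x >= bounds[i] & x <= bounds[i + 1]), numeric(1))
    big <- which(frac >= min_mode_frac)
    if (length(big) < 2) return(FALSE)
    px <- d$x[ord][big]
    if (max(px) - min(px) < min_separation) return(FALSE)
    ## both extreme qualifying peaks must dominate the valley floor
    ## between them
    lo <- min(ord[big]); hi <- max(ord[big])
    vfloor <- min(y[lo:hi])
    py <- y[ord][big]
    min(py[c(which.min(px), which.max(px))]) >=
      min_prominence * max(vfloor, 1e-12)
  }, logical(1))
  names(flags) <- rownames(beta)
  flags
}

#' Sequential probe-level filters
#'
#' Removes probes in the fixed order: (1) SNP-overlapping, (2)
#' cross-reactive, (3) sex-chromosome, (4) multimodal beta distribution,
#' (5) inadequately detected (detection p > `p_thresh` or beads <
#' `bead_thresh`) in more than `sample_frac` of samples.  Counts are
#' bookkept sequentially (a probe is charged to the first step that
#' removes it).
#'
#' @param beta Beta matrix (probe x sample), post-normalization.
#' @param detp Detection p-value matrix (same shape).
#' @param beads Bead-count matrix (same shape).
#' @param annotation Probe annotation covering all probes.
#' @param p_thresh,bead_thresh,sample_frac Detection thresholds
#'   (defaults 0.01, 3, 0.01).
#' @param multimodal_args List of arguments for
#'   [detect_multimodal_probes()].
#' @return A `ProbeFilterReport`: list with `steps` (per-step filtered /
#'   retained data frame), `pass` (named logical per probe),
#'   `first_failing_step` (per probe; `NA` when passing), and
#'   `retained_probes`.
#' @export
filter_probes <- function(beta, detp, beads, annotation,
                          p_thresh = 0.01, bead_thresh = 3,
                          sample_frac = 0.01,
                          multimodal_args = list()) {
  probes <- rownames(beta)
  missing <- setdiff(probes, annotation$probe_id)
  if (length(missing))
    stop("annotation missing probes: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  ann <- annotation[match(probes, annotation$probe_id), ]
  mm <- do.call(detect_multimodal_probes,
                c(list(beta = beta), multimodal_args))
  poor <- detp > p_thresh | beads < bead_thresh
  low_det <- rowMeans(poor) > sample_frac
  criteria <- list(
    snp_overlap = ann$snp_overlap,
    cross_reactive = ann$cross_reactive,
    sex_chromosome = ann$chromosome %in% c("X", "Y"),
    multimodal = as.logical(mm),
    low_detection = as.logical(low_det))
  alive <- rep(TRUE, length(probes))
  first_fail <- rep(NA_character_, length(probes))
  steps <- data.frame(step = names(criteria), filtered = NA_integer_,
                      retained = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(criteria)) {
    hit <- alive & criteria[[i]]
    first_fail[hit] <- names(criteria)[i]
    alive <- alive & !criteria[[i]]
    steps$filtered[i] <- sum(hit)
    steps$retained[i] <- sum(alive)
  }
  stopifnot(identical(
    steps$retained,
    as.integer(sequential_filter_bookkeeping(length(probes),
                                             steps$filtered))))
  names(alive) <- names(first_fail) <- probes
  list(steps = steps, pass = alive, first_failing_step = first_fail,
       retained_probes = probes[alive],
       n_input = length(probes),
       thresholds = list(p_thresh = p_thresh, bead_thresh = bead_thresh,
                         sample_frac = sample_frac,
                         multimodal_args = multimodal_args))
}

#' McNemar's test on paired probe filter outcomes
#'
#' Tests whether the per-probe pass/fail outcome differs between two
#' tissues over the same probe universe, using the discordant counts
#' b (pass in A, fail in B) and c (fail in A, pass in B) with continuity
#' correction: chi^2 = (|b - c| - 1)^2 / (b + c) on 1 df.
#'
#' @param pass_a,pass_b Logical vectors of per-probe pass flags, same
#'   probes in the same order.
#' @return List with `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_filter_test <- function(pass_a, pass_b) {
  if (length(pass_a) != length(pass_b))
    stop("pass vectors must cover the same probe universe")
  b <- sum(pass_a & !pass_b)
  cc <- sum(!pass_a & pass_b)
  if (b + cc == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = cc))
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(statistic = stat, p_value = pchisq(stat, df = 1,
                                          lower.tail = FALSE),
       b = b, c = cc)
}
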