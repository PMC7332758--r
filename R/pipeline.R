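## End-to-end orchestration: sample QC -> normalization -> probe QC ->
## blood deconvolution -> SVA / null EWAS -> cross-tissue correlation.

#' Default pipeline configuration
#'
#' All stage parameters with defaults; [run_pipeline()] merges a partial
#' list over these and rejects unknown keys.  The effective config is
#' echoed into the report for provenance.
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    sim = list(),            # overrides for default_sim_config()
    stages = list(normalize = TRUE, sva = TRUE, correlation = TRUE),
    qc = list(p_thresh = 0.01, bead_thresh = 3, frac_thresh = 0.01,
              sd_mult = 3, mad_mult = 3, ks_thresh = 0.15),
    normalize = list(k = 2, n_quantiles = 500),
    probe_qc = list(p_thresh = 0.01, bead_thresh = 3,
                    sample_frac = 0.01),
    cellcomp = list(n_discriminating = 100, z_thresh = 4,
                    outlier_cell_type = "B_cell"),
    sva = list(n_perm = 20, n_iter = 5, max_sv = 10),
    correlation = list(lo = 0.10, hi = 0.90,
                       targets = c(1, 4, 7, 10, 13)))
}

#' Run the full pipeline on a simulated study
#'
#' Executes, in order: synthetic-data generation, per-tissue sample QC
#' (with the Fisher tissue-quality comparison), background / dye-bias /
#' functional normalization with the replicate-concordance test,
#' sequential probe filters (with the McNemar cross-tissue comparison),
#' blood cell-type deconvolution with composition-outlier exclusion,
#' per-subset surrogate-variable estimation plus permuted-trait null
#' EWAS (unadjusted and SV-adjusted genomic inflation factors), and the
#' blood-CSF correlation analysis per CSF target day with region and
#' orientation stratification.  A single seed fans out to per-stage
#' sub-seeds so stages are individually reproducible.
#'
#' @param config Partial pipeline configuration; see
#'   [default_pipeline_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory: when given, the consolidated
#'   report is written as `report.json` plus per-CpG / per-subject TSVs.
#' @return The consolidated report (named list).
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(config))
    cfg[[nm]] <- modifyList(cfg[[nm]], config[[nm]])
  sub_seed <- withr::with_seed(seed,
    setNames(sample.int(.Machine$integer.max - 1, 4),
             c("sim", "sva", "permute", "misc")))

  sim <- simulate_dataset(cfg$sim, seed = sub_seed[["sim"]])
  ds <- sim$dataset; ann <- sim$annotation
  sheet <- ds$samples
  report <- list(config = cfg, seed = seed, sub_seeds = as.list(sub_seed))

  ## ---- sample QC per tissue (fixed-methylation controls excluded) ----
  qc_reports <- list(); pass_ids <- list()
  for (tissue in c("blood", "csf")) {
    ids <- sheet$sample_id[sheet$tissue == tissue &
                             !sheet$is_control_sample]
    sub <- subset_samples(ds, ids)
    qc <- do.call(sample_qc_report,
                  c(list(ds = sub, annotation = ann), cfg$qc))
    qc_reports[[tissue]] <- qc
    pass_ids[[tissue]] <- qc$sample_id[!qc$fail]
  }
  fisher <- tissue_failure_test(
    sum(qc_reports$csf$fail), nrow(qc_reports$csf),
    sum(qc_reports$blood$fail), nrow(qc_reports$blood))
  report$sample_qc <- list(
    blood = qc_reports$blood, csf = qc_reports$csf,
    n_fail = c(blood = sum(qc_reports$blood$fail),
               csf = sum(qc_reports$csf$fail)),
    pct_fail = c(
      blood = 100 * sum(qc_reports$blood$fail) / nrow(qc_reports$blood),
      csf = 100 * sum(qc_reports$csf$fail) / nrow(qc_reports$csf)),
    fisher = fisher)

  ## ---- normalization per tissue --------------------------------------
  norm <- list(); m_after <- list(); detp_pass <- list()
  for (tissue in c("blood", "csf")) {
    sub <- subset_samples(ds, pass_ids[[tissue]])
    raw <- dataset_beta(sub)
    if (cfg$stages$normalize) {
      fn <- normalize_dataset(sub, ann, k = cfg$normalize$k,
                              n_quantiles = cfg$normalize$n_quantiles)
      conc <- tryCatch(
        replicate_concordance_test(raw$m, fn$m, fn$dataset$samples),
        error = function(e) list(p_value = NA_real_,
                                 reason = conditionMessage(e)))
      norm[[tissue]] <- list(concordance = conc)
      m_after[[tissue]] <- list(beta = fn$beta, m = fn$m,
                                ds = fn$dataset)
    } else {
      norm[[tissue]] <- list(concordance = NULL, provenance = "raw")
      m_after[[tissue]] <- list(beta = raw$beta, m = raw$m, ds = sub)
    }
    detp_pass[[tissue]] <- detection_pvalues(sub, ann)
  }
  report$normalization <- lapply(names(norm), function(tissue) {
    x <- norm[[tissue]]
    proc <- m_after[[tissue]]$ds$processing
    list(p_value = x$concordance$p_value,
         n_pairs = x$concordance$n_pairs,
         mean_d_before = mean(x$concordance$pairs$d_before),
         mean_d_after = mean(x$concordance$pairs$d_after),
         provenance = if (length(proc)) paste(proc, collapse = "+")
                      else "raw")
  })
  names(report$normalization) <- names(norm)

  ## ---- probe QC per tissue --------------------------------------------
  probe_reports <- list()
  for (tissue in c("blood", "csf")) {
    probe_reports[[tissue]] <- do.call(filter_probes, c(
      list(beta = m_after[[tissue]]$beta,
           detp = detp_pass[[tissue]],
           beads = m_after[[tissue]]$ds$beads,
           annotation = ann),
      cfg$probe_qc))
  }
  mcn <- mcnemar_filter_test(probe_reports$blood$pass,
                             probe_reports$csf$pass)
  report$probe_qc <- list(
    blood = probe_reports$blood$steps, csf = probe_reports$csf$steps,
    mcnemar = mcn)

  ## ---- blood cell deconvolution ---------------------------------------
  blood_beta <- m_after$blood$beta
  cc <- estimate_cell_proportions(
    blood_beta, sim$truth$references$blood,
    n_discriminating = cfg$cellcomp$n_discriminating)
  comp_out <- flag_composition_outliers(
    cc$proportions, cfg$cellcomp$outlier_cell_type,
    z_thresh = cfg$cellcomp$z_thresh)
  report$cellcomp <- list(proportions = cc$proportions,
                          outliers = names(comp_out)[comp_out])
  drop_subjects <- unique(sheet$subject_id[
    sheet$sample_id %in% names(comp_out)[comp_out]])

  ## ---- analysis sets: study samples only, replicates/outliers dropped
  keep_study <- function(tissue) {
    ids <- colnames(m_after[[tissue]]$m)
    s <- sheet[match(ids, sheet$sample_id), ]
    ids[!grepl("_rep", ids) & !(s$subject_id %in% drop_subjects)]
  }
  blood_ids <- keep_study("blood")
  csf_ids <- keep_study("csf")
  subsets <- c(list(blood = blood_ids),
               csf_day_subsets(sheet[sheet$sample_id %in% csf_ids, ],
                               targets = cfg$correlation$targets))

  ## ---- SVA + permuted-trait null EWAS per subset ----------------------
  sva_res <- list(); sv_of <- list()
  if (cfg$stages$sva) {
    for (nm in names(subsets)) {
      ids <- subsets[[nm]]
      tissue <- if (nm == "blood") "blood" else "csf"
      m <- m_after[[tissue]]$m[
        probe_reports[[tissue]]$retained_probes, ids, drop = FALSE]
      s <- sheet[match(ids, sheet$sample_id), ]
      trait <- permute_trait(s$trait, seed = sub_seed[["permute"]])
      covars <- data.frame(age = s$age, sex = s$sex)
      varying <- vapply(covars, function(x)
        length(unique(x[!is.na(x)])) > 1, logical(1))
      mod <- cbind(1, trait)
      if (any(varying))
        mod <- cbind(mod, model.matrix(
          ~ ., data = covars[, varying, drop = FALSE])[, -1])
      mod0 <- mod[, -2, drop = FALSE]
      n_sv <- min(estimate_num_sv(m, mod, n_perm = cfg$sva$n_perm,
                                  seed = sub_seed[["sva"]]),
                  cfg$sva$max_sv, ncol(m) - ncol(mod) - 2)
      svs <- if (n_sv >= 1)
        compute_surrogate_variables(m, mod, mod0, n_sv,
                                    n_iter = cfg$sva$n_iter)$sv
        else NULL
      ew0 <- run_ewas(m, trait, covars, svs = NULL)
      ew1 <- if (is.null(svs)) ew0 else run_ewas(m, trait, covars, svs)
      sva_res[[nm]] <- list(n_samples = length(ids), n_sv = n_sv,
                            lambda_unadjusted = ew0$lambda,
                            lambda_adjusted = ew1$lambda)
      sv_of[[nm]] <- svs
    }
  }
  report$sva <- sva_res

  ## ---- blood-CSF correlation per CSF day ------------------------------
  corr_res <- list()
  if (cfg$stages$correlation) {
    shared_probes <- intersect(probe_reports$blood$retained_probes,
                               probe_reports$csf$retained_probes)
    for (nm in setdiff(names(subsets), "blood")) {
      pairs <- pair_subjects(sheet, blood_ids, subsets[[nm]])
      if (nrow(pairs) < 3) next
      bb <- m_after$blood$beta[shared_probes, pairs$blood, drop = FALSE]
      cb <- m_after$csf$beta[shared_probes, pairs$csf, drop = FALSE]
      retained <- extreme_beta_filter(bb, cb, lo = cfg$correlation$lo,
                                      hi = cfg$correlation$hi)
      adj_b <- adjust_subset(m_after$blood$m, sheet, pairs$blood,
                             retained, sv_of[["blood"]])
      adj_c <- adjust_subset(m_after$csf$m, sheet, pairs$csf,
                             retained, sv_of[[nm]])
      r_cpg <- within_cpg_correlation(adj_b, adj_c, pairs)
      r_ind <- within_individual_correlation(adj_b, adj_c, pairs)
      strat <- lapply(c(region = "region", orientation = "orientation"),
                      function(f) tryCatch(
                        stratified_comparison(r_cpg, ann, f),
                        error = function(e) NULL))
      corr_res[[nm]] <- list(
        n_subjects = nrow(pairs), n_cpgs = length(retained),
        mean_r = mean(r_cpg, na.rm = TRUE),
        median_r = median(r_cpg, na.rm = TRUE),
        mean_within_individual_r = mean(r_ind),
        r_cpg = r_cpg, r_individual = r_ind,
        strata = strat)
    }
  }
  report$correlation <- corr_res
  report$truth <- sim$truth
  report$annotation <- ann

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

## residualize a tissue-day subset on age, sex and its own SVs
adjust_subset <- function(m, sheet, ids, probes, svs) {
  s <- sheet[match(ids, sheet$sample_id), ]
  sv_sub <- if (!is.null(svs)) {
    hit <- intersect(ids, rownames(svs))
    if (length(hit) == length(ids)) svs[ids, , drop = FALSE] else NULL
  } else NULL
  adjust_mvalues(m[probes, ids, drop = FALSE], s$age, s$sex, sv_sub)
}

#' Write a pipeline report bundle
#'
#' Persists the consolidated report as `report.json` (scalar summaries;
#' matrices and per-probe vectors are written as TSVs alongside).
#'
#' @param report Report list from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  slim <- report
  slim$truth <- NULL
  slim$annotation <- NULL
  slim$cellcomp$proportions <- NULL
  for (nm in names(slim$correlation)) {
    rc <- slim$correlation[[nm]]
    per_cpg <- data.frame(probe_id = names(rc$r_cpg), r = rc$r_cpg)
    per_cpg <- merge(per_cpg,
                     report$annotation[, c("probe_id", "region",
                                           "orientation")],
                     by = "probe_id", sort = TRUE)
    write.table(per_cpg,
                file.path(out_dir, paste0("corr_cpg_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(subject = names(rc$r_individual),
                           r = rc$r_individual),
                file.path(out_dir, paste0("corr_subject_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    slim$correlation[[nm]]$r_cpg <- NULL
    slim$correlation[[nm]]$r_individual <- NULL
  }
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}
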