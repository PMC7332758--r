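## Shared fixtures, built in code at test time.

## Deterministic 10-probe x 4-sample dataset for container/IO tests.
make_tiny_dataset <- function() {
  probe_ids <- sprintf("cg%05d", 1:10)
  sids <- paste0("S", 1:4)
  base <- outer(seq(2000, 20000, length.out = 10), c(1, 1.1, 0.9, 1.05))
  meth <- round(base * 0.6, 3)
  unmeth <- round(base * 0.4, 3)
  dimnames(meth) <- dimnames(unmeth) <- list(probe_ids, sids)
  beads <- matrix(10L, 10, 4, dimnames = dimnames(meth))
  mk <- function(type, channel, n, lvl) {
    v <- matrix(lvl + seq_len(n * 4), n, 4)
    cbind(data.frame(control_type = type, channel = channel,
                     probe_id = paste0(type, "_", channel, "_",
                                       seq_len(n)),
                     stringsAsFactors = FALSE),
          as.data.frame(setNames(as.data.frame(v), sids)))
  }
  controls <- rbind(mk("negative", "green", 4, 100),
                    mk("negative", "red", 4, 110),
                    mk("bisulfite", "green", 3, 4000),
                    mk("norm_grn", "green", 3, 5000),
                    mk("norm_red", "red", 3, 5200))
  sheet <- data.frame(
    sample_id = sids, subject_id = paste0("P", 1:4), tissue = "blood",
    collection_day = 0L, plate = "B1", chip = 1L, row = 1:4,
    column = 1L, replicate_group = NA_character_,
    trait = c(0, 1, 0, 1), age = c(50, 55, 60, 45),
    sex = c("F", "M", "F", "M"), is_control_sample = FALSE,
    control_level = NA_real_, stringsAsFactors = FALSE)
  methylation_dataset(meth, unmeth, beads, controls, sheet)
}

## Synthetic dataset under the default study conditions, generated once
## per test run and shared across files.
.sim_cache <- new.env(parent = emptyenv())
get_default_sim <- function(seed = 2026L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(seed = seed)
  .sim_cache[[key]]
}

## Generator configuration used for the null-EWAS calibration property:
## one tissue, latent-factor + cell-mixture + batch heterogeneity, no
## planted failures or probe defects.
null_ewas_config <- function() {
  list(n_probes = 4000L, n_subjects = 60L, csf_day_prob = 0,
       failures = c(low_bisulfite = 0L, high_detection_failure = 0L,
                    intensity_outlier = 0L, beta_outlier = 0L),
       n_multimodal_probes = 0L, n_poor_probes = 0L,
       plant_bcell_outlier = FALSE)
}

## One null-EWAS run: permuted trait, estimated SVs, unadjusted and
## adjusted scans plus the truth-predicted unadjusted lambda.
run_null_ewas_once <- function(seed) {
  sim <- simulate_dataset(null_ewas_config(), seed = seed)
  s <- sim$dataset$samples
  ids <- s$sample_id[!s$is_control_sample & !grepl("_rep", s$sample_id)]
  sb <- s[match(ids, s$sample_id), ]
  m <- dataset_beta(subset_samples(sim$dataset, ids))$m
  trait <- permute_trait(sb$trait, seed = seed * 101)
  covars <- data.frame(age = sb$age, sex = sb$sex)
  mod <- cbind(1, trait, model.matrix(~ age + sex, covars)[, -1])
  n_sv <- min(estimate_num_sv(m, mod, seed = seed), 10)
  svs <- compute_surrogate_variables(m, mod, mod[, -2], n_sv)$sv
  m_sys <- sim$truth$m_systematic[, ids]
  noise_var <- median(apply(m - m_sys, 1, var))
  list(lambda_unadj = run_ewas(m, trait, covars)$lambda,
       lambda_adj = run_ewas(m, trait, covars, svs)$lambda,
       lambda_pred = predict_null_lambda(m_sys, noise_var, mod),
       n_sv = n_sv)
}

## Per-tissue QC + normalization + replicate concordance on a default
## simulated study.
concordance_for_seed <- function(seed) {
  sim <- simulate_dataset(seed = seed)
  ds <- sim$dataset; ann <- sim$annotation; s <- ds$samples
  out <- list()
  for (tissue in c("blood", "csf")) {
    ids <- s$sample_id[s$tissue == tissue & !s$is_control_sample]
    qc <- sample_qc_report(subset_samples(ds, ids), ann)
    sub <- subset_samples(ds, qc$sample_id[!qc$fail])
    raw <- dataset_beta(sub)
    fn <- normalize_dataset(sub, ann)
    out[[tissue]] <- replicate_concordance_test(raw$m, fn$m,
                                                fn$dataset$samples)
  }
  out
}
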