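## Synthetic two-tissue methylation study generator.
##
## The generator emulates the statistical structure the pipeline assumes:
## paired blood/CSF subjects with longitudinal CSF sampling, cell-mixture
## betas from tissue-specific reference methylomes, region-dependent
## cross-tissue coupling of subject-level deviations on the M scale,
## latent rank-k heterogeneity factors for SVA to find, per-sample
## monotone intensity distortions keyed to plate/chip/row/column (visible
## in the control probes, so functional normalization can remove them),
## dye imbalance, fixed-methylation control samples, technical replicates
## and planted failing samples / multimodal probes / poorly detected
## probes.  Everything is returned together with a ground-truth record.

#' Default generator configuration
#'
#' Returns the full list of generator parameters with their default
#' values; [simulate_dataset()] accepts a partial list and merges it over
#' these defaults, rejecting unknown keys.  The defaults define the study
#' conditions the package's recovery tests run under: 2,000 probes and
#' roughly 120 study samples (24 subjects, all with one blood sample and
#' longitudinal CSF at target days 1/4/7/10/13 with imperfect
#' availability and occasional one-day substitutes).
#'
#' @return Named list of parameters.
#' @export
default_sim_config <- function() {
  list(
    n_probes = 2000L,
    n_subjects = 24L,
    blood_prob = 1.0,
    csf_target_days = c(1L, 4L, 7L, 10L, 13L),
    csf_day_prob = 0.85,
    csf_day_jitter_prob = 0.2,
    trait_prob = 0.5,
    age_mean = 53, age_sd = 11,
    female_prob = 0.67,
    blood_mean_fracs = c(CD4T = 0.15, CD8T = 0.10, NK = 0.05,
                         monocyte = 0.08, B_cell = 0.07,
                         granulocyte = 0.55),
    blood_concentration = 60,
    csf_mean_fracs = c(lymphocyte = 0.45, monocyte = 0.30,
                       neutrophil = 0.15, erythro_remnant = 0.10),
    csf_concentration = 40,
    n_discriminating = 200L,
    region_probs = c(island = 0.30, shore = 0.25, shelf = 0.15,
                     open_sea = 0.30),
    region_correlation = c(island = 0.45, shore = 0.35, shelf = 0.20,
                           open_sea = 0.10),
    orientation_probs = c("TSS" = 0.15, "5'UTR" = 0.10,
                          "first_exon" = 0.08, "body" = 0.35,
                          "3'UTR" = 0.07, "intergenic" = 0.25),
    design_type_probs = c("I-green" = 0.15, "I-red" = 0.15, "II" = 0.70),
    snp_frac = 0.025, cross_frac = 0.03,
    x_frac = 0.03, y_frac = 0.01,
    subject_sd = 0.5,
    n_latent_factors = 3L,
    latent_loading_sd = 0.4,
    batch_halfwidth = c(plate = 0.14, chip = 0.20, row = 0.10,
                        column = 0.05),
    dye_halfwidth = 0.17,
    noise_sd = 0.1,
    intensity_scale = 6000,
    intensity_probe_sd = 0.3,
    intensity_anchor = 3000,
    background_mean = 150, background_sd = 20,
    n_negative_controls = 30L,
    n_bisulfite_controls = 10L,
    bisulfite_level = 4000,
    n_norm_controls = 15L,
    norm_level = 5000,
    beads_mean = 10,
    failures = c(low_bisulfite = 1L, high_detection_failure = 1L,
                 intensity_outlier = 1L, beta_outlier = 1L),
    detection_failure_frac = 0.05,
    low_bisulfite_factor = 0.25,
    intensity_outlier_factor = 0.25,
    n_multimodal_probes = 20L,
    n_poor_probes = 15L,
    poor_probe_frac = 0.03,
    plant_bcell_outlier = TRUE,
    bcell_outlier_frac = 0.65)
}

#' Simulate a two-tissue methylation dataset with ground truth
#'
#' Generates a complete [methylation_dataset()] (intensities, bead counts,
#' control probes, plate-designed sample sheet), a probe annotation table
#' and a truth record for recovery testing.  See [default_sim_config()]
#' for the tunable parameters; with a fixed seed the result is
#' reproducible bit-for-bit.
#'
#' @param config Partial named list of parameters overriding
#'   [default_sim_config()]; unknown names are rejected.
#' @param seed Integer seed.
#' @return List with elements `dataset` (`MethylationDataset`),
#'   `annotation` (probe annotation data frame) and `truth` (list holding
#'   cell fractions, batch/dye effects, planted failures, multimodal and
#'   poorly detected probes, latent factor scores and loadings, the
#'   noiseless systematic M matrix, the reference methylomes, region
#'   correlation targets, and the effective config and seed).
#' @export
simulate_dataset <- function(config = list(), seed) {
  cfg <- default_sim_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, config)
  if (sum(cfg$failures) > cfg$n_subjects)
    stop("more planted failures than subjects")
  withr::with_seed(seed, build_simulation(cfg, seed))
}

build_simulation <- function(cfg, seed) {
  np <- cfg$n_probes
  probe_ids <- sprintf("cg%05d", seq_len(np))

  ## ---- annotation ------------------------------------------------------
  chrom <- as.character(sample(1:22, np, replace = TRUE))
  sex_probe <- runif(np)
  chrom[sex_probe < cfg$x_frac] <- "X"
  chrom[sex_probe >= cfg$x_frac &
          sex_probe < cfg$x_frac + cfg$y_frac] <- "Y"
  annotation <- data.frame(
    probe_id = probe_ids,
    design_type = sample(names(cfg$design_type_probs), np, replace = TRUE,
                         prob = cfg$design_type_probs),
    chromosome = chrom,
    region = sample(names(cfg$region_probs), np, replace = TRUE,
                    prob = cfg$region_probs),
    orientation = sample(names(cfg$orientation_probs), np, replace = TRUE,
                         prob = cfg$orientation_probs),
    snp_overlap = runif(np) < cfg$snp_frac,
    cross_reactive = runif(np) < cfg$cross_frac,
    stringsAsFactors = FALSE)
  ## reference methylomes (shared baseline architecture across tissues)
  base_beta <- draw_methylome_baseline(np)
  blood_ref <- simulate_reference_methylome(
    np, BLOOD_CELL_TYPES, cfg$n_discriminating, base_beta = base_beta,
    probe_ids = probe_ids)
  csf_ref <- simulate_reference_methylome(
    np, CSF_CELL_TYPES, cfg$n_discriminating, base_beta = base_beta,
    probe_ids = probe_ids)

  ## planted probe defects live outside the annotation flags and outside
  ## the cell-type-discriminating sets, so each defect is caught by
  ## exactly one mechanism
  disc <- union(attr(blood_ref, "discriminating"),
                attr(csf_ref, "discriminating"))
  clean_pool <- setdiff(
    which(!annotation$snp_overlap & !annotation$cross_reactive &
            !(annotation$chromosome %in% c("X", "Y"))), disc)
  mm_probes <- sort(sample(clean_pool, cfg$n_multimodal_probes))
  poor_probes <- sort(sample(setdiff(clean_pool, mm_probes),
                             cfg$n_poor_probes))

  ## ---- subjects and study samples -------------------------------------
  ns <- cfg$n_subjects
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(ns)),
    trait = rbinom(ns, 1, cfg$trait_prob),
    age = round(rnorm(ns, cfg$age_mean, cfg$age_sd), 1),
    sex = sample(c("F", "M"), ns, replace = TRUE,
                 prob = c(cfg$female_prob, 1 - cfg$female_prob)),
    stringsAsFactors = FALSE)
  has_blood <- runif(ns) < cfg$blood_prob
  blood_rows <- subjects[has_blood, ]
  blood_rows$tissue <- "blood"
  blood_rows$collection_day <- 0L
  csf_list <- list()
  for (i in seq_len(ns)) {
    present <- cfg$csf_target_days[runif(length(cfg$csf_target_days)) <
                                     cfg$csf_day_prob]
    if (!length(present)) next
    jit <- sample(c(-1L, 0L, 1L), length(present), replace = TRUE,
                  prob = c(cfg$csf_day_jitter_prob / 2,
                           1 - cfg$csf_day_jitter_prob,
                           cfg$csf_day_jitter_prob / 2))
    days <- unique(pmax(1L, present + jit))
    d <- subjects[rep(i, length(days)), ]
    d$tissue <- "csf"
    d$collection_day <- days
    csf_list[[length(csf_list) + 1]] <- d
  }
  csf_rows <- do.call(rbind, csf_list)

  sub_seeds <- sample.int(.Machine$integer.max - 1, 4)
  blood_sheet <- if (nrow(blood_rows))
    generate_plate_layout(blood_rows, seed = sub_seeds[1]) else NULL
  csf_sheet <- if (!is.null(csf_rows) && nrow(csf_rows))
    generate_plate_layout(csf_rows, seed = sub_seeds[2]) else NULL
  if (is.null(blood_sheet) && is.null(csf_sheet))
    stop("configuration yields no study samples")
  sheet <- rbind(blood_sheet, csf_sheet)
  rownames(sheet) <- NULL
  sid <- sheet$sample_id
  n_samp <- nrow(sheet)
  is_ctrl <- sheet$is_control_sample
  is_rep <- grepl("_rep", sid)
  is_study <- !is_ctrl & !is_rep

  ## biological source of each assay: replicates re-assay their source
  bio_of <- sid
  bio_of[is_rep] <- sub("_repP\\d+n\\d+$", "", sid[is_rep])

  ## ---- cell fractions --------------------------------------------------
  bio_ids <- unique(bio_of[!is_ctrl])
  bio_sheet <- sheet[match(bio_ids, sid), ]
  n_bio <- length(bio_ids)
  W_blood <- rdirichlet(sum(bio_sheet$tissue == "blood"),
                        cfg$blood_mean_fracs * cfg$blood_concentration)
  rownames(W_blood) <- bio_ids[bio_sheet$tissue == "blood"]
  W_csf <- rdirichlet(sum(bio_sheet$tissue == "csf"),
                      cfg$csf_mean_fracs * cfg$csf_concentration)
  rownames(W_csf) <- bio_ids[bio_sheet$tissue == "csf"]

  bcell_outlier <- NA_character_
  if (cfg$plant_bcell_outlier && nrow(W_blood) >= 2) {
    cand <- rownames(W_blood)[is.na(sheet$replicate_group[
      match(rownames(W_blood), sid)])]
    if (!length(cand)) cand <- rownames(W_blood)
    bcell_outlier <- sample(cand, 1)
    w <- W_blood[bcell_outlier, ]
    w <- w * (1 - cfg$bcell_outlier_frac) / (1 - w["B_cell"])
    w["B_cell"] <- cfg$bcell_outlier_frac
    W_blood[bcell_outlier, ] <- w / sum(w)
  }

  ## ---- true M per biological sample -----------------------------------
  rho <- cfg$region_correlation[annotation$region]
  subj_ids <- subjects$subject_id
  B_dev <- matrix(rnorm(np * ns, 0, cfg$subject_sd), np, ns,
                  dimnames = list(probe_ids, subj_ids))
  C_dev <- rho * B_dev +
    sqrt(1 - rho^2) * matrix(rnorm(np * ns, 0, cfg$subject_sd), np, ns)

  k <- cfg$n_latent_factors
  L <- matrix(rnorm(np * k, 0, cfg$latent_loading_sd), np, k,
              dimnames = list(probe_ids, paste0("F", seq_len(k))))
  Fs <- matrix(rnorm(n_bio * k), n_bio, k,
               dimnames = list(bio_ids, paste0("F", seq_len(k))))

  mix_beta <- matrix(NA_real_, np, n_bio,
                     dimnames = list(probe_ids, bio_ids))
  bl <- bio_sheet$tissue == "blood"
  mix_beta[, bl] <- blood_ref %*% t(W_blood[bio_ids[bl], , drop = FALSE])
  mix_beta[, !bl] <- csf_ref %*% t(W_csf[bio_ids[!bl], , drop = FALSE])

  ## multimodal probes: two beta modes split across samples, shared by
  ## both tissues of a subject
  mm_group <- matrix(rbinom(length(mm_probes) * ns, 1, 0.5),
                     length(mm_probes), ns,
                     dimnames = list(probe_ids[mm_probes], subj_ids))
  subj_of_bio <- bio_sheet$subject_id
  for (b in seq_len(n_bio)) {
    g <- mm_group[, subj_of_bio[b]]
    mix_beta[mm_probes, b] <- ifelse(g == 1, 0.85, 0.15) +
      rnorm(length(mm_probes), 0, 0.02)
  }
  mix_beta <- pmin(pmax(mix_beta, 0.01), 0.99)

  m_bio <- m_from_beta(mix_beta)
  dev <- ifelse(matrix(bl, np, n_bio, byrow = TRUE),
                B_dev[, subj_of_bio], C_dev[, subj_of_bio])
  m_bio <- m_bio + dev + L %*% t(Fs)

  ## ---- planted failures ------------------------------------------------
  failing <- data.frame(sample_id = character(), mode = character(),
                        stringsAsFactors = FALSE)
  csf_study_free <- sid[is_study & sheet$tissue == "csf" &
                          is.na(sheet$replicate_group)]
  if (!length(csf_study_free))
    csf_study_free <- sid[is_study & is.na(sheet$replicate_group)]
  for (mode in names(cfg$failures)) {
    n_f <- cfg$failures[[mode]]
    if (n_f == 0) next
    pick <- sample(setdiff(csf_study_free, failing$sample_id), n_f)
    failing <- rbind(failing, data.frame(sample_id = pick, mode = mode,
                                         stringsAsFactors = FALSE))
  }
  beta_out_ids <- failing$sample_id[failing$mode == "beta_outlier"]
  for (s in beta_out_ids)
    m_bio[, s] <- m_from_beta(runif(np, 0.3, 0.7))

  ## ---- expand to all assays (replicates share biology; controls fixed)
  beta_true <- matrix(NA_real_, np, n_samp,
                      dimnames = list(probe_ids, sid))
  beta_true[, !is_ctrl] <- beta_from_m(m_bio[, bio_of[!is_ctrl]])
  for (s in which(is_ctrl))
    beta_true[, s] <- pmin(pmax(sheet$control_level[s], 0.001), 0.999)

  ## ---- batch (power distortion) and dye effects ------------------------
  ## batch and dye effects are drawn from bounded uniform distributions
  ## so the worst-case technical shift is controlled by construction: a
  ## clean sample can never cross the sample-QC outlier fences, yet the
  ## shifts are large enough for normalization to have visible work
  key <- function(...) paste(..., sep = "|")
  draw_eff <- function(keys, hw) {
    u <- unique(keys)
    setNames(runif(length(u), -hw, hw), u)[keys]
  }
  b_plate <- draw_eff(sheet$plate, cfg$batch_halfwidth[["plate"]])
  b_chip <- draw_eff(key(sheet$plate, sheet$chip),
                     cfg$batch_halfwidth[["chip"]])
  b_row <- draw_eff(key(sheet$plate, sheet$row),
                    cfg$batch_halfwidth[["row"]])
  b_col <- draw_eff(key(sheet$plate, sheet$column),
                    cfg$batch_halfwidth[["column"]])
  log2_gamma <- as.numeric(b_plate + b_chip + b_row + b_col)
  gamma <- 2^log2_gamma
  log2_dye <- runif(n_samp, -cfg$dye_halfwidth, cfg$dye_halfwidth)

  T0 <- cfg$intensity_anchor
  power_distort <- function(x, g) T0 * (pmax(x, 1e-8) / T0)^g

  ## channel of each (probe, assay-channel): II = green meth / red unmeth;
  ## Type I uses a single color for both channels
  meth_green <- annotation$design_type %in% c("I-green", "II")
  unmeth_green <- annotation$design_type == "I-green"

  T_probe <- cfg$intensity_scale * rlnorm(np, 0, cfg$intensity_probe_sd)
  meth0 <- beta_true * T_probe
  unmeth0 <- (1 - beta_true) * T_probe

  det_ids <- failing$sample_id[failing$mode == "high_detection_failure"]
  det_entries <- list()
  for (s in det_ids) {
    bad <- sample.int(np, round(cfg$detection_failure_frac * np))
    det_entries[[s]] <- sort(bad)
    meth0[bad, s] <- 0
    unmeth0[bad, s] <- 0
  }

  noise <- function() matrix(rlnorm(np * n_samp, 0, cfg$noise_sd),
                             np, n_samp)
  bg <- function() matrix(pmax(rnorm(np * n_samp, cfg$background_mean,
                                     cfg$background_sd), 10), np, n_samp)
  meth <- meth0 * noise() + bg()
  unmeth <- unmeth0 * noise() + bg()

  apply_sample_effects <- function(mat, green_mask) {
    for (s in seq_len(n_samp)) {
      d <- ifelse(green_mask, 2^log2_dye[s], 2^(-log2_dye[s]))
      mat[, s] <- power_distort(mat[, s] * d, gamma[s])
    }
    mat
  }
  meth <- apply_sample_effects(meth, meth_green)
  unmeth <- apply_sample_effects(unmeth, unmeth_green)

  ## noiseless systematic M (same distortions, no noise/background)
  ms <- apply_sample_effects(pmax(meth0, 1e-6), meth_green)
  us <- apply_sample_effects(pmax(unmeth0, 1e-6), unmeth_green)
  m_systematic <- log2(ms / us)

  int_ids <- failing$sample_id[failing$mode == "intensity_outlier"]
  for (s in int_ids) {
    meth[, s] <- meth[, s] * cfg$intensity_outlier_factor
    unmeth[, s] <- unmeth[, s] * cfg$intensity_outlier_factor
  }

  ## poorly detected probes: background-only signal in a subset of
  ## samples (drives the probe-level low-detection filter); at least two
  ## hits are planted in every tissue so the per-tissue filter sees the
  ## probe, and planted-failure samples are avoided so sample QC does
  ## not mask the hits
  poor_hits <- matrix(FALSE, np, n_samp)
  cand <- which(!is_ctrl & !(sid %in% failing$sample_id))
  cand_by_tissue <- split(cand, sheet$tissue[cand])
  n_aff <- max(2L * length(cand_by_tissue),
               round(cfg$poor_probe_frac * n_samp))
  for (j in poor_probes) {
    hit <- unlist(lapply(cand_by_tissue, sample, size = 2))
    extra <- setdiff(cand, hit)
    if (n_aff > length(hit))
      hit <- c(hit, sample(extra, min(n_aff - length(hit),
                                      length(extra))))
    poor_hits[j, hit] <- TRUE
    meth[j, hit] <- pmax(rnorm(length(hit), cfg$background_mean,
                               cfg$background_sd), 10)
    unmeth[j, hit] <- pmax(rnorm(length(hit), cfg$background_mean,
                                 cfg$background_sd), 10)
  }

  beads <- matrix(4L + stats::rpois(np * n_samp, cfg$beads_mean),
                  np, n_samp, dimnames = list(probe_ids, sid))
  for (s in det_ids)
    beads[det_entries[[s]], s] <- sample(0:2, length(det_entries[[s]]),
                                         replace = TRUE)
  beads[poor_hits] <- sample(0:2, sum(poor_hits), replace = TRUE)

  ## ---- control probes --------------------------------------------------
  ctrl_block <- function(type, channel, n, base) {
    vals <- matrix(base * rlnorm(n * n_samp, 0, cfg$noise_sd), n, n_samp)
    if (type == "negative")
      vals <- matrix(pmax(rnorm(n * n_samp, cfg$background_mean,
                                cfg$background_sd), 10), n, n_samp)
    for (s in seq_len(n_samp)) {
      d <- if (channel == "green") 2^log2_dye[s] else 2^(-log2_dye[s])
      vals[, s] <- power_distort(vals[, s] * d, gamma[s])
    }
    df <- data.frame(control_type = type, channel = channel,
                     probe_id = sprintf("%s_%s_%02d", type, channel,
                                        seq_len(n)),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(setNames(as.data.frame(vals), sid)))
  }
  nb <- cfg$n_bisulfite_controls
  controls <- rbind(
    ctrl_block("negative", "green", cfg$n_negative_controls, NA),
    ctrl_block("negative", "red", cfg$n_negative_controls, NA),
    ctrl_block("bisulfite", "green", ceiling(nb / 2), cfg$bisulfite_level),
    ctrl_block("bisulfite", "red", floor(nb / 2), cfg$bisulfite_level),
    ctrl_block("norm_grn", "green", cfg$n_norm_controls, cfg$norm_level),
    ctrl_block("norm_red", "red", cfg$n_norm_controls, cfg$norm_level))

  bis_ids <- failing$sample_id[failing$mode == "low_bisulfite"]
  bis_rows <- controls$control_type == "bisulfite"
  for (s in bis_ids)
    controls[bis_rows, s] <- controls[bis_rows, s] *
      cfg$low_bisulfite_factor

  dimnames(meth) <- dimnames(unmeth) <- list(probe_ids, sid)
  ds <- methylation_dataset(meth, unmeth, beads, controls, sheet)

  truth <- list(
    cell_fractions = list(blood = W_blood, csf = W_csf),
    batch = data.frame(sample_id = sid, log2_gamma = log2_gamma,
                       log2_dye = log2_dye, stringsAsFactors = FALSE),
    failing_samples = failing,
    multimodal_probes = probe_ids[mm_probes],
    poor_probes = probe_ids[poor_probes],
    region_correlation = cfg$region_correlation,
    sv_factors = Fs,
    sv_loadings = L,
    m_systematic = m_systematic,
    references = list(blood = blood_ref, csf = csf_ref),
    bcell_outlier = bcell_outlier,
    subjects = subjects,
    config = cfg,
    seed = seed)
  list(dataset = ds, annotation = annotation, truth = truth)
}

#' Subset a dataset to selected samples
#'
#' Keeps the matrix columns, control-probe intensity columns and sample
#' sheet rows of the chosen samples.
#'
#' @param ds A `MethylationDataset`.
#' @param sample_ids Character vector of sample IDs to keep.
#' @return A `MethylationDataset` with only those samples.
#' @export
subset_samples <- function(ds, sample_ids) {
  missing <- setdiff(sample_ids, colnames(ds$meth))
  if (length(missing))
    stop("samples not in dataset: ", paste(missing, collapse = ", "))
  meta_cols <- c("control_type", "channel", "probe_id")
  methylation_dataset(
    ds$meth[, sample_ids, drop = FALSE],
    ds$unmeth[, sample_ids, drop = FALSE],
    ds$beads[, sample_ids, drop = FALSE],
    ds$controls[, c(meta_cols, sample_ids)],
    ds$samples[match(sample_ids, ds$samples$sample_id), ],
    processing = ds$processing)
}
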