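make_subject_rows <- function(n_case, n_ctrl, days = 0L,
                              tissue = "blood") {
  n <- n_case + n_ctrl
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = sprintf("P%02d", i), tissue = tissue,
               collection_day = days,
               trait = as.numeric(i <= n_case), age = 50, sex = "F",
               stringsAsFactors = FALSE)
  }))
}

test_that("all longitudinal samples of a subject share one chip", {
  subj <- make_subject_rows(4, 4, tissue = "csf")
  subj <- subj[rep(1:8, each = 3), ]
  subj$collection_day <- rep(c(1L, 4L, 7L), 8)
  sheet <- generate_plate_layout(subj, seed = 1)
  study <- sheet[!sheet$is_control_sample &
                   !grepl("_rep", sheet$sample_id), ]
  chips_per_subject <- tapply(paste(study$plate, study$chip),
                              study$subject_id,
                              function(x) length(unique(x)))
  expect_true(all(chips_per_subject == 1))
})

test_that("a balanced chip is checkerboarded under 4-neighborhood", {
  sheet <- generate_plate_layout(make_subject_rows(6, 6), seed = 3)
  study <- sheet[!sheet$is_control_sample &
                   !grepl("_rep", sheet$sample_id), ]
  for (ch in unique(paste(study$plate, study$chip))) {
    d <- study[paste(study$plate, study$chip) == ch, ]
    counts <- table(factor(d$trait, levels = c(0, 1)))
    p0 <- sum((d$row + d$column) %% 2 == 0)
    if (max(counts) > max(p0, nrow(d) - p0)) next  # counts do not permit
    for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
      adjacent <- abs(d$row[i] - d$row[j]) +
        abs(d$column[i] - d$column[j]) == 1
      if (adjacent) expect_true(d$trait[i] != d$trait[j])
    }
  }
})

test_that("plate layout is deterministic and refuses oversized subjects", {
  subj <- make_subject_rows(3, 3, tissue = "csf")
  subj <- subj[rep(1:6, each = 2), ]
  subj$collection_day <- rep(c(1L, 4L), 6)
  expect_identical(generate_plate_layout(subj, seed = 9),
                   generate_plate_layout(subj, seed = 9))
  big <- data.frame(subject_id = "P1", tissue = "csf",
                    collection_day = 1:13, trait = 0, age = 50,
                    sex = "F")
  expect_error(generate_plate_layout(big, seed = 1), "12")
})

test_that("plate QC material follows the design", {
  sim <- get_default_sim()
  s <- sim$dataset$samples
  for (pl in unique(s$plate)) {
    on_plate <- s[s$plate == pl, ]
    expect_equal(sum(on_plate$is_control_sample), 4)
    expect_setequal(on_plate$control_level[on_plate$is_control_sample],
                    c(0, 0.3, 0.7, 1.0))
    expect_equal(sum(grepl("_rep", on_plate$sample_id)), 4)
  }
  ## 0% and 100% controls at identical fixed positions on every plate
  ctrl <- s[s$is_control_sample & s$control_level %in% c(0, 1), ]
  pos <- unique(ctrl[, c("control_level", "chip", "row", "column")])
  expect_equal(nrow(pos), 2)
  ## the CSF anchor sample recurs as a replicate on every CSF plate
  csf_plates <- unique(s$plate[s$tissue == "csf"])
  if (length(csf_plates) > 1) {
    reps <- s[grepl("_rep", s$sample_id) & s$tissue == "csf", ]
    src <- sub("_repP\\d+n\\d+$", "", reps$sample_id)
    anchor <- names(which(table(src) >= length(csf_plates)))
    expect_gte(length(anchor), 1)
  }
})

test_that("reference methylome has the documented structure", {
  ref <- simulate_reference_methylome(300, n_discriminating = 0,
                                      seed = 4)
  expect_true(all(ref == ref[, 1]))          # degenerate: no separation
  ref6 <- simulate_reference_methylome(300, n_discriminating = 60,
                                       seed = 4)
  expect_identical(colnames(ref6),
                   c("CD4T", "CD8T", "NK", "monocyte", "B_cell",
                     "granulocyte"))
  expect_identical(ref6,
                   simulate_reference_methylome(300,
                                                n_discriminating = 60,
                                                seed = 4))
  disc <- attr(ref6, "discriminating")
  expect_length(disc, 60)
  rng <- apply(ref6[disc, ], 1, function(x) diff(range(x)))
  expect_true(all(rng > 0.5))
  expect_true(all(ref6 >= 0 & ref6 <= 1))
  expect_error(simulate_reference_methylome(10, n_discriminating = 11),
               "exceed")
})

test_that("simulated dataset is reproducible bit-for-bit", {
  a <- simulate_dataset(seed = 77)
  b <- simulate_dataset(seed = 77)
  expect_identical(a, b)
  c_ <- simulate_dataset(seed = 78)
  expect_false(identical(a$dataset$meth, c_$dataset$meth))
})

test_that("generator invariants hold: beads, controls, fractions", {
  sim <- get_default_sim()
  ds <- sim$dataset; truth <- sim$truth; s <- ds$samples
  ## beads >= 1 except at planted detection-failure / poor entries
  det_ids <- truth$failing_samples$sample_id[
    truth$failing_samples$mode == "high_detection_failure"]
  clean_cols <- setdiff(colnames(ds$beads), det_ids)
  clean_rows <- setdiff(rownames(ds$beads), truth$poor_probes)
  expect_true(all(ds$beads[clean_rows, clean_cols] >= 1))
  ## 30%-methylated control samples average near 0.30
  beta <- dataset_beta(ds)$beta
  ctrl30 <- s$sample_id[s$is_control_sample & s$control_level == 0.3]
  expect_true(all(colMeans(beta[, ctrl30, drop = FALSE]) > 0.25 &
                    colMeans(beta[, ctrl30, drop = FALSE]) < 0.35))
  ## cell fractions on the simplex
  for (w in truth$cell_fractions)
    expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-9)
  ## planted low-bisulfite sample sits below the 3-SD fence by
  ## construction
  lb <- truth$failing_samples$sample_id[
    truth$failing_samples$mode == "low_bisulfite"]
  csf_ids <- s$sample_id[s$tissue == "csf" & !s$is_control_sample]
  bis <- ds$controls[ds$controls$control_type == "bisulfite", csf_ids]
  mns <- colMeans(as.matrix(bis))
  expect_lt(mns[lb], mean(mns) - 3 * sd(mns))
})

test_that("degenerate configs behave as closed forms predict", {
  ## Dirichlet concentration -> infinity: identical rows, and
  ## deconvolution returns near-identical estimates
  sim <- simulate_dataset(list(blood_concentration = 1e9,
                               n_subjects = 12L, csf_day_prob = 0,
                               subject_sd = 1e-9,
                               latent_loading_sd = 1e-9,
                               noise_sd = 0.01,
                               failures = c(low_bisulfite = 0L,
                                            high_detection_failure = 0L,
                                            intensity_outlier = 0L,
                                            beta_outlier = 0L),
                               n_multimodal_probes = 0L,
                               n_poor_probes = 0L,
                               plant_bcell_outlier = FALSE),
                          seed = 12)
  W <- sim$truth$cell_fractions$blood
  expect_lt(max(abs(sweep(W, 2, colMeans(W)))), 1e-3)
  beta <- dataset_beta(sim$dataset)$beta
  ids <- rownames(W)
  est <- estimate_cell_proportions(beta[, ids],
                                   sim$truth$references$blood)
  expect_lt(max(apply(est$proportions, 2, sd)), 0.02)
  ## unknown config keys are rejected
  expect_error(simulate_dataset(list(nonsense = 1), seed = 1),
               "unknown config")
  expect_error(simulate_dataset(list(failures = c(
    low_bisulfite = 99L, high_detection_failure = 0L,
    intensity_outlier = 0L, beta_outlier = 0L)), seed = 1),
    "failures")
})
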