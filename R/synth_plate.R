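## Plate layout generation.
##
## A plate holds 8 chips of 12 positions (6 rows x 2 columns).  Per plate,
## four positions carry fixed-methylation control samples (0/30/70/100%;
## two at fixed positions on every plate, two at seeded-random positions)
## and four carry technical replicates.  All longitudinal samples of a
## subject are kept on one chip, and trait cases/controls are
## checkerboarded within chips by (row + column) parity where counts
## permit.

PLATE_CHIPS <- 8L
CHIP_ROWS <- 6L
CHIP_COLS <- 2L
CHIP_SIZE <- CHIP_ROWS * CHIP_COLS            # 12
PLATE_SIZE <- PLATE_CHIPS * CHIP_SIZE         # 96
PLATE_QC_POSITIONS <- 8L                      # 4 controls + 4 replicates
PLATE_STUDY_CAPACITY <- PLATE_SIZE - PLATE_QC_POSITIONS  # 88

## Fixed control positions, identical on every plate (last chip, last row).
FIXED_CONTROL_SLOTS <- data.frame(
  chip = c(PLATE_CHIPS, PLATE_CHIPS), row = c(CHIP_ROWS, CHIP_ROWS),
  column = c(1L, 2L), control_level = c(0, 1.0))

#' Generate a plate layout for one tissue
#'
#' Packs study samples onto plates/chips so that all longitudinal samples
#' of a subject share one chip, checkerboards DCI-like trait cases and
#' controls within chips by position parity, and adds the per-plate QC
#' material: four fixed-methylation control samples (0, 30, 70, 100%
#' methylated; the 0% and 100% controls at the same position on every
#' plate, the 30% and 70% at seeded-random positions) and four technical
#' replicates.  For CSF, one designated sample recurs as a replicate on
#' every plate; the remaining replicates duplicate random samples of the
#' same plate.
#'
#' @param subjects Data frame with one row per study sample: columns
#'   `subject_id`, `tissue` (single value), `collection_day`, `trait`,
#'   `age`, `sex`.
#' @param seed Integer seed; the layout is deterministic given it.
#' @param plate_prefix Prefix for plate identifiers (default derived from
#'   the tissue: `"B"` or `"C"`).
#' @param anchor_replicate Should one sample recur as a replicate on every
#'   plate (the CSF design)?  Default `TRUE` for csf, `FALSE` for blood.
#' @return A validated sample sheet (see [validate_sample_sheet()]).
#' @export
generate_plate_layout <- function(subjects, seed,
                                  plate_prefix = NULL,
                                  anchor_replicate = NULL) {
  stopifnot(is.data.frame(subjects), nrow(subjects) > 0)
  tissue <- unique(subjects$tissue)
  if (length(tissue) != 1)
    stop("generate_plate_layout handles one tissue at a time")
  if (is.null(plate_prefix))
    plate_prefix <- if (tissue == "blood") "B" else "C"
  if (is.null(anchor_replicate)) anchor_replicate <- tissue == "csf"
  sizes <- table(subjects$subject_id)
  if (any(sizes > CHIP_SIZE))
    stop("subject(s) with more than ", CHIP_SIZE,
         " longitudinal samples cannot fit one chip: ",
         paste(names(sizes)[sizes > CHIP_SIZE], collapse = ", "))
  withr::with_seed(seed, build_layout(subjects, plate_prefix,
                                      anchor_replicate))
}

build_layout <- function(subjects, plate_prefix, anchor_replicate) {
  subjects$sample_id <- paste0(subjects$subject_id, "_", subjects$tissue,
                               "_d", subjects$collection_day)
  if (anyDuplicated(subjects$sample_id))
    stop("duplicate (subject, day) study samples")

  ## Order subjects: interleave trait cases and controls, larger
  ## longitudinal series first, so chips mix both trait groups.
  per_subj <- split(subjects, subjects$subject_id)
  subj_trait <- vapply(per_subj, function(d) d$trait[1], numeric(1))
  subj_size <- vapply(per_subj, nrow, integer(1))
  cases <- names(per_subj)[!is.na(subj_trait) & subj_trait == 1]
  ctrls <- setdiff(names(per_subj), cases)
  cases <- cases[order(-subj_size[cases])]
  ctrls <- ctrls[order(-subj_size[ctrls])]
  ord <- character(0)
  i <- j <- 1
  while (i <= length(cases) || j <= length(ctrls)) {
    if (i <= length(cases)) { ord <- c(ord, cases[i]); i <- i + 1 }
    if (j <= length(ctrls)) { ord <- c(ord, ctrls[j]); j <- j + 1 }
  }

  ## First-fit packing of subjects into chips; the last chip of each plate
  ## loses the two fixed control positions.
  chip_cap <- function(chip) {
    CHIP_SIZE - sum(FIXED_CONTROL_SLOTS$chip == chip)
  }
  n_plates <- max(1L, ceiling(nrow(subjects) / PLATE_STUDY_CAPACITY))
  repeat {
    chips <- expand.grid(chip = seq_len(PLATE_CHIPS),
                         plate = seq_len(n_plates))
    chips <- chips[order(chips$plate, chips$chip), ]
    chips$free <- vapply(chips$chip, chip_cap, integer(1))
    plate_free <- rep(PLATE_STUDY_CAPACITY, n_plates)
    assign_chip <- rep(NA_integer_, length(ord))
    ok <- TRUE
    for (s in seq_along(ord)) {
      size <- subj_size[ord[s]]
      hit <- which(chips$free >= size & plate_free[chips$plate] >= size)
      if (!length(hit)) { ok <- FALSE; break }
      k <- hit[1]
      assign_chip[s] <- k
      chips$free[k] <- chips$free[k] - size
      plate_free[chips$plate[k]] <- plate_free[chips$plate[k]] - size
    }
    if (ok) break
    n_plates <- n_plates + 1L
  }

  ## Position assignment within each chip: trait cases on one parity,
  ## controls on the other, overflow greedily into remaining slots.
  rows <- list()
  for (k in seq_len(nrow(chips))) {
    ids <- ord[which(assign_chip == k)]
    if (!length(ids)) next
    d <- do.call(rbind, per_subj[ids])
    plate <- chips$plate[k]; chip <- chips$chip[k]
    slots <- expand.grid(row = seq_len(CHIP_ROWS),
                         column = seq_len(CHIP_COLS))
    fixed_here <- FIXED_CONTROL_SLOTS[FIXED_CONTROL_SLOTS$chip == chip, ]
    if (nrow(fixed_here)) {
      drop <- paste(slots$row, slots$column) %in%
        paste(fixed_here$row, fixed_here$column)
      slots <- slots[!drop, ]
    }
    parity <- (slots$row + slots$column) %% 2
    p0 <- slots[parity == 0, ]; p1 <- slots[parity == 1, ]
    is_case <- !is.na(d$trait) & d$trait == 1
    case_rows <- d[is_case, ]; ctrl_rows <- d[!is_case, ]
    take <- function(pool, n) if (n == 0) pool[0, ] else pool[seq_len(n), ]
    n_case0 <- min(nrow(case_rows), nrow(p0))
    n_ctrl1 <- min(nrow(ctrl_rows), nrow(p1))
    assigned <- rbind(
      cbind(take(p0, n_case0), case_rows[seq_len(n_case0), , drop = FALSE]),
      cbind(take(p1, n_ctrl1), ctrl_rows[seq_len(n_ctrl1), , drop = FALSE]))
    left <- rbind(case_rows[seq_len(nrow(case_rows)) > n_case0, ,
                            drop = FALSE],
                  ctrl_rows[seq_len(nrow(ctrl_rows)) > n_ctrl1, ,
                            drop = FALSE])
    if (nrow(left)) {
      used <- paste(assigned$row, assigned$column)
      rest <- slots[!(paste(slots$row, slots$column) %in% used), ]
      assigned <- rbind(assigned, cbind(take(rest, nrow(left)), left))
    }
    assigned$plate <- plate; assigned$chip <- chip
    rows[[length(rows) + 1]] <- assigned
  }
  sheet <- do.call(rbind, rows)
  sheet$replicate_group <- NA_character_
  sheet$is_control_sample <- FALSE
  sheet$control_level <- NA_real_

  ## QC material per plate: fixed + random controls, then replicates.
  qc <- list()
  anchor_id <- NULL
  for (p in seq_len(n_plates)) {
    on_plate <- sheet[sheet$plate == p, ]
    used <- paste(on_plate$chip, on_plate$row, on_plate$column)
    all_slots <- expand.grid(row = seq_len(CHIP_ROWS),
                             column = seq_len(CHIP_COLS),
                             chip = seq_len(PLATE_CHIPS))
    fixed_key <- paste(FIXED_CONTROL_SLOTS$chip, FIXED_CONTROL_SLOTS$row,
                       FIXED_CONTROL_SLOTS$column)
    free <- all_slots[!(paste(all_slots$chip, all_slots$row,
                              all_slots$column) %in% c(used, fixed_key)), ]
    free <- free[sample.int(nrow(free)), ]
    tissue <- subjects$tissue[1]
    ctrl_row <- function(level, chip, row, column) {
      data.frame(sample_id = sprintf("CTRL%03d_%s_P%d", round(level * 100),
                                     tissue, p),
                 subject_id = sprintf("CTRL%03d", round(level * 100)),
                 tissue = tissue, collection_day = 0L,
                 plate = p, chip = chip, row = row, column = column,
                 replicate_group = NA_character_, trait = NA_real_,
                 age = NA_real_, sex = NA_character_,
                 is_control_sample = TRUE, control_level = level)
    }
    qc[[length(qc) + 1]] <- ctrl_row(0, FIXED_CONTROL_SLOTS$chip[1],
                                     FIXED_CONTROL_SLOTS$row[1],
                                     FIXED_CONTROL_SLOTS$column[1])
    qc[[length(qc) + 1]] <- ctrl_row(1, FIXED_CONTROL_SLOTS$chip[2],
                                     FIXED_CONTROL_SLOTS$row[2],
                                     FIXED_CONTROL_SLOTS$column[2])
    qc[[length(qc) + 1]] <- ctrl_row(0.3, free$chip[1], free$row[1],
                                     free$column[1])
    qc[[length(qc) + 1]] <- ctrl_row(0.7, free$chip[2], free$row[2],
                                     free$column[2])
    free <- free[-(1:2), ]

    ## Replicates: one cross-plate anchor (csf design) + random same-plate
    ## duplicates.
    if (anchor_replicate && is.null(anchor_id))
      anchor_id <- sheet$sample_id[sheet$plate == 1][
        sample.int(sum(sheet$plate == 1), 1)]
    n_rep <- 4L
    src_ids <- character(0)
    if (anchor_replicate) src_ids <- anchor_id
    pool <- setdiff(on_plate$sample_id, src_ids)
    src_ids <- c(src_ids,
                 sample(pool, min(n_rep - length(src_ids), length(pool))))
    for (r in seq_along(src_ids)) {
      src <- sheet[sheet$sample_id == src_ids[r], ]
      grp <- paste0("rg_", src$sample_id)
      sheet$replicate_group[sheet$sample_id == src$sample_id] <- grp
      qc[[length(qc) + 1]] <- data.frame(
        sample_id = paste0(src$sample_id, "_repP", p, "n", r),
        subject_id = src$subject_id, tissue = src$tissue,
        collection_day = src$collection_day,
        plate = p, chip = free$chip[r], row = free$row[r],
        column = free$column[r],
        replicate_group = grp, trait = src$trait, age = src$age,
        sex = src$sex, is_control_sample = FALSE,
        control_level = NA_real_)
    }
  }
  keep <- c("sample_id", "subject_id", "tissue", "collection_day",
            "plate", "chip", "row", "column", "replicate_group", "trait",
            "age", "sex", "is_control_sample", "control_level")
  sheet <- rbind(sheet[, keep], do.call(rbind, qc)[, keep])
  sheet$plate <- paste0(plate_prefix, sheet$plate)
  sheet <- sheet[order(sheet$plate, sheet$chip, sheet$column, sheet$row), ]
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
  sheet
}
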