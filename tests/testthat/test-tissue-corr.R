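test_that("extreme-beta filter needs both tissues uniformly extreme", {
  probes <- c("all_high", "high_blood_only", "all_low", "mixed")
  bb <- rbind(rep(0.95, 5), rep(0.95, 5), rep(0.05, 5),
              c(0.2, 0.5, 0.8, 0.3, 0.6))
  cb <- rbind(rep(0.93, 5), c(0.95, 0.5, 0.95, 0.95, 0.95),
              rep(0.04, 5), rep(0.5, 5))
  rownames(bb) <- rownames(cb) <- probes
  kept <- extreme_beta_filter(bb, cb)
  expect_setequal(kept, c("high_blood_only", "mixed"))
  ## idempotent and order-invariant over samples
  perm <- c(3, 1, 5, 2, 4)
  expect_setequal(extreme_beta_filter(bb[, perm], cb[, perm]), kept)
  expect_setequal(extreme_beta_filter(bb[kept, ], cb[kept, ]), kept)
})

test_that("M-value adjustment removes covariate effects", {
  withr::with_seed(4, {
    n <- 40; np <- 200
    age <- rnorm(n, 50, 10)
    sex <- sample(c("F", "M"), n, TRUE)
    svs <- matrix(rnorm(n * 2), n, 2)
    M <- matrix(rnorm(np * n), np, n)
    ## residual mode: orthogonal to all design columns
    adj <- adjust_mvalues(M, age, sex, svs, keep_intercept = FALSE)
    X <- cbind(1, scale(age, scale = FALSE),
               as.numeric(sex == "M") - mean(sex == "M"), svs)
    expect_lt(max(abs(adj %*% X)), 1e-7)
    ## perfect fit: M linear in age vanishes
    M2 <- outer(rnorm(np), age)
    adj2 <- adjust_mvalues(M2, age, sex, keep_intercept = FALSE)
    expect_lt(max(abs(adj2)), 1e-7)
    ## default keeps the probe mean on the M scale
    adj3 <- adjust_mvalues(M + 5, age, sex)
    expect_equal(rowMeans(adj3), rowMeans(M + 5), tolerance = 1e-8)
    ## rank-deficient design rejected
    expect_error(adjust_mvalues(M, age, sex,
                                cbind(age - mean(age), svs)),
                 "rank deficient")
  })
})

test_that("within-CpG correlation is Pearson across paired subjects", {
  pairs <- data.frame(subject_id = paste0("P", 1:4),
                      blood = paste0("b", 1:4), csf = paste0("c", 1:4))
  bb <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4, byrow = TRUE,
               dimnames = list(c("cg1", "cg2"), paste0("b", 1:4)))
  ## identical and affine profiles give r = 1
  cb <- 2 * bb + 3
  colnames(cb) <- paste0("c", 1:4)
  r <- within_cpg_correlation(bb, cb, pairs)
  expect_equal(unname(r), c(1, 1))
  ## hand-computed Pearson: (1,2,3,4) vs (2,1,4,3) -> 0.6
  cb2 <- rbind(c(2, 1, 4, 3), c(2, 1, 4, 3))
  dimnames(cb2) <- dimnames(cb)
  expect_equal(unname(within_cpg_correlation(bb, cb2, pairs)[1]), 0.6)
  ## zero variance -> NA
  bb0 <- bb; bb0[1, ] <- 7
  expect_true(is.na(within_cpg_correlation(bb0, cb, pairs)[1]))
  expect_error(within_cpg_correlation(bb, cb, pairs[1:2, ]), "3")
  ## invariance to per-tissue affine maps, near machine precision
  withr::with_seed(8, {
    n <- 30; np <- 50
    pr <- data.frame(subject_id = paste0("P", 1:n),
                     blood = paste0("b", 1:n), csf = paste0("c", 1:n))
    xb <- matrix(rnorm(np * n), np, n,
                 dimnames = list(paste0("cg", 1:np), pr$blood))
    xc <- matrix(rnorm(np * n), np, n,
                 dimnames = list(paste0("cg", 1:np), pr$csf))
    r0 <- within_cpg_correlation(xb, xc, pr)
    r1 <- within_cpg_correlation(1.7 * xb - 4, 0.3 * xc + 11, pr)
    expect_equal(r0, r1, tolerance = 1e-12)
  })
})

test_that("within-individual correlation behaves at both extremes", {
  withr::with_seed(10, {
    n <- 6; np <- 10000
    pr <- data.frame(subject_id = paste0("P", 1:n),
                     blood = paste0("b", 1:n), csf = paste0("c", 1:n))
    base <- rnorm(np, 0, 2)
    xb <- matrix(base, np, n, dimnames = list(NULL, pr$blood))
    xc <- matrix(base, np, n, dimnames = list(NULL, pr$csf))
    expect_equal(unname(within_individual_correlation(xb, xc, pr)),
                 rep(1, n))
    ## independent noise profiles: |r| ~ 1/sqrt(np)
    xb2 <- matrix(rnorm(np * n), np, n, dimnames = list(NULL, pr$blood))
    xc2 <- matrix(rnorm(np * n), np, n, dimnames = list(NULL, pr$csf))
    expect_true(all(abs(within_individual_correlation(xb2, xc2, pr)) <
                      0.05))
    expect_error(within_individual_correlation(xb2[1:5, ], xc2[1:5, ],
                                               pr), "10")
  })
})

test_that("shared architecture dissociates the two correlation scales", {
  ## strong within-individual r can coexist with weak within-CpG r when
  ## tissues share the probe-level methylation architecture
  withr::with_seed(12, {
    n <- 30; np <- 3000
    pr <- data.frame(subject_id = paste0("P", 1:n),
                     blood = paste0("b", 1:n), csf = paste0("c", 1:n))
    mu <- rnorm(np, 0, 2)                    # shared architecture
    rho <- 0.2
    b_dev <- matrix(rnorm(np * n, 0, 0.5), np, n)
    c_dev <- rho * b_dev +
      sqrt(1 - rho^2) * matrix(rnorm(np * n, 0, 0.5), np, n)
    xb <- mu + b_dev; xc <- mu + c_dev
    dimnames(xb) <- list(NULL, pr$blood)
    dimnames(xc) <- list(NULL, pr$csf)
    r_cpg <- within_cpg_correlation(xb, xc, pr)
    r_ind <- within_individual_correlation(xb, xc, pr)
    expect_lt(mean(r_cpg), 0.35)
    expect_gt(mean(r_ind), 0.9)
  })
})

test_that("stratified comparison is calibrated and recovers ordering", {
  ann <- data.frame(probe_id = sprintf("cg%04d", 1:1200),
                    design_type = "II", chromosome = "1",
                    region = rep(c("island", "shore", "shelf",
                                   "open_sea"), each = 300),
                    orientation = "body", snp_overlap = FALSE,
                    cross_reactive = FALSE)
  ## identical distributions: omnibus p uniform over replicates
  ps <- withr::with_seed(13, vapply(1:80, function(i) {
    r <- setNames(rnorm(1200, 0.2, 0.15), ann$probe_id)
    stratified_comparison(r, ann, "region")$omnibus$p_value
  }, numeric(1)))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  ## shifted strata: ordering recovered, omnibus significant
  r2 <- withr::with_seed(14, setNames(
    rnorm(1200, rep(c(0.45, 0.35, 0.20, 0.10), each = 300), 0.15),
    ann$probe_id))
  sc <- stratified_comparison(r2, ann, "region")
  means <- setNames(sc$summary$mean, sc$summary$stratum)
  expect_true(means["island"] > means["shore"] &
                means["shore"] > means["shelf"] &
                means["shelf"] > means["open_sea"])
  expect_lt(sc$omnibus$p_value, 0.001)
  expect_true(all(dim(sc$pairwise) == c(3, 3)))
  ## a single stratum is an error
  ann1 <- ann; ann1$region <- "island"
  expect_error(
    suppressWarnings(stratified_comparison(r2, ann1, "region")),
    "2 strata")
  ## NA correlations are excluded and counted
  r3 <- r2; r3[1:5] <- NA
  expect_equal(stratified_comparison(r3, ann, "region")$n_na, 5)
})
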