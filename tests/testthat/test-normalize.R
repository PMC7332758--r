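test_that("normexp background correction matches the convolution model", {
  ## the posterior-mean engine agrees with numerical integration
  mu <- 100; sigma <- 10; alpha <- 500
  par <- c(mu, log(sigma), log(alpha))
  for (x in c(120, 150, 300, 1000)) {
    expect_equal(limma::normexp.signal(par, x),
                 normexp_posterior_quadrature(x, mu, sigma, alpha),
                 tolerance = 1e-4, label = paste("x =", x))
  }
  ## asymptote: far above background, corrected ~ observed - mu
  x <- mu + 20 * sigma + 5000
  expect_equal(limma::normexp.signal(par, x), x - mu,
               tolerance = 0.01 * x)
  ## positivity at zero observed intensity
  expect_gt(limma::normexp.signal(par, 0), 0)
})

test_that("background correction is positive and idempotent", {
  sim <- get_default_sim()
  s <- sim$dataset$samples
  ids <- s$sample_id[s$tissue == "blood" & !s$is_control_sample]
  sub <- subset_samples(sim$dataset, ids)
  bg <- background_correct(sub, sim$annotation)
  expect_true(all(bg$meth > 0) && all(bg$unmeth > 0))
  expect_true("background_corrected" %in% bg$processing)
  ## high-signal probes shift by about the background mean
  neg <- sub$controls[sub$controls$control_type == "negative", ]
  s1 <- ids[1]
  mu_g <- mean(neg[neg$channel == "green", s1])
  big <- which(sub$meth[, s1] > mu_g + 8 * sd(neg[neg$channel == "green",
                                                 s1]))
  ## restrict to green-channel meth probes
  ch <- sim$annotation$design_type[match(rownames(sub$meth),
                                         sim$annotation$probe_id)]
  big <- intersect(big, which(ch %in% c("II", "I-green")))
  expect_true(all(abs(bg$meth[big, s1] - (sub$meth[big, s1] - mu_g)) <
                    0.02 * sub$meth[big, s1]))
  ## re-application is an exact identity
  expect_identical(background_correct(bg, sim$annotation), bg)
})

test_that("dye-bias correction equalizes channel control means", {
  sim <- get_default_sim()
  s <- sim$dataset$samples
  ids <- s$sample_id[s$tissue == "blood" & !s$is_control_sample]
  sub <- subset_samples(sim$dataset, ids)
  dc <- dye_bias_correct(sub, sim$annotation)
  g <- colMeans(as.matrix(
    dc$controls[dc$controls$control_type == "norm_grn", ids]))
  r <- colMeans(as.matrix(
    dc$controls[dc$controls$control_type == "norm_red", ids]))
  expect_equal(unname(g), unname(r), tolerance = 1e-9)
  ## idempotent within numerical tolerance
  dc2 <- dye_bias_correct(dc, sim$annotation)
  expect_equal(dc2$meth, dc$meth, tolerance = 1e-6)
  ## balanced channels: identity transform
  bal <- sub
  v <- as.matrix(bal$controls[, ids])
  v[bal$controls$control_type == "norm_grn", ] <- 5000
  v[bal$controls$control_type == "norm_red", ] <- 5000
  bal$controls[, ids] <- v
  dcb <- dye_bias_correct(bal, sim$annotation)
  expect_equal(dcb$meth, bal$meth, tolerance = 1e-9)
})

test_that("functional normalization has its quantile semantics", {
  sim <- get_default_sim()
  s <- sim$dataset$samples
  ids <- s$sample_id[s$tissue == "blood" & !s$is_control_sample]
  sub <- subset_samples(sim$dataset, ids)
  ## k = 0: plain quantile normalization, all samples share quantiles
  fn0 <- functional_normalize(sub, sim$annotation, k = 0)
  ch <- sim$annotation$design_type[match(rownames(sub$meth),
                                         sim$annotation$probe_id)]
  q <- apply(fn0$dataset$meth[ch == "II", ], 2, quantile,
             probs = c(0.1, 0.25, 0.5, 0.75, 0.9))
  ## shared to within the 500-anchor interpolation resolution
  expect_lt(max(apply(q, 1, sd) / apply(q, 1, mean)), 0.01)
  ## rank order within sample and stratum is preserved
  for (d in c("I-green", "II")) {
    idx <- which(ch == d)
    s1 <- ids[1]
    expect_equal(rank(fn0$dataset$meth[idx, s1], ties.method = "first"),
                 rank(sub$meth[idx, s1], ties.method = "first"))
  }
  ## identical samples: output equals input within interpolation
  ## tolerance
  same <- sub
  for (nm in c("meth", "unmeth"))
    same[[nm]] <- matrix(same[[nm]][, 1], nrow(same[[nm]]),
                         ncol(same[[nm]]), dimnames = dimnames(same[[nm]]))
  v <- as.matrix(same$controls[, ids])
  same$controls[, ids] <- v[, rep(1, length(ids))]
  fn_same <- functional_normalize(same, sim$annotation, k = 2)
  expect_equal(fn_same$dataset$meth, same$meth, tolerance = 1e-6)
  ## k >= n_samples rejected
  expect_error(functional_normalize(sub, sim$annotation,
                                    k = length(ids)), "k")
})

test_that("control-PC-correlated distortion is removed almost entirely", {
  ## samples identical up to a monotone power distortion mirrored in the
  ## control probes
  set.seed(3)
  np <- 400; ns <- 12
  x0 <- 6000 * rlnorm(np, 0, 0.4)
  gam <- seq(0.8, 1.2, length.out = ns)
  T0 <- 10000
  pd <- function(x, g) T0 * (x / T0)^g
  meth <- sapply(gam, function(g) pd(x0 * 0.6, g))
  unmeth <- sapply(gam, function(g) pd(x0 * 0.4, g))
  probe_ids <- sprintf("cg%03d", 1:np)
  sids <- sprintf("S%02d", 1:ns)
  dimnames(meth) <- dimnames(unmeth) <- list(probe_ids, sids)
  beads <- matrix(10L, np, ns, dimnames = dimnames(meth))
  mk <- function(type, channel, n, lvl) {
    v <- sapply(gam, function(g) pd(rep(lvl, n), g))
    cbind(data.frame(control_type = type, channel = channel,
                     probe_id = paste0(type, channel, 1:n)),
          as.data.frame(setNames(as.data.frame(v), sids)))
  }
  controls <- rbind(mk("negative", "green", 10, 150),
                    mk("negative", "red", 10, 150),
                    mk("bisulfite", "green", 5, 4000),
                    mk("norm_grn", "green", 8, 5000),
                    mk("norm_red", "red", 8, 5000))
  sheet <- data.frame(sample_id = sids, subject_id = sids,
                      tissue = "blood", collection_day = 0L, plate = 1,
                      chip = rep(1:2, each = 6), row = rep(1:6, 2),
                      column = 1L, replicate_group = NA_character_,
                      trait = NA_real_, age = NA_real_,
                      sex = NA_character_, is_control_sample = FALSE,
                      control_level = NA_real_)
  ds <- methylation_dataset(meth, unmeth, beads, controls, sheet)
  fn <- functional_normalize(ds, k = 2)
  qsd <- function(m) mean(apply(apply(log2(m + 1), 2, quantile,
                                      probs = seq(0.05, 0.95, 0.05)),
                                1, sd))
  expect_lt(qsd(fn$dataset$meth), 0.1 * qsd(ds$meth))
})

test_that("replicate concordance test has the stated behavior", {
  ## degenerate: after == before -> undefined, p = NA with reason
  m <- matrix(rnorm(100 * 6), 100, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  groups <- list(g1 = c("S1", "S2"), g2 = c("S3", "S4"),
                 g3 = c("S5", "S6"))
  same <- replicate_concordance_test(m, m, groups)
  expect_true(is.na(same$p_value))
  expect_match(same$reason, "zero variance")
  ## frozen arithmetic: d_before = (4,9,16,25), d_after = (1,1,4,4)
  ## -> paired t on differences (3,8,12,21), df = 3
  med_b <- c(S1 = 0, S2 = 2, S3 = 0, S4 = 3, S5 = 0, S6 = 4,
             S7 = 0, S8 = 5)
  med_a <- c(S1 = 0, S2 = 1, S3 = 0, S4 = 1, S5 = 0, S6 = 2,
             S7 = 0, S8 = 2)
  mb <- rbind(med_b, med_b, med_b)   # constant columns: median = value
  ma <- rbind(med_a, med_a, med_a)
  colnames(mb) <- colnames(ma) <- names(med_b)
  groups2 <- list(p1 = c("S1", "S2"), p2 = c("S3", "S4"),
                  p3 = c("S5", "S6"), p4 = c("S7", "S8"))
  res <- replicate_concordance_test(mb, ma, groups2)
  expect_equal(sort(res$pairs$d_before), c(4, 9, 16, 25))
  expect_equal(sort(res$pairs$d_after), c(1, 1, 4, 4))
  d <- c(3, 8, 12, 21)
  t_manual <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, pt(t_manual, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  ## groups of size > 2 expand into all unordered pairs
  expect_equal(nrow(replicate_pairs(list(g = paste0("S", 1:4)))), 6)
  ## perfect equalization with varying d_before: p < 0.05
  res2 <- replicate_concordance_test(mb, 0 * ma, groups2)
  expect_lt(res2$p_value, 0.05)
})

test_that("normalization tightens replicates on planted batch effects", {
  conc <- concordance_for_seed(11)
  for (tissue in c("blood", "csf"))
    expect_lt(mean(conc[[tissue]]$pairs$d_after),
              mean(conc[[tissue]]$pairs$d_before))
})
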