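make_expr_sheet <- function(tnf, actd, time_h = 1) {
  # one gene per row of cbind(tnf, actd); two identical replicates per arm
  expr <- cbind(tnf, tnf, actd, actd)
  rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  colnames(expr) <- c("t1", "t2", "a1", "a2")
  sheet <- data.frame(sample_id = colnames(expr), time_h = time_h,
                      arm = c("TNF", "TNF", "TNF_ACTD", "TNF_ACTD"),
                      replicate = c(1, 2, 1, 2))
  list(expr = expr, sheet = sheet)
}

test_that("stability ratios follow the chase/no-chase definition", {
  d <- make_expr_sheet(tnf = c(100, 200, 0, 100), actd = c(100, 50, 10, 130))
  st <- stability_ratio(d$expr, d$sheet, 1)
  expect_equal(st$S_raw[1:2], c(1, 0.25))
  expect_true(st$excluded[3])
  expect_equal(st$reason[3], "zero_tnf_mean")
  # raw ratio above 1 clips to 1 -> class 5
  expect_equal(st$S_raw[4], 1.3)
  expect_equal(st$S[4], 1)
  expect_equal(st$stability_class[4], 5L)
  expect_error(stability_ratio(d$expr, d$sheet, 3), "required at time 3")
})

test_that("replicates are averaged per arm before the ratio", {
  expr <- matrix(c(100, 300, 40, 60), 1, 4,
                 dimnames = list("gA", c("t1", "t2", "a1", "a2")))
  sheet <- data.frame(sample_id = colnames(expr), time_h = 1,
                      arm = c("TNF", "TNF", "TNF_ACTD", "TNF_ACTD"),
                      replicate = c(1, 2, 1, 2))
  st <- stability_ratio(expr, sheet, 1)
  expect_equal(st$S_raw, 50 / 200)  # mean(40,60)/mean(100,300), not mean of ratios
})

test_that("classification uses equal-width 0.2 bins with closed top bin", {
  expect_equal(classify_stability(c(0.15, 0.85)), c(1L, 5L))
  expect_equal(classify_stability(c(0, 0.2, 0.4, 0.6, 0.8, 1)),
               c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_error(classify_stability(1.3), "clipped")
})

test_that("composition fractions are exact and sum to 1", {
  expect_equal(stabilome_composition(rep(5L, 4))$fraction, c(0, 0, 0, 0, 1))
  expect_equal(stabilome_composition(c(1L, 1L, 5L, 5L))$fraction,
               c(0.5, 0, 0, 0, 0.5))
  expect_error(stabilome_composition(integer(0)), "empty")
  set.seed(2)
  for (i in 1:10) {
    cls <- sample.int(5, 50, replace = TRUE)
    expect_equal(sum(stabilome_composition(cls)$fraction), 1,
                 tolerance = 1e-12)
  }
})

test_that("noiseless expected counts give S = exp(-lambda * t_chase) exactly", {
  lambda <- c(0, 0.1, 0.5, 2)
  t_chase <- 3
  tnf <- rep(1000, 4)
  d <- make_expr_sheet(tnf = tnf, actd = tnf * exp(-lambda * t_chase))
  st <- stability_ratio(d$expr, d$sheet, 1)
  expect_equal(st$S_raw, exp(-lambda * t_chase), tolerance = 1e-12)
})

test_that("ActD response test flags unstable genes and honors the count filter", {
  set.seed(51)
  n <- 300
  truth <- make_truth(n, mixture = c(constitutive = 1),
                      basal_range = c(300, 3000), s_jitter_sd = 0, seed = 51)
  # half the genes strongly destabilized (S = 0.1), half perfectly stable
  for (t in c(1, 72)) truth[[paste0("lambda_", t)]] <-
    rep(c(-log(0.1) / 3, 0), length.out = n)
  sim <- simulate_counts(truth, sim_design(times = c(0, 1, 72),
                                           sf = rep(1, 10), seed = 52))
  res <- actd_response_test(sim$counts, sim$sheet, 1,
                            sf = setNames(rep(1, 10), sim$sheet$sample_id))
  unstable <- seq(1, n, 2)
  down <- res$significant & res$log2fc < 0
  expect_gt(mean(down[match(truth$gene_id[unstable], res$gene_id)],
                 na.rm = TRUE), 0.95)
  stable_called <- down[match(truth$gene_id[-unstable], res$gene_id)]
  expect_lt(mean(stable_called, na.rm = TRUE), 0.15)

  # gene with 80 raw TNF counts is excluded by the >100 filter
  cm <- sim$counts
  cm["gene00001", sim$sheet$arm == "TNF" & sim$sheet$time_h == 1] <- 40L
  res2 <- actd_response_test(cm, sim$sheet, 1)
  expect_false("gene00001" %in% res2$gene_id)
})

test_that("two-step workflow classifies stabilized vs destabilized genes", {
  set.seed(61)
  n <- 240
  truth <- make_truth(n, mixture = c(constitutive = 1),
                      basal_range = c(300, 3000), s_jitter_sd = 0, seed = 61)
  kind <- rep(c("stabilized", "destabilized", "stable"), length.out = n)
  s_early <- c(stabilized = 0.2, destabilized = 0.8, stable = 1)[kind]
  s_late <- c(stabilized = 0.8, destabilized = 0.2, stable = 1)[kind]
  truth$lambda_1 <- -log(pmax(s_early, 1e-6)) / 3
  truth$lambda_72 <- -log(pmax(s_late, 1e-6)) / 3
  sim <- simulate_counts(truth, sim_design(times = c(0, 1, 72),
                                           sf = rep(1, 10), seed = 62))
  wf <- two_step_stabilization_workflow(sim$counts, sim$sheet,
                                        sf = setNames(rep(1, 10),
                                                      sim$sheet$sample_id))
  calls <- wf$genes$direction[match(truth$gene_id[kind == "stabilized"],
                                    wf$genes$gene_id)]
  expect_gt(mean(calls == "stabilized", na.rm = TRUE), 0.9)
  # destabilized genes (S_early = 0.8) are mostly not ActD-down at early,
  # but those that enter step 1 must be called destabilized
  calls_d <- wf$genes$direction[match(truth$gene_id[kind == "destabilized"],
                                      wf$genes$gene_id)]
  calls_d <- calls_d[!is.na(calls_d)]
  if (length(calls_d)) expect_gt(mean(calls_d == "destabilized"), 0.8)
  expect_true(all(c("sign_only", "sign_and_late_significant") %in%
                    wf$summary$variant))
})

test_that("genes not expressed at late are dropped with a reason", {
  set.seed(63)
  truth <- make_truth(120, mixture = c(constitutive = 1),
                      basal_range = c(500, 2000), s_jitter_sd = 0, seed = 63)
  truth$lambda_1 <- rep(-log(0.1) / 3, 120)
  truth$lambda_72 <- rep(-log(0.1) / 3, 120)
  # first gene disappears at 72 h
  truth$fold_72[1] <- 1e-4
  sim <- simulate_counts(truth, sim_design(times = c(0, 1, 72),
                                           sf = rep(1, 10), seed = 64))
  # known factors: every gene shares the same decay, so estimated factors
  # would absorb the chase signal (see vignette)
  wf <- two_step_stabilization_workflow(sim$counts, sim$sheet,
                                        sf = setNames(rep(1, 10),
                                                      sim$sheet$sample_id))
  expect_true(truth$gene_id[1] %in% wf$dropped$gene_id)
  expect_match(wf$dropped$reason[1], "not expressed at late")
})

test_that("differential stabilization recovers beta_delta and directions flip", {
  set.seed(71)
  n <- 150
  truth <- make_truth(n, mixture = c(constitutive = 1),
                      basal_range = c(500, 5000),
                      disp_trend = c(a0 = 0.05, a1 = 0), disp_noise_sd = 0,
                      s_jitter_sd = 0, seed = 71)
  truth$lambda_1 <- rep(-log(0.125) / 3, n)
  truth$lambda_72 <- rep(-log(0.5) / 3, n)
  sim <- simulate_counts(truth, sim_design(times = c(0, 1, 72),
                                           sf = rep(1, 10), seed = 72))
  sf1 <- setNames(rep(1, 10), sim$sheet$sample_id)
  res <- differential_stability_test(sim$counts, sim$sheet, 1, 72, sf = sf1)
  expect_lt(abs(median(res$beta_delta) - log(4)) / log(4), 0.15)
  expect_gt(mean(res$padj < 0.1 & res$direction == "stabilized"), 0.9)

  # antisymmetry: swapping early/late flips stabilized <-> destabilized
  swapped <- differential_stability_test(sim$counts, sim$sheet, 72, 1,
                                         sf = sf1)
  m <- match(res$gene_id, swapped$gene_id)
  expect_equal(swapped$stabilization_degree[m], -res$stabilization_degree,
               tolerance = 1e-10)
  tab <- table(res$direction, swapped$direction[m])
  expect_equal(sum(res$direction == "stabilized"),
               sum(swapped$direction == "destabilized"))

  # low-expression exclusion: normalized TNF counts ~8 are filtered out
  cm <- sim$counts
  low <- sim$sheet$arm == "TNF"
  cm[1, low] <- 8L
  res2 <- differential_stability_test(cm, sim$sheet, 1, 72, sf = sf1)
  expect_false(rownames(cm)[1] %in% res2$gene_id)
})

test_that("ranking sorts by degree with padj and gene-id tie-breaks", {
  res <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    stabilization_degree = c(2, 3, 1, 2, 2),
                    padj = c(0.05, 0.2, 0.01, 0.01, 0.01))
  top <- rank_stabilized(res, 5)
  expect_equal(top$gene_id, c("g2", "g4", "g5", "g1", "g3"))
  expect_warning(out <- rank_stabilized(res, 10), "exceeds")
  expect_equal(nrow(out), 5)
  expect_equal(nrow(rank_stabilized(res, 2)), 2)
})
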