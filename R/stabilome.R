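# Stability ratios, five-class stabilome composition, the two-step
# stabilized/destabilized workflow and the dependent-ratio differential
# stabilization GLM.

#' Normalized expression matrix
#'
#' Counts divided by their size factors, tagged with unit `NORM_COUNTS` so
#' downstream tables record which expression unit they were computed from.
#'
#' @param counts integer count matrix.
#' @param sf size factors (defaults to [size_factors()]).
#' @return numeric matrix with attribute `unit = "NORM_COUNTS"`.
#' @export
normalized_counts <- function(counts, sf = NULL) {
  counts <- validate_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  val <- sweep(counts, 2, sf, "/")
  attr(val, "unit") <- "NORM_COUNTS"
  val
}

#' Per-gene stability ratio at one time point
#'
#' The stability ratio S is the mean expression in the chase arm (TNF +
#' actinomycin D) divided by the mean expression in the no-chase (TNF) arm at
#' the same stimulation time. Replicates are averaged per arm before the
#' ratio is taken. S near 1 marks a stable transcript, near 0 an unstable
#' one; raw values above 1 are clipped to 1 for classification only.
#'
#' @param expr expression matrix (RPKM or normalized counts) with an optional
#'   `unit` attribute.
#' @param sheet sample sheet covering the columns of `expr`.
#' @param time_h stimulation time (hours) at which both arms must be present.
#' @param min_expr genes whose TNF-arm mean expression is below this are
#'   flagged excluded (`below_min_expr`); default 0 keeps all genes with a
#'   positive TNF mean.
#' @return data.frame with columns `gene_id`, `time_h`, `S_raw`, `S`
#'   (clipped), `stability_class` (1 = very unstable .. 5 = very stable),
#'   `excluded`, `reason`.
#' @export
stability_ratio <- function(expr, sheet, time_h, min_expr = 0) {
  sheet <- match_sheet(expr, sheet)
  tnf <- sheet$arm == "TNF" & sheet$time_h == time_h
  act <- sheet$arm == "TNF_ACTD" & sheet$time_h == time_h
  if (!any(tnf) || !any(act))
    stop("both TNF and TNF_ACTD arms are required at time ", time_h, " h")
  m_tnf <- rowMeans(expr[, tnf, drop = FALSE])
  m_act <- rowMeans(expr[, act, drop = FALSE])
  excluded <- m_tnf <= 0 | m_tnf < min_expr
  reason <- rep(NA_character_, nrow(expr))
  reason[m_tnf < min_expr] <- "below_min_expr"
  reason[m_tnf <= 0] <- "zero_tnf_mean"
  s_raw <- ifelse(m_tnf > 0, m_act / m_tnf, NA_real_)
  s <- pmin(pmax(s_raw, 0), 1)
  cls <- ifelse(excluded, NA_integer_, classify_stability(s))
  out <- data.frame(gene_id = rownames(expr), time_h = time_h,
                    S_raw = s_raw, S = ifelse(excluded, NA_real_, s),
                    stability_class = cls, excluded = excluded,
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "unit") <- attr(expr, "unit")
  rownames(out) <- NULL
  out
}

#' Classify a stability ratio into one of five classes
#'
#' Equal-width bins of 0.2 over the clipped ratio: class 1 = \[0, 0.2) "very
#' unstable" through class 5 = \[0.8, 1\] "very stable".
#'
#' @param S stability ratio(s), clipped to \[0, 1\].
#' @return integer class 1..5.
#' @export
classify_stability <- function(S) {
  if (any(S < 0 | S > 1, na.rm = TRUE))
    stop("S must be clipped to [0, 1] before classification")
  cls <- findInterval(S, c(0.2, 0.4, 0.6, 0.8)) + 1L
  as.integer(cls)
}

#' Stability-class composition
#'
#' Fraction of genes in each of the five stability classes (the stacked-bar
#' summary of the stabilome).
#'
#' @param classes integer vector of class labels 1..n_classes (NAs dropped).
#' @param n_classes number of classes (default 5).
#' @return data.frame with `class`, `count`, `fraction`; fractions sum to 1.
#' @export
stabilome_composition <- function(classes, n_classes = 5L) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) stop("empty gene set: no stability classes to summarize")
  if (any(classes < 1 | classes > n_classes))
    stop("class labels outside 1..", n_classes)
  cnt <- tabulate(classes, nbins = n_classes)
  data.frame(class = seq_len(n_classes), count = cnt,
             fraction = cnt / sum(cnt))
}

# shared plumbing for the two-group chase / induction tests
two_group_test_core <- function(counts, sheet, sel1, sel2, label1, label2,
                                keep, sf, dispersion, alpha) {
  if (sum(sel1) < 2 || sum(sel2) < 2)
    stop("need >= 2 replicates per group (", label1, ": ", sum(sel1), ", ",
         label2, ": ", sum(sel2), ")")
  cols <- which(sel1 | sel2)
  sub <- counts[keep, cols, drop = FALSE]
  sf_sub <- sf[cols]
  if (is.null(dispersion)) {
    dm <- estimate_dispersion(counts[, cols, drop = FALSE],
                              sheet[cols, , drop = FALSE], sf = sf_sub)
    k <- dm$final[keep]
  } else {
    k <- dispersion$final[rownames(counts)][keep]
  }
  grp <- factor(ifelse(sel1[cols], label1, label2), levels = c(label1, label2))
  res <- nb_two_group(sub, sf_sub, k, grp)
  lfc <- log2((res$mean2 + 0.5) / (res$mean1 + 0.5))
  padj <- bh_adjust(res$p)
  data.frame(gene_id = rownames(counts)[keep],
             mean1 = res$mean1, mean2 = res$mean2,
             log2fc = lfc, stat = res$stat, pvalue = res$p, padj = padj,
             significant = padj < alpha, stringsAsFactors = FALSE)
}

#' Actinomycin-D response test at one time point
#'
#' Two-group NB likelihood-ratio test (df = 1) of the chase arm against the
#' no-chase TNF arm at a given stimulation time. Genes are pre-filtered on
#' raw expression in the TNF-treated (no-chase) condition: total raw counts
#' across the TNF-arm replicates at the tested time must exceed
#' `min_counts`. Significance is called at BH-adjusted p < `alpha`.
#'
#' @param counts integer count matrix (all samples; size factors are joint).
#' @param sheet sample sheet.
#' @param time_h stimulation time to test.
#' @param min_counts raw-count filter on the TNF arm (default 100).
#' @param alpha adjusted-p significance threshold (default 0.1).
#' @param sf optional joint size factors; computed from `counts` if NULL.
#' @param dispersion optional `dispersion_model`; estimated from the tested
#'   samples if NULL.
#' @return data.frame with per-gene normalized means (`mean_tnf`,
#'   `mean_actd`), `log2fc` (chase over no-chase), `stat`, `pvalue`, `padj`,
#'   `significant`.
#' @export
actd_response_test <- function(counts, sheet, time_h, min_counts = 100,
                               alpha = 0.1, sf = NULL, dispersion = NULL) {
  counts <- validate_counts(counts)
  sheet <- match_sheet(counts, sheet)
  if (is.null(sf)) sf <- size_factors(counts)
  tnf <- sheet$arm == "TNF" & sheet$time_h == time_h
  act <- sheet$arm == "TNF_ACTD" & sheet$time_h == time_h
  keep <- rowSums(counts[, tnf, drop = FALSE]) > min_counts
  if (!any(keep)) stop("no gene passes the >", min_counts, " count filter")
  out <- two_group_test_core(counts, sheet, tnf, act, "TNF", "TNF_ACTD",
                             keep, sf, dispersion, alpha)
  names(out)[names(out) == "mean1"] <- "mean_tnf"
  names(out)[names(out) == "mean2"] <- "mean_actd"
  out$time_h <- time_h
  out
}

#' Two-step stabilized/destabilized workflow
#'
#' Step 1 identifies genes significantly down-regulated by the chase at the
#' early time (unstable candidates). Step 2 restricts to genes still
#' expressed at the late time and compares the chase log2 fold changes:
#' genes whose fold change moved toward 0 are called stabilized, genes whose
#' fold change decreased are destabilized. Both the sign-only call and the
#' variant additionally requiring significance of the late-time test are
#' reported.
#'
#' @param counts,sheet count matrix and sample sheet.
#' @param early_h,late_h early and late stimulation times (defaults 1 and 72).
#' @param min_counts,alpha filters as in [actd_response_test()].
#' @param sf optional joint size factors.
#' @return list with `early` and `late` test tables, `genes` (per-gene calls
#'   with `direction` and `sig_at_late`), `dropped` (gene, reason) and
#'   `summary` counts for both variants.
#' @export
two_step_stabilization_workflow <- function(counts, sheet, early_h = 1,
                                            late_h = 72, min_counts = 100,
                                            alpha = 0.1, sf = NULL) {
  counts <- validate_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  early <- actd_response_test(counts, sheet, early_h, min_counts, alpha, sf)
  late <- actd_response_test(counts, sheet, late_h, min_counts, alpha, sf)
  down <- early$gene_id[early$significant & early$log2fc < 0]
  at_late <- down %in% late$gene_id
  dropped <- data.frame(gene_id = down[!at_late],
                        reason = rep("not expressed at late", sum(!at_late)),
                        stringsAsFactors = FALSE)
  ids <- down[at_late]
  le <- early[match(ids, early$gene_id), ]
  ll <- late[match(ids, late$gene_id), ]
  direction <- ifelse(ll$log2fc > le$log2fc, "stabilized",
                      ifelse(ll$log2fc < le$log2fc, "destabilized",
                             "unchanged"))
  genes <- data.frame(gene_id = ids, log2fc_early = le$log2fc,
                      log2fc_late = ll$log2fc, direction = direction,
                      sig_at_late = ll$significant, stringsAsFactors = FALSE)
  summary <- data.frame(
    variant = c("sign_only", "sign_and_late_significant"),
    n_actd_down = length(down),
    n_expressed_late = length(ids),
    n_stabilized = c(sum(direction == "stabilized"),
                     sum(direction == "stabilized" & ll$significant)),
    n_destabilized = c(sum(direction == "destabilized"),
                       sum(direction == "destabilized" & ll$significant)))
  list(early = early, late = late, genes = genes, dropped = dropped,
       summary = summary)
}

#' Differential mRNA stabilization test between two stimulation times
#'
#' Dependent-ratio NB GLM: for each gene the eight libraries (TNF and
#' TNF+ActD arms at the early and late times, two replicates each by
#' default) are modeled with a log link and log size-factor offsets.
#' The alternative model has four coefficients - a TNF-arm intercept, a
#' chase-arm intercept, a shared late-time effect, and the differential
#' chase-by-time interaction `beta_delta` - and the null model drops
#' `beta_delta`. Differential stabilization is the likelihood-ratio test of
#' `beta_delta = 0` against chi-squared(1), BH-adjusted across tested genes.
#'
#' Genes whose mean normalized TNF-arm count is below `min_norm` at either
#' time are excluded. The stabilization degree is
#' `log2(S_late / S_early)` computed from mean normalized counts with
#' pseudocount 0.5, positive when stability increased over time.
#'
#' @param counts,sheet count matrix and sample sheet.
#' @param early_h,late_h the two stimulation times compared (defaults 1, 72).
#' @param min_norm normalized-count filter on the TNF arm (default 10).
#' @param alpha adjusted-p threshold for direction calls (default 0.1).
#' @param sf optional joint size factors.
#' @param dispersion optional `dispersion_model` for the eight libraries;
#'   estimated internally if NULL.
#' @return data.frame with `gene_id`, `beta_delta` (natural log),
#'   `stabilization_degree` (log2), `stat`, `pvalue`, `padj`, `direction`
#'   (stabilized / destabilized / unchanged), `flag`.
#' @export
differential_stability_test <- function(counts, sheet, early_h = 1,
                                        late_h = 72, min_norm = 10,
                                        alpha = 0.1, sf = NULL,
                                        dispersion = NULL) {
  counts <- validate_counts(counts)
  sheet <- match_sheet(counts, sheet)
  if (early_h == late_h) stop("early_h and late_h must differ")
  if (is.null(sf)) sf <- size_factors(counts)
  sel <- sheet$arm %in% c("TNF", "TNF_ACTD") & sheet$time_h %in% c(early_h, late_h)
  sub_sheet <- sheet[sel, , drop = FALSE]
  cells <- with(sub_sheet, table(droplevels(arm), time_h))
  if (!all(dim(cells) == c(2, 2)) || any(cells == 0))
    stop("all four design cells (TNF / TNF_ACTD at ", early_h, " h and ",
         late_h, " h) must be present")
  sub <- counts[, sel, drop = FALSE]
  sf_sub <- sf[sel]
  norm <- sweep(sub, 2, sf_sub, "/")

  tnf_e <- sub_sheet$arm == "TNF" & sub_sheet$time_h == early_h
  tnf_l <- sub_sheet$arm == "TNF" & sub_sheet$time_h == late_h
  act_e <- sub_sheet$arm == "TNF_ACTD" & sub_sheet$time_h == early_h
  act_l <- sub_sheet$arm == "TNF_ACTD" & sub_sheet$time_h == late_h

  keep <- rowMeans(norm[, tnf_e, drop = FALSE]) >= min_norm &
    rowMeans(norm[, tnf_l, drop = FALSE]) >= min_norm
  if (!any(keep))
    stop("no gene passes the normalized-count filter (>= ", min_norm, ")")

  if (is.null(dispersion))
    dispersion <- estimate_dispersion(sub, sub_sheet, sf = sf_sub)
  k <- dispersion$final[rownames(counts)][keep]
  Y <- sub[keep, , drop = FALSE]

  # alternative (saturated) fit: independent cell means maximize it exactly
  cell_sets <- list(tnf_e = tnf_e, act_e = act_e, tnf_l = tnf_l, act_l = act_l)
  fits <- lapply(cell_sets, function(s)
    nb_group_mean(Y[, s, drop = FALSE], sf_sub[s], k))
  ll_alt <- Reduce(`+`, lapply(fits, `[[`, "loglik"))
  beta_delta <- log(fits$act_l$q / fits$tnf_l$q) -
    log(fits$act_e$q / fits$tnf_e$q)

  # null model: shared time effect, no chase-by-time interaction
  arm_actd <- as.numeric(sub_sheet$arm == "TNF_ACTD")
  late <- as.numeric(sub_sheet$time_h == late_h)
  X0 <- cbind(tnf = 1 - arm_actd, actd = arm_actd, late = late)
  fit0 <- nb_glm_rows(Y, X0, k, log(sf_sub))

  test <- lrt(list(loglik = fit0$loglik, df = 3L),
              list(loglik = ll_alt, df = 4L))
  flag <- ifelse(!fit0$converged, "nonconvergent",
                 ifelse(test$flagged, "negative_lrt", ""))
  ok <- flag == ""
  p <- ifelse(ok, test$p, NA_real_)
  padj <- rep(NA_real_, length(p))
  padj[ok] <- bh_adjust(p[ok])

  s_early <- (rowMeans(norm[keep, act_e, drop = FALSE]) + 0.5) /
    (rowMeans(norm[keep, tnf_e, drop = FALSE]) + 0.5)
  s_late <- (rowMeans(norm[keep, act_l, drop = FALSE]) + 0.5) /
    (rowMeans(norm[keep, tnf_l, drop = FALSE]) + 0.5)
  degree <- log2(s_late / s_early)

  direction <- rep("unchanged", sum(keep))
  direction[ok & padj < alpha & degree > 0] <- "stabilized"
  direction[ok & padj < alpha & degree < 0] <- "destabilized"

  out <- data.frame(gene_id = rownames(counts)[keep],
                    beta_delta = beta_delta,
                    stabilization_degree = degree,
                    loglik_null = fit0$loglik, loglik_alt = ll_alt,
                    stat = test$stat, pvalue = p, padj = padj,
                    direction = direction, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "early_h") <- early_h
  attr(out, "late_h") <- late_h
  rownames(out) <- NULL
  out
}

#' Rank genes by stabilization degree
#'
#' Sorts a differential-stabilization table by decreasing stabilization
#' degree, breaking ties by ascending adjusted p-value and then gene id.
#'
#' @param results output of [differential_stability_test()].
#' @param top_n number of rows to return; if larger than the table a warning
#'   is issued and the full table returned.
#' @return the top `top_n` rows, re-ranked.
#' @export
rank_stabilized <- function(results, top_n = 40L) {
  o <- order(-results$stabilization_degree, results$padj, results$gene_id)
  out <- results[o, , drop = FALSE]
  if (top_n > nrow(out)) {
    warning("top_n = ", top_n, " exceeds table size ", nrow(out),
            "; returning all rows")
    top_n <- nrow(out)
  }
  out <- out[seq_len(top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
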