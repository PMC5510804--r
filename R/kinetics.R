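# TNF-induction testing, temporal-switch stability summaries,
# expression-stability association and hierarchical clustering of induction
# kinetics.

#' TNF induction test at one time point
#'
#' Two-group NB likelihood-ratio test (df = 1) of the TNF arm at `time_h`
#' against the unstimulated control libraries (time 0). Fold changes are
#' computed from mean normalized counts with pseudocount 0.5. The induced
#' flags are purely fold-change based (>= 2-fold, >= 5-fold); the
#' `significant` column carries the BH-adjusted p < `alpha` call so callers
#' can require both.
#'
#' @inheritParams actd_response_test
#' @return data.frame with `mean_ctrl`, `mean_tnf`, `log2fc` (TNF over
#'   control), `stat`, `pvalue`, `padj`, `significant`, `induced_2fold`,
#'   `induced_5fold`.
#' @export
tnf_induction_test <- function(counts, sheet, time_h, min_counts = 100,
                               alpha = 0.1, sf = NULL, dispersion = NULL) {
  counts <- validate_counts(counts)
  sheet <- match_sheet(counts, sheet)
  if (is.null(sf)) sf <- size_factors(counts)
  ctrl <- sheet$arm == "CONTROL"
  tnf <- sheet$arm == "TNF" & sheet$time_h == time_h
  if (!any(ctrl)) stop("no CONTROL (unstimulated) samples in the design")
  if (!any(tnf)) stop("no TNF samples at time ", time_h, " h")
  keep <- rowSums(counts[, tnf, drop = FALSE]) > min_counts
  if (!any(keep)) stop("no gene passes the >", min_counts, " count filter")
  out <- two_group_test_core(counts, sheet, ctrl, tnf, "CONTROL", "TNF",
                             keep, sf, dispersion, alpha)
  names(out)[names(out) == "mean1"] <- "mean_ctrl"
  names(out)[names(out) == "mean2"] <- "mean_tnf"
  out$induced_2fold <- out$log2fc >= 1
  out$induced_5fold <- out$log2fc >= log2(5)
  out$time_h <- time_h
  out
}

#' Stability distribution of TNF-induced genes (temporal switch)
#'
#' Bins the stability ratios of the genes induced at least `fold_threshold`
#' fold at a time point, the summary behind the early-unstable /
#' late-stable temporal switch.
#'
#' @param induction induction table from [tnf_induction_test()].
#' @param stability stability table from [stability_ratio()] at the same
#'   time point.
#' @param fold_threshold minimal induction fold (default 2).
#' @param n_bins number of equal-width bins over \[0, 1\] (default 20).
#' @param require_significant also require the BH-adjusted induction call.
#' @return list with `n` (induced genes with a stability call), `breaks`,
#'   `counts`, `density`, `frac_class1`, `frac_class5`, `gene_id`.
#' @export
temporal_switch_density <- function(induction, stability, fold_threshold = 2,
                                    n_bins = 20L, require_significant = FALSE) {
  induced <- induction$log2fc >= log2(fold_threshold)
  if (require_significant) induced <- induced & induction$significant
  ids <- induction$gene_id[induced]
  st <- stability[match(ids, stability$gene_id), ]
  st <- st[!is.na(st$S) & !st$excluded, , drop = FALSE]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  if (!nrow(st)) {
    warning("no induced genes with a stability call")
    return(list(n = 0L, breaks = breaks, counts = rep(0L, n_bins),
                density = rep(NA_real_, n_bins), frac_class1 = NA_real_,
                frac_class5 = NA_real_, gene_id = character(0)))
  }
  h <- graphics::hist(st$S, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(n = nrow(st), breaks = breaks, counts = h$counts,
       density = h$counts / nrow(st) * n_bins,
       frac_class1 = mean(st$stability_class == 1),
       frac_class5 = mean(st$stability_class == 5),
       gene_id = st$gene_id)
}

#' Stability composition of the most highly expressed genes
#'
#' Ranks genes by their TNF-arm mean expression at a time point, takes the
#' top fraction and reports the stability-class composition of that set,
#' together with the unstable members (classes 1-2) and their expression
#' ranks.
#'
#' @param expr expression matrix (RPKM or normalized counts).
#' @param stability stability table at the same time point.
#' @param sheet sample sheet covering `expr`.
#' @param time_h stimulation time.
#' @param top_fraction fraction of ranked genes to keep (default 0.10);
#'   `ceiling(top_fraction * n)` genes are taken. Ties are broken by gene id.
#' @return list with `top` (gene, expression, rank, class), `composition`
#'   (five-class fractions of the top set) and `unstable` (class 1-2 members).
#' @export
top_expressed_stability <- function(expr, stability, sheet, time_h,
                                    top_fraction = 0.10) {
  sheet <- match_sheet(expr, sheet)
  tnf <- sheet$arm == "TNF" & sheet$time_h == time_h
  if (!any(tnf)) stop("no TNF samples at time ", time_h, " h")
  level <- rowMeans(expr[, tnf, drop = FALSE])
  st <- stability[!stability$excluded & !is.na(stability$stability_class), ]
  ids <- intersect(rownames(expr), st$gene_id)
  if (!length(ids)) stop("no genes with both expression and a stability call")
  lev <- level[ids]
  o <- order(-lev, ids)
  n_top <- ceiling(top_fraction * length(ids))
  top_ids <- ids[o][seq_len(n_top)]
  cls <- st$stability_class[match(top_ids, st$gene_id)]
  top <- data.frame(gene_id = top_ids, expression = lev[top_ids],
                    rank = seq_len(n_top), stability_class = cls,
                    stringsAsFactors = FALSE)
  list(top = top,
       composition = stabilome_composition(cls),
       unstable = top[top$stability_class <= 2, , drop = FALSE])
}

#' Mean normalized time-course profiles
#'
#' Builds the per-gene expression time course used for kinetic clustering:
#' mean normalized counts of the unstimulated controls at 0 h and of the TNF
#' arm at each later time point.
#'
#' @param counts,sheet count matrix and sample sheet.
#' @param sf optional size factors.
#' @param genes optional subset of gene ids (default all).
#' @return numeric matrix genes x time points, columns named by time.
#' @export
kinetic_profiles <- function(counts, sheet, sf = NULL, genes = NULL) {
  counts <- validate_counts(counts)
  sheet <- match_sheet(counts, sheet)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  if (!is.null(genes)) norm <- norm[genes, , drop = FALSE]
  times <- sort(unique(sheet$time_h))
  prof <- vapply(times, function(t) {
    sel <- if (t == 0) sheet$arm == "CONTROL" & sheet$time_h == 0
           else sheet$arm == "TNF" & sheet$time_h == t
    if (!any(sel)) return(rep(NA_real_, nrow(norm)))
    rowMeans(norm[, sel, drop = FALSE])
  }, numeric(nrow(norm)))
  prof <- matrix(prof, nrow = nrow(norm),
                 dimnames = list(rownames(norm), times))
  prof[, colSums(is.na(prof)) == 0, drop = FALSE]
}

#' Hierarchical clustering of induction kinetics
#'
#' Rows are z-scored across time so that profile shape rather than magnitude
#' drives the grouping; distance is 1 - Pearson correlation with average
#' linkage, and the tree is cut at `k` clusters. Clusters are renumbered by
#' the peak time of their mean profile (earliest peak = cluster 1), which
#' makes labels invariant to gene order.
#'
#' @param profiles numeric matrix genes x time points (e.g. from
#'   [kinetic_profiles()]); rows with zero variance are dropped with a
#'   warning.
#' @param k number of clusters (default 6).
#' @return list of class `kinetic_clusters` with `labels` (named integer
#'   vector), `k`, `centroids` (k x times mean z-profiles), `hclust`.
#' @export
cluster_kinetics <- function(profiles, k = 6L) {
  profiles <- as.matrix(profiles)
  sds <- apply(profiles, 1, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warning(sum(flat), " constant profile(s) dropped before clustering")
    profiles <- profiles[!flat, , drop = FALSE]
  }
  if (nrow(profiles) < k)
    stop("fewer genes (", nrow(profiles), ") than clusters (", k, ")")
  z <- t(scale(t(profiles)))
  if (k == 1) {
    labels <- stats::setNames(rep(1L, nrow(z)), rownames(z))
    cent <- matrix(colMeans(z), 1, ncol(z),
                   dimnames = list(1, colnames(profiles)))
    return(structure(list(labels = labels, k = 1L, centroids = cent,
                          hclust = NULL), class = "kinetic_clusters"))
  }
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  cent <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(z[raw == cl, , drop = FALSE])))
  peak <- apply(cent, 1, which.max)
  tt <- as.numeric(colnames(profiles))
  # earliest peak first; ties broken by the profile's time centroid
  wmean <- apply(cent - apply(cent, 1, min), 1,
                 function(w) sum(w * tt) / sum(w))
  new_order <- order(peak, wmean)
  relabel <- match(seq_len(k), new_order)
  labels <- stats::setNames(relabel[raw], rownames(z))
  cent <- cent[new_order, , drop = FALSE]
  rownames(cent) <- seq_len(k)
  colnames(cent) <- colnames(profiles)
  structure(list(labels = labels, k = as.integer(k), centroids = cent,
                 hclust = hc), class = "kinetic_clusters")
}

#' @export
print.kinetic_clusters <- function(x, ...) {
  cat("kinetic_clusters: ", length(x$labels), " genes in ", x$k,
      " clusters\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Stability composition per kinetic cluster
#'
#' @param clusters `kinetic_clusters` object.
#' @param stability stability table at the time point of interest.
#' @param groups optional list of cluster-label vectors to merge before
#'   summarizing (e.g. `list("1" = 1, "2&3" = c(2, 3))`); defaults to one
#'   group per cluster.
#' @return data.frame with `group`, `class`, `count`, `fraction` (fractions
#'   sum to 1 within each group).
#' @export
cluster_stability_composition <- function(clusters, stability, groups = NULL) {
  if (is.null(groups)) {
    groups <- as.list(seq_len(clusters$k))
    names(groups) <- as.character(seq_len(clusters$k))
  }
  st_cls <- stability$stability_class[match(names(clusters$labels),
                                            stability$gene_id)]
  missing <- is.na(st_cls)
  if (any(missing))
    warning(sum(missing), " clustered gene(s) without a stability call ",
            "excluded")
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    in_grp <- clusters$labels %in% groups[[gname]] & !missing
    if (!any(in_grp)) return(NULL)
    comp <- stabilome_composition(st_cls[in_grp])
    cbind(group = gname, comp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
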