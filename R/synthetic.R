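# Synthetic ActD-chase RNA-seq generator with known per-gene induction
# kinetics, first-order decay rates and NB dispersion, emulating a
# two-replicate TNF time-course design with a 3 h chase arm per time point.

ARCHETYPES <- c("early_transient", "intermediate", "late_sustained",
                "constitutive", "silent")

# base induction folds at times 0, 1, 3, 24, 72 h
ARCH_FOLDS <- list(
  early_transient = c(1, 16, 6, 1.5, 1),
  intermediate    = c(1, 1.5, 3, 8, 1.8),
  late_sustained  = c(1, 1.2, 2, 5, 10),
  constitutive    = c(1, 1, 1, 1, 1),
  silent          = c(1, 1, 1, 1, 1))

# base stability ratios over the same times (exp(-lambda * t_chase));
# stabilized early-transient genes progress from unstable to very stable
ARCH_S <- list(
  early_transient            = c(0.1, 0.1, 0.1, 0.1, 0.1),
  early_transient_stabilized = c(0.1, 0.1, 0.2, 0.5, 0.8),
  intermediate               = c(0.5, 0.5, 0.5, 0.5, 0.5),
  late_sustained             = c(0.9, 0.9, 0.9, 0.9, 0.9))

# stability-class mixture for background (constitutive / silent) genes:
# most expressed transcripts are very stable
BACKGROUND_CLASS_MIX <- c(0.05, 0.05, 0.10, 0.15, 0.65)

#' Generate a synthetic ground-truth table
#'
#' Draws per-gene generative parameters: basal mean expression (log-uniform),
#' NB dispersion from a mean-dispersion trend `a0 + a1 / mean` with
#' log-normal noise, archetype-specific induction folds and first-order
#' decay rates. A configurable fraction of early-transient genes receives
#' TNF-induced stabilization (stability ratio rising from 0.1 to 0.8 across
#' the time course). Background (constitutive) genes draw a constant
#' stability from a class mixture dominated by very stable transcripts.
#'
#' @param n_genes number of genes.
#' @param mixture named archetype fractions summing to 1. Default:
#'   early_transient 0.10, intermediate 0.10, late_sustained 0.15,
#'   constitutive 0.60, silent 0.05.
#' @param frac_stabilized fraction of early-transient genes that get
#'   TNF-induced stabilization (default 0.5).
#' @param times TNF stimulation times in hours (default 0, 1, 3, 24, 72).
#' @param t_chase chase duration in hours (default 3).
#' @param basal_range range of basal mean normalized counts, drawn
#'   log-uniformly (default 5 to 5000).
#' @param disp_trend coefficients `c(a0, a1)` of the dispersion trend
#'   (default 0.01 and 2).
#' @param disp_noise_sd log-normal noise sd around the trend (default 0.3).
#' @param s_jitter_sd log-normal jitter applied to decay rates (default
#'   0.15; 0 for exact archetype stabilities).
#' @param seed optional random seed.
#' @return data.frame of class `synthetic_truth` with columns `gene_id`,
#'   `archetype`, `stabilized`, `basal_mean`, `dispersion`, `fold_<t>` and
#'   `lambda_<t>` per time; attributes `times`, `t_chase`.
#' @export
make_truth <- function(n_genes,
                       mixture = c(early_transient = 0.10,
                                   intermediate = 0.10,
                                   late_sustained = 0.15,
                                   constitutive = 0.60,
                                   silent = 0.05),
                       frac_stabilized = 0.5,
                       times = c(0, 1, 3, 24, 72), t_chase = 3,
                       basal_range = c(5, 5000),
                       disp_trend = c(a0 = 0.01, a1 = 2),
                       disp_noise_sd = 0.3, s_jitter_sd = 0.15,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(names(mixture)) || !all(names(mixture) %in% ARCHETYPES))
    stop("mixture must be named with archetypes: ",
         paste(ARCHETYPES, collapse = ", "))
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    stop("mixture fractions must be non-negative and sum to 1")
  times <- sort(unique(times))
  if (any(times < 0)) stop("times must be non-negative")

  # deterministic largest-remainder allocation of genes to archetypes
  target <- mixture * n_genes
  n_arch <- floor(target)
  rem <- n_genes - sum(n_arch)
  if (rem > 0) {
    o <- order(target - n_arch, decreasing = TRUE)
    n_arch[o[seq_len(rem)]] <- n_arch[o[seq_len(rem)]] + 1
  }
  archetype <- rep(names(mixture), n_arch)

  width <- max(5, nchar(n_genes))
  gene_id <- sprintf("gene%0*d", width, seq_len(n_genes))
  basal <- exp(stats::runif(n_genes, log(basal_range[1]), log(basal_range[2])))
  basal[archetype == "silent"] <- stats::runif(sum(archetype == "silent"),
                                               0, 0.5)
  disp <- (disp_trend[1] + disp_trend[2] / pmax(basal, 0.5)) *
    stats::rlnorm(n_genes, meanlog = -disp_noise_sd^2 / 2, sd = disp_noise_sd)

  nt <- length(times)
  folds <- matrix(1, n_genes, nt)
  lambdas <- matrix(0, n_genes, nt)
  stabilized <- rep(FALSE, n_genes)
  et <- which(archetype == "early_transient")
  if (length(et) && frac_stabilized > 0)
    stabilized[et[seq_len(round(frac_stabilized * length(et)))]] <- TRUE

  jit <- if (s_jitter_sd > 0)
    stats::rlnorm(n_genes, 0, s_jitter_sd) else rep(1, n_genes)
  for (g in seq_len(n_genes)) {
    a <- archetype[g]
    folds[g, ] <- approx_profile(ARCH_FOLDS[[a]], times)
    s_base <- if (a == "early_transient" && stabilized[g])
      ARCH_S[["early_transient_stabilized"]]
    else if (a %in% names(ARCH_S)) ARCH_S[[a]]
    else {  # background: constant stability drawn from the class mixture
      cls <- sample.int(5, 1, prob = BACKGROUND_CLASS_MIX)
      rep(stats::runif(1, (cls - 1) / 5, cls / 5), 5)
    }
    s <- approx_profile(s_base, times)
    s <- pmax(s, 1e-6)
    lambdas[g, ] <- -log(s) / t_chase * jit[g]
  }
  colnames(folds) <- paste0("fold_", times)
  colnames(lambdas) <- paste0("lambda_", times)

  out <- data.frame(gene_id = gene_id, archetype = archetype,
                    stabilized = stabilized, basal_mean = basal,
                    dispersion = disp, folds, lambdas,
                    stringsAsFactors = FALSE)
  attr(out, "times") <- times
  attr(out, "t_chase") <- t_chase
  class(out) <- c("synthetic_truth", "data.frame")
  out
}

# interpolate a 5-point archetype profile onto arbitrary times (log-time)
approx_profile <- function(base, times) {
  ref <- c(0, 1, 3, 24, 72)
  if (length(times) == 5 && all(times == ref)) return(base)
  stats::approx(log1p(ref), base, xout = log1p(times), rule = 2)$y
}

#' Simulation design for the chase experiment
#'
#' @param times stimulation times (hours); time 0 carries the unstimulated
#'   controls, each later time a TNF arm and a TNF+ActD chase arm.
#' @param t_chase chase duration in hours.
#' @param reps biological replicates per design cell (default 2).
#' @param sf per-sample size factors; drawn log-normally (sd 0.1, geometric
#'   mean 1) when NULL.
#' @param leakage fraction of transcription continuing during the chase
#'   (default 0 = complete shutoff).
#' @param seed random seed; fully determines the simulated dataset.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(times = c(0, 1, 3, 24, 72), t_chase = 3, reps = 2L,
                       sf = NULL, leakage = 0, seed = 1L) {
  if (reps < 1) stop("reps must be >= 1")
  if (leakage < 0 || leakage > 1) stop("leakage must be in [0, 1]")
  structure(list(times = times, t_chase = t_chase, reps = as.integer(reps),
                 sf = sf, leakage = leakage, seed = seed),
            class = "sim_design")
}

#' Simulate an ActD-chase count dataset from a truth table
#'
#' Expected TNF-arm counts are `size_factor * basal_mean * fold(t)`; chase
#' arm counts are the TNF-arm expectation times
#' `(1 - leakage) * exp(-lambda(t) * t_chase) + leakage`. Counts are drawn
#' NB with the per-gene dispersion (Poisson when the dispersion is 0). The
#' seed in the design fully determines the output.
#'
#' @param truth `synthetic_truth` table from [make_truth()].
#' @param design `sim_design` object.
#' @return list with `counts` (integer matrix), `sheet` (sample sheet),
#'   `sf` (size factors used).
#' @export
simulate_counts <- function(truth, design = sim_design()) {
  if (!inherits(truth, "synthetic_truth"))
    stop("truth must come from make_truth()")
  if (!inherits(design, "sim_design")) stop("design must be a sim_design")
  times <- design$times
  ttimes <- attr(truth, "times")
  if (!all(times %in% ttimes))
    stop("design times must be a subset of the truth's times")
  if (!is.null(design$seed)) set.seed(design$seed)

  rows <- list()
  for (t in times) {
    if (t == 0) {
      for (r in seq_len(design$reps))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("ctrl_0h_r%d", r), time_h = 0,
          arm = "CONTROL", replicate = r, stringsAsFactors = FALSE)
    } else {
      for (arm in c("TNF", "TNF_ACTD")) for (r in seq_len(design$reps))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%gh_r%d",
                              if (arm == "TNF") "tnf" else "actd", t, r),
          time_h = t, arm = arm, replicate = r, stringsAsFactors = FALSE)
    }
  }
  sheet <- validate_sample_sheet(do.call(rbind, rows))
  n_s <- nrow(sheet)
  sf <- design$sf
  if (is.null(sf)) {
    sf <- stats::rlnorm(n_s, 0, 0.1)
    sf <- sf / exp(mean(log(sf)))
  }
  sf <- rep_len(sf, n_s)
  if (any(sf <= 0)) stop("size factors must be positive")

  G <- nrow(truth)
  mu <- matrix(0, G, n_s)
  for (j in seq_len(n_s)) {
    t <- sheet$time_h[j]
    ti <- match(t, ttimes)
    fold <- if (sheet$arm[j] == "CONTROL") 1 else truth[[paste0("fold_", t)]]
    base <- truth$basal_mean * fold
    if (sheet$arm[j] == "TNF_ACTD") {
      s <- exp(-truth[[paste0("lambda_", t)]] * design$t_chase)
      base <- base * ((1 - design$leakage) * s + design$leakage)
    }
    mu[, j] <- sf[j] * base
  }
  counts <- matrix(0L, G, n_s,
                   dimnames = list(truth$gene_id, sheet$sample_id))
  pois <- truth$dispersion <= 0
  for (j in seq_len(n_s)) {
    col <- integer(G)
    if (any(pois)) col[pois] <- stats::rpois(sum(pois), mu[pois, j])
    if (any(!pois))
      col[!pois] <- stats::rnbinom(sum(!pois),
                                   size = 1 / truth$dispersion[!pois],
                                   mu = mu[!pois, j])
    counts[, j] <- col
  }
  list(counts = validate_counts(counts), sheet = sheet,
       sf = stats::setNames(sf, sheet$sample_id))
}

#' Ground-truth stability ratios
#'
#' `S_true(t) = exp(-lambda(t) * t_chase)`, adjusted for transcription
#' leakage when the design specifies any.
#'
#' @param truth `synthetic_truth` table.
#' @param design optional `sim_design` (for `t_chase` and `leakage`);
#'   defaults to the chase duration stored in the truth and zero leakage.
#' @return numeric matrix genes x times of true stability ratios.
#' @export
expected_stability <- function(truth, design = NULL) {
  t_chase <- if (is.null(design)) attr(truth, "t_chase") else design$t_chase
  leak <- if (is.null(design)) 0 else design$leakage
  times <- attr(truth, "times")
  s <- vapply(times, function(t)
    (1 - leak) * exp(-truth[[paste0("lambda_", t)]] * t_chase) + leak,
    numeric(nrow(truth)))
  s <- matrix(s, nrow = nrow(truth),
              dimnames = list(truth$gene_id, times))
  s
}

#' Write a truth table as TSV
#' @param truth `synthetic_truth` table.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
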