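# Independent oracles and small fixture builders shared across tests.

# adjusted Rand index, from the contingency-table definition
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force BH step-up: adj_i = min over j with p_(j) >= p_(i) of m p_(j)/j
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)
    adj[i] <- min(1, min(m * p[ord][r:m] / (r:m)))
  }
  adj
}

# numeric-search oracle for the NB GLM MLE: Nelder-Mead then BFGS on the
# log-likelihood, independent of the IRLS code path
nb_glm_oracle <- function(y, X, k, offset = 0) {
  offset <- rep_len(offset, length(y))
  nll <- function(b)
    -sum(dnbinom(y, size = 1 / k,
                 mu = exp(pmin(drop(X %*% b) + offset, 30)), log = TRUE))
  b0 <- qr.coef(qr(X), log(pmax(y, 0.5)) - offset)
  b0[is.na(b0)] <- 0
  o <- optim(b0, nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  o <- optim(o$par, nll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  list(coef = o$par, loglik = -o$value)
}

# design matrices of the dependent-ratio model (4 cells x 2 reps)
diffstab_design <- function() {
  X0 <- cbind(tnf = c(1, 1, 0, 0, 1, 1, 0, 0),
              actd = c(0, 0, 1, 1, 0, 0, 1, 1),
              late = c(0, 0, 0, 0, 1, 1, 1, 1))
  list(null = X0, alt = cbind(X0, delta = c(0, 0, 0, 0, 0, 0, 1, 1)))
}

# small deterministic count matrix + sheet fixture
tiny_dataset <- function(seed = 1, n_genes = 60, times = c(0, 1, 72),
                         basal_range = c(50, 2000)) {
  truth <- make_truth(n_genes, mixture = c(constitutive = 1),
                      basal_range = basal_range, seed = seed)
  sim <- simulate_counts(truth, sim_design(times = times, seed = seed + 1000))
  c(sim, list(truth = truth))
}
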