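# shared fixtures, all generated in code

# small generator config: informative analytes among a reduced panel,
# all other generator parameters at their defaults
small_config <- function(n = 300, p_prot = 20, p_met = 10, seed = 1, ...) {
  generator_config(n_subjects = n, n_protein_analytes = p_prot,
                   n_metabolite_analytes = p_met, seed = seed, ...)
}

# a QC'd, imputed training cohort ready for modeling
make_training_cohort <- function(n = 300, p_prot = 20, p_met = 10, seed = 1, ...) {
  co <- generate_cohort(small_config(n, p_prot, p_met, seed, ...))
  parts <- split_cohorts(co)
  qc_cohort(parts$training, qc_config(impute_seed = seed))$cohort
}

# correlated-block matrix: `blocks` groups of equally correlated columns
make_block_matrix <- function(n = 300, p = 30, blocks = 6, rho = 0.8, seed = 1) {
  stopifnot(p %% blocks == 0)
  per <- p / blocks
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    cols <- lapply(seq_len(blocks), function(b) {
      shared <- rnorm(n)
      sapply(seq_len(per), function(j)
        sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n))
    })
    x <- do.call(cbind, cols)
    colnames(x) <- paste0("V", seq_len(p))
    x
  })
}

# mask a fraction of cells MCAR; returns the masked matrix and the mask
mask_cells <- function(x, frac = 0.1, seed = 1) {
  set.seed(seed)
  mask <- matrix(runif(length(x)) < frac, nrow(x), ncol(x))
  xm <- x
  xm[mask] <- NA
  list(masked = xm, mask = mask)
}

# exhaustive all-pairs AUC oracle with half credit for ties
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == "abnormal"]
  neg <- scores[labels != "abnormal"]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# exhaustive cutpoint oracle: scan every candidate threshold directly
cutoff_scan_oracle <- function(levels, status, criterion) {
  u <- sort(unique(levels))
  cand <- if (length(u) == 1) u else c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  pos <- status == "abnormal"
  vals <- sapply(cand, function(t) {
    pred <- levels < t
    tp <- sum(pred & pos); fn <- sum(!pred & pos)
    fp <- sum(pred & !pos); tn <- sum(!pred & !pos)
    se <- tp / (tp + fn); sp <- tn / (tn + fp)
    acc <- (tp + tn) / length(pos)
    po <- acc
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / length(pos)^2
    kap <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
    switch(criterion,
           Youden = se + sp - 1,
           ROC01 = (1 - se)^2 + (1 - sp)^2,
           MaxSpSe = min(se, sp),
           MaxProdSpSe = se * sp,
           MaxEfficiency = acc,
           MaxKappa = kap)
  })
  best <- if (criterion == "ROC01") min(vals) else max(vals)
  list(value = best, thresholds = cand[vals == best])
}

# Breslow partial likelihood for a single binary covariate, for brute-force
# maximization in tests
breslow_loglik <- function(beta, time, event, z) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(z[d]) -
      length(d) * log(sum(exp(beta * z[risk])))
  }
  ll
}
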