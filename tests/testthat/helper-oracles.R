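# Independent reference implementations used as test oracles. These are
# deliberately written with naive, step-by-step code (apply loops, explicit
# tabulations, grid searches) and never call the package's own routines.

# Alternating median sweeps for the additive two-way model, implemented
# with apply() column by column / row by row (samples swept first).
oracle_median_polish <- function(x, tol = 1e-6, max_iter = 10L) {
  z <- as.matrix(x)
  row_eff <- numeric(nrow(z))
  col_eff <- numeric(ncol(z))
  for (it in seq_len(max_iter)) {
    cm_ <- apply(z, 2, median)
    for (j in seq_len(ncol(z))) z[, j] <- z[, j] - cm_[j]
    col_eff <- col_eff + cm_
    rm_ <- apply(z, 1, median)
    for (i in seq_len(nrow(z))) z[i, ] <- z[i, ] - rm_[i]
    row_eff <- row_eff + rm_
    if (max(abs(rm_), abs(cm_)) < tol) break
  }
  shift <- median(row_eff)
  list(row_eff = unname(row_eff - shift), col_eff = unname(col_eff + shift),
       residuals = z)
}

# Per-gene FIRMA scores computed the long way: explicit loops over probe
# sets and samples on top of the polish oracle.
oracle_firma_gene <- function(x, probe_sets, mad_floor = 1e-6) {
  fit <- oracle_median_polish(x)
  r <- fit$residuals
  s <- max(1.4826 * median(abs(r)), mad_floor)
  sets <- unique(probe_sets)
  out <- matrix(NA_real_, length(sets), ncol(x), dimnames = list(sets, colnames(x)))
  for (j in seq_along(sets)) {
    for (k in seq_len(ncol(x))) {
      out[j, k] <- median(r[probe_sets == sets[j], k]) / s
    }
  }
  out
}

# Pearson correlation via the explicit covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Pooled-variance two-sample t statistic.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Log-rank statistic by explicit O/E/V tabulation over event times.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Cox partial log-likelihood for a single covariate, no tied event times,
# and its maximizer found by a two-stage grid search.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, lim = 5) {
  grid <- seq(-lim, lim, by = 0.01)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1), time = time, event = event, x = x)
  fine[which.max(llf)]
}

# Rank-based AUC cross-check.
oracle_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Small deterministic fixtures -------------------------------------------

toy_chipdef <- function() {
  new_chipdef(tibble::tibble(
    probe_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8"),
    probe_set_id = c("E1", "E1", "E2", "E2", "E3", "E3", "E4", "E4"),
    gene_id = c("GA", "GA", "GA", "GA", "GB", "GB", "GB", "GB")
  ))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
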