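# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written with naive loops and, where possible, on a
# different algebraic route than the package code.

# Radius of gyration via the pairwise identity
# Rg^2 = sum_ij m_i m_j |r_i - r_j|^2 / (2 M^2)  — no centroid computed.
oracle_rgyr <- function(coords, masses = rep(1, nrow(coords))) {
  M <- sum(masses)
  acc <- 0
  for (i in seq_len(nrow(coords))) for (j in seq_len(nrow(coords))) {
    d <- coords[i, ] - coords[j, ]
    acc <- acc + masses[i] * masses[j] * sum(d * d)
  }
  sqrt(acc / (2 * M^2))
}

# Levene/Brown-Forsythe W from the textbook formula.
oracle_levene <- function(groups, center = mean) {
  k <- length(groups)
  N <- sum(lengths(groups))
  Z <- lapply(groups, function(g) abs(g - center(g)))
  Zbar_i <- vapply(Z, mean, numeric(1))
  Zbar <- mean(unlist(Z))
  num <- sum(lengths(groups) * (Zbar_i - Zbar)^2) / (k - 1)
  den <- sum(vapply(Z, function(z) sum((z - mean(z))^2), numeric(1))) / (N - k)
  W <- num / den
  list(W = W, p = stats::pf(W, k - 1, N - k, lower.tail = FALSE))
}

# Full ranking pipeline evaluated with explicit loops on a log10 IC50 matrix
# (rows compounds, cols enzymes, NA = no readout). Imputation z = 2,
# readout-count weights, weighted mean divided by panel_size.
oracle_rank <- function(logic50, panel_size = ncol(logic50), impute_z = 2) {
  n_c <- nrow(logic50); n_e <- ncol(logic50)
  z <- matrix(NA_real_, n_c, n_e, dimnames = dimnames(logic50))
  N <- integer(n_e)
  for (e in seq_len(n_e)) {
    vals <- c()
    for (c_ in seq_len(n_c)) if (!is.na(logic50[c_, e])) vals <- c(vals, logic50[c_, e])
    N[e] <- length(vals)
    xbar <- sum(vals) / length(vals)
    s <- sqrt(sum((vals - xbar)^2) / (length(vals) - 1))
    for (c_ in seq_len(n_c))
      z[c_, e] <- if (is.na(logic50[c_, e])) impute_z else (logic50[c_, e] - xbar) / s
  }
  w <- numeric(n_e)
  for (e in seq_len(n_e)) w[e] <- N[e] / sum(N)
  zbar <- numeric(n_c)
  for (c_ in seq_len(n_c)) {
    acc <- 0
    for (e in seq_len(n_e)) acc <- acc + w[e] * z[c_, e]
    zbar[c_] <- acc / panel_size
  }
  names(zbar) <- rownames(logic50)
  list(z = z, w = w, N = N, zbar = zbar,
       order = rownames(logic50)[order(zbar, rownames(logic50))])
}

# Random log10 IC50 matrix with missing entries; every enzyme keeps >= 2
# successful readouts.
random_logic50_panel <- function(n_compounds = 58, n_enzymes = 7, p_missing = 0.5) {
  m <- matrix(stats::rnorm(n_compounds * n_enzymes, -6, 1), n_compounds, n_enzymes,
              dimnames = list(sprintf("C%02d", 1:n_compounds),
                              sprintf("E%d", 1:n_enzymes)))
  miss <- matrix(stats::runif(length(m)) < p_missing, nrow(m))
  for (e in seq_len(n_enzymes)) {   # guarantee a defined scale per enzyme
    keep <- which(!miss[, e])
    if (length(keep) < 2) miss[sample(n_compounds, 2), e] <- FALSE
  }
  m[miss] <- NA
  m
}

# Convert a log10 IC50 matrix into a minimal fits table for rank_compounds().
panel_to_fits <- function(logic50) {
  idx <- expand.grid(compound_id = rownames(logic50), enzyme_id = colnames(logic50),
                     stringsAsFactors = FALSE)
  idx$log10_ic50 <- logic50[cbind(idx$compound_id, idx$enzyme_id)]
  idx$ic50 <- 10^idx$log10_ic50
  idx$category <- ifelse(is.na(idx$log10_ic50), "BASELINE", "IN_RANGE")
  idx
}
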