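# Independent oracles used across the test files. These deliberately share
# no code with the package internals: the GEE oracle builds every
# cluster-sized matrix explicitly and solves with dense linear algebra; the
# Robson oracle encodes each of the ten groups as a full positive predicate
# and checks they tile the covariate space.

# ---- dense GEE oracle -------------------------------------------------

# Fisher scoring on the GEE score equations with explicit per-cluster
# covariance matrices V_i = phi * A^(1/2) R(alpha) A^(1/2).
dense_gee_oracle <- function(y, X, id, family = c("poisson_log", "gaussian_identity"),
                             corstr = c("exchangeable", "independence"),
                             tol = 1e-12, maxit = 200) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  id <- droplevels(factor(id))
  p <- ncol(X)
  pois <- family == "poisson_log"
  groups <- split(seq_along(y), id)
  n_i <- lengths(groups)

  beta <- if (pois) qr.solve(X, log(pmax(y, 0.25))) else qr.solve(X, y)
  alpha <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- if (pois) exp(eta) else eta
    a <- if (pois) mu else rep(1, length(y))
    r <- (y - mu) / sqrt(a)
    phi <- mean(r^2)
    if (corstr == "exchangeable" && phi > 1e-12) {
      num <- 0; den <- 0
      for (g in groups) {
        rg <- r[g]
        num <- num + sum(outer(rg, rg))- sum(rg^2)
        den <- den + length(rg) * (length(rg) - 1)
      }
      alpha <- (num / den) / phi
      alpha <- min(max(alpha, -1 / (max(n_i) - 1) + 1e-8), 1 - 1e-8)
    }
    Amat <- matrix(0, p, p); U <- numeric(p)
    for (g in groups) {
      ng <- length(g)
      R <- matrix(alpha, ng, ng); diag(R) <- 1
      Ah <- diag(sqrt(a[g]), ng)
      Vi <- Ah %*% R %*% Ah
      Di <- if (pois) mu[g] * X[g, , drop = FALSE] else X[g, , drop = FALSE]
      Wi <- t(Di) %*% solve(Vi)
      Amat <- Amat + Wi %*% Di
      U <- U + Wi %*% (y[g] - mu[g])
    }
    step <- drop(solve(Amat, U))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  # final pieces at convergence
  eta <- drop(X %*% beta)
  mu <- if (pois) exp(eta) else eta
  a <- if (pois) mu else rep(1, length(y))
  r <- (y - mu) / sqrt(a)
  phi <- mean(r^2)
  if (corstr == "exchangeable" && phi > 1e-12) {
    num <- 0; den <- 0
    for (g in groups) {
      rg <- r[g]
      num <- num + sum(outer(rg, rg)) - sum(rg^2)
      den <- den + length(rg) * (length(rg) - 1)
    }
    alpha <- (num / den) / phi
    alpha <- min(max(alpha, -1 / (max(n_i) - 1) + 1e-8), 1 - 1e-8)
  } else if (corstr == "independence") alpha <- 0
  Amat <- matrix(0, p, p)
  cl <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    ng <- length(g)
    R <- matrix(alpha, ng, ng); diag(R) <- 1
    Ah <- diag(sqrt(a[g]), ng)
    Vi <- Ah %*% R %*% Ah
    Di <- if (pois) mu[g] * X[g, , drop = FALSE] else X[g, , drop = FALSE]
    cl[[k]] <- list(D = Di, Vinv = solve(Vi), e = y[g] - mu[g])
    Amat <- Amat + t(Di) %*% cl[[k]]$Vinv %*% Di
  }
  list(beta = drop(beta), alpha = alpha, phi = phi, Amat = Amat, clusters = cl)
}

# dense sandwich / Mancl-DeRouen from the oracle pieces
dense_sandwich_oracle <- function(or, kind = c("sandwich", "mancl_derouen")) {
  kind <- match.arg(kind)
  p <- nrow(or$Amat)
  B <- solve(or$Amat)
  M <- matrix(0, p, p)
  for (cl in or$clusters) {
    e <- cl$e
    if (kind == "mancl_derouen") {
      H <- cl$D %*% B %*% t(cl$D) %*% cl$Vinv
      e <- drop(solve(diag(length(e)) - H, e))
    }
    gvec <- drop(t(cl$D) %*% cl$Vinv %*% e)
    M <- M + tcrossprod(gvec)
  }
  B %*% M %*% B
}

# ---- Robson oracle ----------------------------------------------------

# WHO-manual groups, each written as a complete predicate on the profile.
# Returns the group number; asserts exactly one predicate fires.
robson_oracle <- function(parity, prev_cs, onset, pres, fetuses, ga, term_at = 37) {
  nulli <- parity == 0
  multi <- !nulli
  term <- ga >= term_at
  preds <- c(
    g1 = nulli && fetuses == 1 && term && pres == "cephalic" &&
      onset == "spontaneous",
    g2 = nulli && fetuses == 1 && term && pres == "cephalic" &&
      onset %in% c("induced", "prelabor_cesarean"),
    g3 = multi && prev_cs == 0 && fetuses == 1 && term && pres == "cephalic" &&
      onset == "spontaneous",
    g4 = multi && prev_cs == 0 && fetuses == 1 && term && pres == "cephalic" &&
      onset %in% c("induced", "prelabor_cesarean"),
    g5 = multi && prev_cs >= 1 && fetuses == 1 && term && pres == "cephalic",
    g6 = nulli && fetuses == 1 && pres == "breech",
    g7 = multi && fetuses == 1 && pres == "breech",
    g8 = fetuses >= 2,
    g9 = fetuses == 1 && pres == "transverse_oblique",
    g10 = fetuses == 1 && pres == "cephalic" && !term
  )
  # group 1/2 exclude previous cesarean by construction (nulliparous women
  # cannot have one); groups 6/7/9/10 include it, group 8 trumps everything
  stopifnot(sum(preds) == 1)
  which(preds)[[1]]
}

# ---- simulation config helper -----------------------------------------

# a generator configuration producing a pure Robson Group 1 cohort at a
# given control cesarean rate and relative risk (used by recovery and
# coverage checks)
group1_config <- function(seed, p0 = 0.40, rr = 1, m = 120, cv = 0.60,
                          icc = 0.02, cac = 0.90,
                          design = default_trial_design()) {
  generator_config(
    design = design, mean_cluster_period_size = m, cv_cluster_size = cv,
    p_nulliparous = 1,
    p_onset = c(spontaneous = 1, induced = 0, prelabor_cesarean = 0),
    p_presentation = c(cephalic = 1, breech = 0, transverse_oblique = 0),
    p_multiple = 0, ga_term_mean = 39, ga_term_sd = 0.8, p_early = 0,
    cs_baseline = stats::setNames(rep(p0, 10), as.character(1:10)),
    cesarean_rr = rr, icc = icc, cac = cac, seed = seed)
}

# generate, restrict to analyzable Group 1 records, add the treatment flag
group1_trial <- function(cfg) {
  d <- generate_trial(cfg)
  d <- d[d$robson_group == 1L & d$condition != "transition", , drop = FALSE]
  d$treatment <- as.integer(d$condition == "intervention")
  d
}

# empirical within-cluster-period and between-period correlation of a
# binary outcome from per-cell sums (pairwise moment estimator)
empirical_icc <- function(y, cluster, period) {
  cell <- interaction(cluster, period, drop = TRUE)
  S <- tapply(y, cell, sum)
  n <- tapply(y, cell, length)
  p <- mean(y)
  pair_mean <- sum(S^2 - S) / sum(n * (n - 1))
  within <- (pair_mean - p^2) / (p * (1 - p))
  # between-period: pairs of cells in the same cluster, different periods
  cl <- tapply(as.integer(cluster), cell, function(x) x[1])
  num <- 0; den <- 0
  for (k in unique(cl)) {
    Sk <- S[cl == k]; nk <- n[cl == k]
    num <- num + sum(outer(Sk, Sk)) - sum(Sk^2)
    den <- den + sum(outer(nk, nk)) - sum(nk^2)
  }
  between <- (num / den - p^2) / (p * (1 - p))
  c(within = within, between = between)
}

# the printed 12-row, 3-cluster toy dataset used for hand-checkable fits
toy_gee_data <- function() {
  data.frame(
    y       = c(1, 0, 1, 1,  0, 0, 1, 0,  1, 1, 0, 1),
    trt     = c(0, 0, 1, 1,  0, 0, 1, 1,  0, 1, 1, 1),
    period  = c(1, 2, 2, 3,  1, 2, 2, 3,  1, 1, 2, 3),
    cluster = c(1, 1, 1, 1,  2, 2, 2, 2,  3, 3, 3, 3))
}
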