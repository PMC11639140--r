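# Independent brute-force oracles, written term by term from the model
# equations; they share no code with the package's likelihood path.

# naive per-dimension disutility: explicit sums, no matrix tricks
oracle_disutility <- function(spec, coefs, levels) {
  a <- if (spec$tto_intercept) coefs[["alpha_tto"]] else 0
  d <- 0
  for (j in seq_along(dims_fx)) {
    l <- levels[j]
    if (l == 0) next
    d <- d + switch(spec$family,
      main = coefs[[paste0(dims_fx[j], ".l", l)]],
      linear = l * coefs[[dims_fx[j]]] / 7,
      cale = {
        m <- if (l == 7) 1 else coefs[[paste0("lvl.", l)]]
        m * coefs[[dims_fx[j]]]
      },
      calesep = {
        pre <- if (dims_fx[j] %in% sym_fx) "lvlS." else "lvlI."
        m <- if (l == 7) 1 else coefs[[paste0(pre, l)]]
        m * coefs[[dims_fx[j]]]
      })
  }
  a + d
}

# term-by-term censored normal log-likelihood
oracle_tto_loglik <- function(spec, coefs, tto, design) {
  ll <- 0
  for (i in seq_len(nrow(tto))) {
    row <- design[design$state_id == tto$state_id[i], ]
    mu <- oracle_disutility(spec, coefs, as.numeric(row[1, dims_fx]))
    sig <- if (spec$heteroscedastic)
      coefs[["alpha_sigma"]] + coefs[["beta_sigma"]] * mu
    else coefs[["sigma"]]
    if (isTRUE(tto$censored[i])) {
      ll <- ll + log(pnorm((mu - 2) / sig))
    } else {
      y <- 1 - tto$value[i]
      ll <- ll - 0.5 * (log(2 * pi * sig^2) + ((y - mu) / sig)^2)
    }
  }
  ll
}

# term-by-term Bernoulli logit log-likelihood
oracle_dce_loglik <- function(spec, coefs, dce, pairs) {
  ll <- 0
  for (i in seq_len(nrow(dce))) {
    row <- pairs[pairs$pair_id == dce$pair_id[i], ]
    da <- oracle_disutility(spec, coefs, as.numeric(row[1, paste0("A_", dims_fx)]))
    db <- oracle_disutility(spec, coefs, as.numeric(row[1, paste0("B_", dims_fx)]))
    eta <- db - da
    if (spec$scope == "hybrid") eta <- eta / coefs[["theta"]]
    if (spec$dce_intercept) eta <- eta + coefs[["alpha_dce"]]
    p <- 1 / (1 + exp(-eta))
    ll <- ll + if (dce$choice[i] == "A") log(p) else log(1 - p)
  }
  ll
}

# grid-refinement oracle for the intercept-only censored-normal MLE
oracle_censored_mean <- function(values, censored = values <= -1) {
  y <- 1 - values
  y[censored] <- 2
  ll <- function(mu, sig) {
    sum(dnorm(y[!censored], mu, sig, log = TRUE)) +
      sum(censored) * pnorm((mu - 2) / sig, log.p = TRUE)
  }
  mu_r <- c(-1, 3); sig_r <- c(0.01, 3)
  for (pass in 1:6) {
    mus <- seq(mu_r[1], mu_r[2], length.out = 41)
    sigs <- seq(sig_r[1], sig_r[2], length.out = 41)
    val <- outer(mus, sigs, Vectorize(ll))
    best <- arrayInd(which.max(val), dim(val))
    step_m <- diff(mu_r) / 40; step_s <- diff(sig_r) / 40
    mu_r <- mus[best[1]] + c(-1, 1) * step_m
    sig_r <- pmax(sigs[best[2]] + c(-1, 1) * step_s, 1e-4)
  }
  c(mean = mean(mu_r), sigma = mean(sig_r))
}

# Lin's concordance correlation, straight from the closed form
oracle_ccc <- function(x, y) {
  2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)
}
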