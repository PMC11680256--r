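# Fixture builders and independent brute-force oracles. The oracles are
# written as plain loops (or stats::lm for the regression measures) so that
# they share no code path with the package's vectorized implementations.

make_series <- function(estimate, population = rep(1, length(estimate)),
                        se = NULL, type = "nonordered",
                        order = if (type == "ordered")
                          seq_along(estimate) else NULL,
                        ...) {
  disagg_series(estimate = estimate, population = population, se = se,
                order = order, dimension_type = type, ...)
}

# Random valid series; call set.seed() before looping.
random_series <- function(type = "nonordered", n = sample(3:10, 1),
                          with_se = FALSE, min_est = 1, max_est = 99) {
  if (type == "binary") n <- 2L
  make_series(estimate = runif(n, min_est, max_est),
              population = rgamma(n, shape = 2, rate = 1) + 0.05,
              se = if (with_se) runif(n, 0.1, 4) else NULL,
              type = type)
}

flat_series <- function(value, type = "nonordered", n = 5L) {
  if (type == "binary") n <- 2L
  make_series(rep(value, n), population = runif(n, 0.5, 2), type = type)
}

# --- oracles -----------------------------------------------------------------

oracle_mu <- function(s) {
  if (!is.na(s$setting_average)) return(s$setting_average)
  tot <- sum(s$data$population)
  acc <- 0
  for (j in seq_len(nrow(s$data)))
    acc <- acc + s$data$population[j] / tot * s$data$estimate[j]
  acc
}

oracle_ridit <- function(s) {
  d <- s$data[order(s$data$order), ]
  p <- d$population / sum(d$population)
  X <- numeric(length(p))
  cum <- 0
  for (j in seq_along(p)) {
    X[j] <- cum + p[j] / 2
    cum <- cum + p[j]
  }
  list(y = d$estimate, p = p, X = X)
}

# ACI as twice the weighted covariance of estimate and ridit rank.
oracle_aci <- function(s) {
  r <- oracle_ridit(s)
  ybar <- sum(r$p * r$y)
  xbar <- sum(r$p * r$X)
  2 * sum(r$p * (r$y - ybar) * (r$X - xbar))
}

oracle_rci <- function(s) 100 * oracle_aci(s) / oracle_mu(s)

# SII/RII via stats::lm, an independent fitting route.
oracle_sii_fit <- function(s) {
  r <- oracle_ridit(s)
  fit <- stats::lm(r$y ~ r$X, weights = r$p)
  pred <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * c(0, 1))
  list(sii = pred[2] - pred[1], pred0 = pred[1], pred1 = pred[2])
}

oracle_mdmu <- function(s) {
  mu <- oracle_mu(s)
  mean(vapply(s$data$estimate, function(y) abs(y - mu), 0))
}

oracle_mdmw <- function(s) {
  mu <- oracle_mu(s)
  p <- s$data$population / sum(s$data$population)
  acc <- 0
  for (j in seq_along(p)) acc <- acc + p[j] * abs(s$data$estimate[j] - mu)
  acc
}

oracle_bgv <- function(s) {
  mu <- oracle_mu(s)
  p <- s$data$population / sum(s$data$population)
  acc <- 0
  for (j in seq_along(p)) acc <- acc + p[j] * (s$data$estimate[j] - mu)^2
  acc
}

oracle_theil <- function(s) {
  mu <- oracle_mu(s)
  p <- s$data$population / sum(s$data$population)
  acc <- 0
  for (j in seq_along(p)) {
    r <- s$data$estimate[j] / mu
    if (r > 0) acc <- acc + p[j] * r * log(r)
  }
  1000 * acc
}

oracle_par <- function(s) {
  mu <- oracle_mu(s)
  d <- s$data
  yref <- if (s$dimension_type == "ordered") d$estimate[which.max(d$order)]
          else if (s$favourable) max(d$estimate) else min(d$estimate)
  raw <- yref - mu
  if (s$favourable) max(raw, 0) else min(raw, 0)
}

est_of <- function(res) res$estimate

noise_free <- function(sc) {
  sc$noise_n <- Inf
  sc
}
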