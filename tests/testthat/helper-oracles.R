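# Independent oracles and fixture builders shared across tests.

# Pseudo-inverse OLS oracle: every statistic recomputed from scratch via the
# SVD, sharing no code path with fit_ols (which uses a Cholesky solve).
oracle_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  sv <- svd(X)
  pinv <- sv$v %*% (t(sv$u) / sv$d)
  beta <- drop(pinv %*% y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- sv$v %*% (t(sv$v) / sv$d^2)
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  list(coefficients = beta,
       standard_errors = se,
       t_values = tval,
       p_values = 2 * pt(abs(tval), n - p, lower.tail = FALSE),
       r_squared = 1 - rss / tss,
       f_statistic = ((tss - rss) / (p - 1)) / sigma2,
       log_likelihood = -n / 2 * (log(2 * pi) + log(rss / n) + 1),
       rss = rss)
}

# Estimand contracts per coding scheme, straight from the level means.
expected_contrasts <- function(scheme, m) {
  k <- length(m)
  switch(scheme,
    treatment = ,
    simple = m[-1] - m[1],
    sum = m[-k] - mean(m),
    backward_difference = diff(m),
    helmert = vapply(seq_len(k - 1), function(j) {
      m[j + 1] - mean(m[seq_len(j)])
    }, numeric(1)))
}

# Noiseless balanced one-way fixture: reps observations exactly at each mean.
balanced_oneway <- function(m, reps = 3L) {
  lv <- LETTERS[seq_along(m)]
  data.frame(g = factor(rep(lv, each = reps), levels = lv),
             y = rep(m, each = reps))
}

# Random full-rank regression instance (first column intercept).
random_instance <- function(n, p) {
  X <- cbind("(Intercept)" = 1,
             matrix(rnorm(n * (p - 1)), n, p - 1,
                    dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  beta <- rnorm(p, sd = 2)
  list(X = X, y = drop(X %*% beta) + rnorm(n), beta = beta)
}

# A small in-memory study document used by document/query tests.
tiny_study <- function(document_id = "toy") {
  el_group <- nidm_element("fs_dx01", "DX_GROUP", "diagnostic group",
                           value_type = "categorical", levels = c("1", "2"))
  el_age <- nidm_element("age_x1", "age", "age at scan",
                         concept_urls = "http://uri.interlex.org/ilx_0100400",
                         value_type = "numeric")
  el_vol <- nidm_element("fs_000008", "brainvol", "supratentorial volume",
                         value_type = "numeric")
  obs <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), times = 3),
    element_id = rep(c("fs_dx01", "age_x1", "fs_000008"), each = 3),
    value = c("1", "2", "1", "10", "20", "30", "100", "120", "140"))
  nidm_study(document_id, list(el_group, el_age, el_vol), obs)
}

# True coefficient vector of the default two-site fixture, in design order.
default_truth_beta <- function(tokens = c("(Intercept)", "DX_GROUP[2-1]",
                                          "PIQ", "age")) {
  setNames(c(1200, -25, 1.2, 3.5), tokens)
}
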