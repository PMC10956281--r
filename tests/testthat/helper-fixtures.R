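# Small-world fixtures built in code. The mini spec keeps the full case
# classes (278/222) but a small non-case class so model fitting still has
# events; the tiny spec shrinks everything for fast determinism checks.

mini_spec <- function(n_none = 5000L, ...) {
  cohort_spec(n_none = n_none, ...)
}

tiny_spec <- function(...) {
  cohort_spec(n_incontinent = 120L, n_continent = 100L, n_none = 2500L, ...)
}

perfect_code_params <- function() {
  list(incontinent = list(sens = 1, p_cross = 0, fp_count_none = 0,
                          differential = FALSE),
       continent = list(sens = 1, p_cross = 0, fp_count_none = 0,
                        differential = FALSE))
}

# brute-force all-pairs concordance, the independent oracle for cstat()
cstat_bruteforce <- function(p, y) {
  y <- as.logical(y)
  pp <- p[y]; pn <- p[!y]
  cmp <- outer(pp, pn, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pp) * length(pn))
}

# independent multinomial deviance via stats::optim on a hand-written
# likelihood (no Newton machinery shared with the package engine)
optim_multinom_deviance <- function(X, Y) {
  X <- as.matrix(X)
  p <- ncol(X)
  nll <- function(theta) {
    B <- matrix(theta, p, 2L)
    eta <- X %*% B
    m <- pmax(0, eta[, 1], eta[, 2])
    logden <- m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m))
    -sum(Y[, 1] * eta[, 1] + Y[, 2] * eta[, 2] - logden)
  }
  fit <- stats::optim(rep(0, 2 * p), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  2 * fit$value
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
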