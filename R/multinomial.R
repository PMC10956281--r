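#' Multinomial logistic regression engine
#'
#' Fits a generalized-logit (softmax) model for a 3-level outcome with one
#' reference class and two modelled classes by Newton-Raphson with
#' step-halving. Written in-package because the surrounding pipeline needs
#' an exact log-likelihood (for likelihood-ratio forward selection) and many
#' fast refits (bootstrap optimism correction); no unpenalized multinomial
#' fitter is otherwise available here.
#'
#' @param X numeric design matrix, first column the intercept.
#' @param Y n x 2 indicator matrix for the two modelled outcome classes
#'   (rowSums in \{0, 1\}; a zero row is the reference class).
#' @param weights optional nonnegative case weights (default all 1).
#' @param ridge nonnegative ridge penalty on non-intercept coefficients;
#'   0 gives maximum likelihood. A small value guards against separation.
#' @param maxit,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return list with elements `coef` (p x 2 matrix, columns the two modelled
#'   classes), `loglik`, `deviance`, `converged`, `iterations`, and
#'   `separation` (TRUE when coefficients are diverging, i.e. some class is
#'   perfectly predicted).
#' @export
fit_multinomial <- function(X, Y, weights = NULL, ridge = 0,
                            maxit = 150L, tol = 1e-10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nrow(Y) == n, ncol(Y) == 2L)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0))

  # standardize non-intercept columns internally for conditioning;
  # coefficients are mapped back to the original scale on exit
  ctr <- c(0, if (p > 1L) colMeans(X[, -1L, drop = FALSE]))
  scl <- c(1, if (p > 1L) apply(X[, -1L, drop = FALSE], 2L, stats::sd))
  scl[!is.finite(scl) | scl <= 0] <- 1
  if (p > 1L)
    X[, -1L] <- sweep(sweep(X[, -1L, drop = FALSE], 2L, ctr[-1L]), 2L,
                      scl[-1L], `/`)

  B <- matrix(0, p, 2L)
  pen_mask <- c(0, rep(1, p - 1L))  # no penalty on intercept

  loglik_at <- function(B) {
    eta <- X %*% B
    m <- pmax(0, eta[, 1L], eta[, 2L])
    logden <- m + log(exp(-m) + exp(eta[, 1L] - m) + exp(eta[, 2L] - m))
    ll <- sum(w * (Y[, 1L] * eta[, 1L] + Y[, 2L] * eta[, 2L] - logden))
    ll - 0.5 * ridge * sum((pen_mask * B)^2)
  }

  probs_at <- function(B) {
    eta <- X %*% B
    m <- pmax(0, eta[, 1L], eta[, 2L])
    logden <- m + log(exp(-m) + exp(eta[, 1L] - m) + exp(eta[, 2L] - m))
    cbind(exp(eta[, 1L] - logden), exp(eta[, 2L] - logden))
  }

  ll <- loglik_at(B)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- probs_at(B)
    G <- crossprod(X, w * (Y - P)) - ridge * (pen_mask * B)
    # Hessian blocks: H[j,k] = -X' diag(w * P_j (1[j=k] - P_k)) X
    w11 <- w * P[, 1L] * (1 - P[, 1L])
    w22 <- w * P[, 2L] * (1 - P[, 2L])
    w12 <- -w * P[, 1L] * P[, 2L]
    H11 <- crossprod(X, X * w11)
    H22 <- crossprod(X, X * w22)
    H12 <- crossprod(X, X * w12)
    H <- rbind(cbind(H11, H12), cbind(H12, H22)) +
      diag(ridge * rep(pen_mask, 2L), 2L * p)
    g <- c(G[, 1L], G[, 2L])
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    lam <- 1e-8 * (1 + max(abs(diag(H))))
    while (is.null(step)) {  # ill-conditioned under separation: jitter
      step <- tryCatch(solve(H + diag(lam, 2L * p), g),
                       error = function(e) NULL)
      lam <- lam * 100
    }
    step <- matrix(step, p, 2L)
    fac <- 1
    repeat {
      B_new <- B + fac * step
      ll_new <- loglik_at(B_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) { B_new <- B; ll_new <- ll; break }
    }
    dll <- ll_new - ll
    B <- B_new; ll <- ll_new
    if (abs(dll) < tol * (abs(ll) + 0.1)) { converged <- TRUE; break }
    if (iter >= maxit) break
  }

  # map coefficients back to the original covariate scale
  B_orig <- B / scl
  if (p > 1L)
    B_orig[1L, ] <- B[1L, ] - colSums(B[-1L, , drop = FALSE] *
                                        (ctr[-1L] / scl[-1L]))
  list(coef = B_orig, loglik = ll, deviance = -2 * ll, converged = converged,
       iterations = iter, separation = max(abs(B)) > 20)
}

#' Predicted class probabilities from a coefficient matrix
#'
#' @param B p x 2 coefficient matrix (two modelled classes vs. reference).
#' @param X design matrix conformable with `B`.
#' @return n x 3 matrix of probabilities, columns = class 1, class 2,
#'   reference; rows sum to 1.
#' @export
multinomial_probs <- function(B, X) {
  eta <- as.matrix(X) %*% B
  m <- pmax(0, eta[, 1L], eta[, 2L])
  logden <- m + log(exp(-m) + exp(eta[, 1L] - m) + exp(eta[, 2L] - m))
  p1 <- exp(eta[, 1L] - logden)
  p2 <- exp(eta[, 2L] - logden)
  cbind(p1, p2, exp(-logden))
}
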