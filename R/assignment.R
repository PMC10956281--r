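#' Case-status assignment methods
#'
#' The three ways of deciding, per admission, whether the procedure of a
#' given diversion type occurred: take the procedure code at face value;
#' dichotomize the model-predicted probability at an optimized threshold;
#' or impute status stochastically from the predicted probability inside a
#' bootstrap loop.
#'
#' @name assignment
NULL

#' Assign status from the procedure code flag
#' @param table cohort table.
#' @param diversion "incontinent" or "continent".
#' @return logical vector.
#' @export
assign_by_code <- function(table, diversion = c("incontinent", "continent")) {
  diversion <- match.arg(diversion)
  col <- paste0("code_", diversion)
  if (!(col %in% names(table))) stop_schema("column '", col, "' missing")
  as.logical(table[[col]])
}

#' Optimal probability threshold on the ROC curve
#'
#' Candidate thresholds are the distinct predicted values; classification
#' is positive when the predicted probability is greater than or equal to
#' the threshold. `youden_j` maximizes sensitivity + specificity - 1;
#' `closest_to_corner` minimizes (1-sens)^2 + (1-spec)^2. Ties break toward
#' the smallest threshold. A constant prediction vector returns that
#' constant with `flagged = TRUE` (J = 0).
#'
#' @param p_hat predicted probabilities.
#' @param truth logical true status (must contain both classes).
#' @param criterion `"youden_j"` (default) or `"closest_to_corner"`.
#' @return object of class `threshold_rule`: tau, criterion, sensitivity,
#'   specificity, j, flagged.
#' @export
find_threshold <- function(p_hat, truth,
                           criterion = c("youden_j", "closest_to_corner")) {
  criterion <- match.arg(criterion)
  truth <- as.logical(truth)
  stopifnot(length(p_hat) == length(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop_degenerate("truth has a single class")
  o <- order(p_hat, decreasing = TRUE)
  ps <- p_hat[o]; ts <- truth[o]
  # at threshold = ps[i]: everything with p >= ps[i] is positive
  tp <- cumsum(ts); fp <- cumsum(!ts)
  last <- !duplicated(ps, fromLast = TRUE)  # last row of each distinct value
  tau_cand <- ps[last]
  sens <- tp[last] / n1
  spec <- 1 - fp[last] / n0
  score <- if (criterion == "youden_j") sens + spec - 1 else
    -((1 - sens)^2 + (1 - spec)^2)
  best <- max(score)
  i <- max(which(score >= best - 1e-12))  # candidates sorted desc: max index = smallest tau
  flagged <- length(tau_cand) == 1L
  structure(list(tau = tau_cand[i], criterion = criterion,
                 sensitivity = sens[i], specificity = spec[i],
                 j = sens[i] + spec[i] - 1, flagged = flagged),
            class = "threshold_rule")
}

#' Dichotomize predicted probabilities at a threshold rule
#'
#' Positive when the probability is equal to or above the threshold.
#' @param p_hat predicted probabilities.
#' @param rule a `threshold_rule` (or bare numeric threshold).
#' @return logical vector.
#' @export
assign_by_threshold <- function(p_hat, rule) {
  tau <- if (inherits(rule, "threshold_rule")) rule$tau else as.numeric(rule)
  stopifnot(tau > 0, tau <= 1)
  p_hat >= tau
}

#' Bootstrap imputation of case status
#'
#' For each of `n_boot` replicates the cohort is resampled with replacement
#' to its original size; each sampled admission draws one uniform number u,
#' and status is imputed from the predicted probabilities by partitioning
#' the unit interval: incontinent when u < p_inc, continent when
#' p_inc <= u < p_inc + p_cont (so the mutually exclusive statuses can
#' never both be imputed on one row; the strict inequality makes the
#' marginal imputation probability exactly p). With
#' `exclusive = FALSE` each type draws its own uniform independently. All
#' battery statistics are computed per replicate for each diversion type;
#' the replicate mean is the point estimate and the 2.5th/97.5th
#' percentiles the confidence interval. Replicates in which a statistic is
#' inestimable are excluded from that statistic's aggregation and counted.
#'
#' @param table cohort table.
#' @param p_hat matrix with columns `p_incontinent`, `p_continent` (a
#'   `predict_probabilities()` result works).
#' @param battery statistic definitions from [statistic_battery()].
#' @param n_boot number of replicates (>= 2; the source protocol uses 1000).
#' @param seed integer seed.
#' @param resample resample rows with replacement (TRUE, the method);
#'   FALSE is a test hook that imputes on the original rows only.
#' @param exclusive shared-uniform partition imputation (default) vs.
#'   independent per-type draws.
#' @param log optional log environment.
#' @return data.frame of class `bi_result`: diversion, statistic, estimate,
#'   ci_low, ci_high, n_used, n_boot.
#' @export
bootstrap_impute <- function(table, p_hat, battery = statistic_battery(),
                             n_boot = 1000L, seed = 1L, resample = TRUE,
                             exclusive = TRUE, log = NULL) {
  if (n_boot < 2L) stop_spec("n_boot must be >= 2")
  p_hat <- as.matrix(p_hat)
  ci <- grep("incontinent", colnames(p_hat))[1]
  cc <- setdiff(grep("continent", colnames(p_hat)), ci)[1]
  if (is.na(ci) || is.na(cc))
    stop_schema("p_hat needs incontinent and continent probability columns")
  p1 <- p_hat[, ci]; p2 <- p_hat[, cc]
  n <- nrow(table)
  stopifnot(length(p1) == n)
  M <- battery_matrix(table, battery)
  set.seed(seed)
  res <- array(NA_real_, c(n_boot, nrow(battery), 2L))
  for (b in seq_len(n_boot)) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    u <- stats::runif(n)
    if (exclusive) {
      imp_inc <- u < p1[idx]
      imp_con <- !imp_inc & (u < p1[idx] + p2[idx])
    } else {
      imp_inc <- u < p1[idx]
      imp_con <- stats::runif(n) < p2[idx]
    }
    res[b, , 1L] <- compute_statistics_fast(M, idx, imp_inc, battery)
    res[b, , 2L] <- compute_statistics_fast(M, idx, imp_con, battery)
  }
  out <- do.call(rbind, lapply(1:2, function(k) {
    vals <- res[, , k, drop = FALSE]
    dim(vals) <- c(n_boot, nrow(battery))
    data.frame(
      diversion = c("incontinent", "continent")[k],
      statistic = battery$name,
      estimate = colMeans(vals, na.rm = TRUE),
      ci_low = apply(vals, 2L, stats::quantile, 0.025, na.rm = TRUE),
      ci_high = apply(vals, 2L, stats::quantile, 0.975, na.rm = TRUE),
      n_used = colSums(!is.na(vals)),
      n_boot = n_boot,
      row.names = NULL
    )
  }))
  dropped <- sum(out$n_used < n_boot)
  if (dropped > 0)
    run_log("bootstrap_impute: ", dropped,
            " statistics had inestimable replicates excluded", log = log)
  class(out) <- c("bi_result", class(out))
  out
}
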