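#' Degrees-of-freedom budget for the prediction model
#'
#' Implements the four sample-size criteria of the Riley framework for
#' clinical prediction models, solved for the number of candidate
#' parameters p given the planned n and event count: (1) events per
#' variable; (2) mean absolute error around individual predictions no
#' worse than `margin`, via the van Smeden rare-outcome approximation
#' ln MAPE = -0.508 - 0.544 ln n + 0.259 ln phi + 0.504 ln p; (3) expected
#' uniform shrinkage no worse than `shrinkage`,
#' p = n (S - 1) ln(1 - R2/S); (4) optimism in apparent Cox-Snell
#' R-squared no worse than `optimism`, the shrinkage form at the shrinkage
#' level S = R2/(R2 + optimism). Criteria 3-4 need an anticipated model
#' R-squared, rarely stated in protocols; the default (Cox-Snell 0.072, a
#' highly discriminative model, and the value implied by the published
#' 32.1-df shrinkage allowance at these planning inputs) is recorded in
#' the result. With the published planning inputs (n = 429,000, 250 events
#' per outcome type) these give 25 / 42.6 / 32.1 / ~223 df, and the
#' binding criterion is events-per-variable: 25 df.
#'
#' @param n number of observations planned.
#' @param events number of outcome events (per modelled outcome level).
#' @param epv events allowed per degree of freedom (default 10).
#' @param margin target mean absolute prediction error.
#' @param shrinkage target expected shrinkage factor.
#' @param optimism target optimism in apparent Cox-Snell R-squared.
#' @param r2_cs anticipated Cox-Snell R-squared.
#' @return object of class `df_budget` with the four per-criterion df
#'   values and `allowed_df` = their minimum.
#' @export
compute_df_budget <- function(n, events, epv = 10, margin = 0.0005,
                              shrinkage = 0.999, optimism = 0.0005,
                              r2_cs = 0.072) {
  if (events <= 0) stop_degenerate("events must be positive")
  if (n <= events) stop_spec("n must exceed events")
  phi <- events / n
  epv_df <- events / epv
  r2_max <- 1 - exp(2 * (phi * log(phi) + (1 - phi) * log(1 - phi)))
  # shrinkage: n = p / ((S-1) * ln(1 - R2/S))  =>  p = n (S-1) ln(1 - R2/S)
  shrinkage_df <- n * (shrinkage - 1) * log(1 - r2_cs / shrinkage)
  # optimism: shrinkage level implied by tolerated optimism in R2_CS
  s_opt <- r2_cs / (r2_cs + optimism)
  optimism_df <- n * (s_opt - 1) * log(1 - r2_cs / s_opt)
  # van Smeden MAPE approximation solved for p
  precision_df <- exp((log(margin) + 0.508 + 0.544 * log(n) -
                         0.259 * log(phi)) / 0.504)
  vals <- c(epv_df = epv_df, precision_df = precision_df,
            shrinkage_df = shrinkage_df, optimism_df = optimism_df)
  if (any(vals <= 0))
    stop_spec("a criterion permits no degrees of freedom at this n/events: ",
              paste(names(vals)[vals <= 0], collapse = ", "))
  structure(list(epv_df = epv_df, precision_df = precision_df,
                 shrinkage_df = shrinkage_df, optimism_df = optimism_df,
                 allowed_df = min(vals),
                 assumptions = list(n = n, events = events, epv = epv,
                                    margin = margin, shrinkage = shrinkage,
                                    optimism = optimism, r2_cs = r2_cs,
                                    r2_cs_max = r2_max)),
            class = "df_budget")
}

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial transform of degree 1
#'
#' `(x + shift) / scale` raised to `power`, with power 0 meaning the
#' natural logarithm.
#' @param x numeric vector.
#' @param power one of -2, -1, -0.5, 0, 0.5, 1, 2, 3.
#' @param shift,scale positivity shift and order-of-magnitude scale.
#' @export
fp_transform <- function(x, power, shift = 0, scale = 1) {
  z <- (x + shift) / scale
  if (any(z <= 0)) stop_spec("fp_transform requires positive shifted values")
  if (power == 0) log(z) else z^power
}

fp_shift_for <- function(x) {
  if (min(x) > 0) return(0)
  ux <- sort(unique(x))
  spacing <- if (length(ux) > 1L) min(diff(ux)) else 1
  spacing - min(x)
}

fp_scale_for <- function(x, shift) {
  gm <- exp(mean(log(x + shift)))
  10^round(log10(gm))
}

#' Select the best single fractional-polynomial power for a covariate
#'
#' Fits the current multinomial model plus each candidate power of the
#' shifted/scaled covariate and picks the power with the smallest deviance;
#' ties (within `tie_tol`) break toward the linear term p = 1. A constant
#' covariate returns p = 1 with `flagged = TRUE`.
#'
#' @param x continuous covariate values.
#' @param Y n x 2 outcome indicator matrix (see [fit_multinomial()]), or a
#'   3-level factor whose last level is the reference.
#' @param X_base design matrix of terms already in the model (default
#'   intercept only).
#' @param ridge,tie_tol fitting ridge and deviance tie tolerance.
#' @return list with `power`, `shift`, `scale`, `flagged`, and the named
#'   `deviances` over all eight powers.
#' @export
select_fp1 <- function(x, Y, X_base = NULL, ridge = 0, tie_tol = 1e-6) {
  Y <- as_outcome_matrix(Y)
  n <- length(x)
  if (is.null(X_base)) X_base <- matrix(1, n, 1L)
  if (length(unique(x)) < 2L)
    return(list(power = 1, shift = fp_shift_for(x), scale = 1,
                flagged = TRUE, deviances = NULL))
  shift <- fp_shift_for(x)
  scale <- fp_scale_for(x, shift)
  dev <- vapply(FP_POWERS, function(p) {
    fit_multinomial(cbind(X_base, fp_transform(x, p, shift, scale)),
                    Y, ridge = ridge)$deviance
  }, numeric(1))
  names(dev) <- as.character(FP_POWERS)
  best <- min(dev)
  if (dev[["1"]] <= best + tie_tol) {
    power <- 1
  } else {
    power <- FP_POWERS[which.min(dev)]
  }
  list(power = power, shift = shift, scale = scale, flagged = FALSE,
       deviances = dev)
}

as_outcome_matrix <- function(y) {
  if (is.matrix(y)) {
    stopifnot(ncol(y) == 2L)
    return(y)
  }
  y <- factor(y, levels = STATUS_LEVELS)
  cbind(incontinent = as.numeric(y == "incontinent"),
        continent = as.numeric(y == "continent"))
}

#' Candidate variables in default priority ranking
#'
#' Ranking mirrors how surgeons would order administrative covariates by
#' ability to identify the procedure: the procedure-code flags first, then
#' service/admission context, bladder-cancer history, and the continuous
#' utilization measures.
#'
#' @return data.frame with columns name, rank, kind.
#' @export
default_candidates <- function() {
  data.frame(
    name = c("code_incontinent", "code_continent", "urology_service",
             "elective", "bladder_cancer_abstract", "acute_los",
             "operative_time", "unplanned_return_or_28d",
             "bladder_cancer_registry", "transfusion", "age",
             "main_or_procedure", "general_anesthetic"),
    rank = 1:13,
    kind = c("binary", "binary", "binary", "binary", "binary", "continuous",
             "continuous", "binary", "binary", "binary", "continuous",
             "binary", "binary"),
    stringsAsFactors = FALSE
  )
}

build_design <- function(terms, table, n = nrow(table)) {
  X <- matrix(1, n, 1L + length(terms))
  colnames(X) <- c("(Intercept)", vapply(terms, `[[`, "", "name"))
  for (j in seq_along(terms)) {
    tm <- terms[[j]]
    if (!(tm$name %in% names(table)))
      stop_schema("column '", tm$name, "' missing from table")
    x <- table[[tm$name]]
    X[, j + 1L] <- if (tm$kind == "continuous") {
      fp_transform(as.numeric(x), tm$power, tm$shift, tm$scale)
    } else {
      as.numeric(x)
    }
  }
  X
}

#' Forward selection of a multinomial status model
#'
#' Candidates are offered strictly in rank order; each enters both outcome
#' equations simultaneously and is retained when the likelihood-ratio test
#' (2 df: one per outcome equation) has p <= `alpha`. Continuous candidates
#' are offered as their best single fractional-polynomial transform,
#' selected in the current model context. Selection never exceeds
#' `budget$allowed_df` non-intercept terms per outcome equation, but every
#' candidate is still offered and traced. Perfect separation does not abort
#' the fit (Newton with step-halving converges in likelihood); the trace
#' flags such variables.
#'
#' @param table cohort table with `true_status` and all candidate columns.
#' @param candidates data.frame as [default_candidates()].
#' @param alpha retention p-value threshold.
#' @param budget optional [compute_df_budget()] result.
#' @param ridge optional ridge guard passed to the fitter (default 0).
#' @param log optional log environment.
#' @return object of class `status_model`: terms, coefficient matrix,
#'   selection trace, deviance.
#' @export
forward_select <- function(table, candidates = default_candidates(),
                           alpha = 0.05, budget = NULL, ridge = 0,
                           log = NULL) {
  if (!("true_status" %in% names(table)))
    stop_schema("column 'true_status' is required")
  Y <- as_outcome_matrix(table$true_status)
  n <- nrow(table)
  allowed <- if (is.null(budget)) Inf else budget$allowed_df
  candidates <- candidates[order(candidates$rank), , drop = FALSE]

  terms <- list()
  X <- matrix(1, n, 1L)
  fit0 <- fit_multinomial(X, Y, ridge = ridge)
  trace <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    x <- table[[cand$name]]
    if (is.null(x)) stop_schema("column '", cand$name, "' missing from table")
    term <- list(name = cand$name, kind = cand$kind,
                 power = NA_real_, shift = 0, scale = 1)
    fp_flag <- FALSE
    if (cand$kind == "continuous") {
      fp <- select_fp1(as.numeric(x), Y, X_base = X, ridge = ridge)
      term$power <- fp$power; term$shift <- fp$shift; term$scale <- fp$scale
      fp_flag <- fp$flagged
      col <- fp_transform(as.numeric(x), fp$power, fp$shift, fp$scale)
    } else {
      col <- as.numeric(x)
    }
    if (length(unique(col)) < 2L) {
      trace[[i]] <- data.frame(name = cand$name, lrt = NA_real_,
                               p_value = NA_real_, kept = FALSE,
                               reason = "constant", separation = FALSE,
                               fp_power = term$power)
      next
    }
    fit1 <- fit_multinomial(cbind(X, col), Y, ridge = ridge)
    lrt <- max(0, fit0$deviance - fit1$deviance)
    pval <- stats::pchisq(lrt, df = 2L, lower.tail = FALSE)
    over_budget <- length(terms) + 1L > allowed
    keep <- (pval <= alpha) && !over_budget
    reason <- if (keep) "kept" else if (over_budget) "budget" else "lrt"
    if (keep) {
      terms <- c(terms, list(term))
      X <- cbind(X, col)
      fit0 <- fit1
    }
    trace[[i]] <- data.frame(name = cand$name, lrt = lrt, p_value = pval,
                             kept = keep, reason = reason,
                             separation = fit1$separation || fp_flag,
                             fp_power = term$power)
    run_log("offer ", cand$name, ": LRT=", signif(lrt, 4),
            " p=", signif(pval, 3), " -> ", reason, log = log)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(name = character(), lrt = numeric(), p_value = numeric(),
               kept = logical(), reason = character(), separation = logical(),
               fp_power = numeric())
  colnames(fit0$coef) <- c("incontinent", "continent")
  rownames(fit0$coef) <- c("(Intercept)", vapply(terms, `[[`, "", "name"))
  structure(list(terms = terms, coef = fit0$coef, trace = trace,
                 deviance = fit0$deviance, loglik = fit0$loglik,
                 converged = fit0$converged, separation = fit0$separation,
                 ridge = ridge, n = n,
                 levels = STATUS_LEVELS, allowed_df = allowed),
            class = "status_model")
}

#' @export
print.status_model <- function(x, ...) {
  cat("Multinomial status model:", length(x$terms), "terms, n =", x$n, "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Predicted status probabilities
#'
#' @param model a `status_model`.
#' @param table cohort table containing every model column.
#' @return n x 3 matrix with columns `p_incontinent`, `p_continent`,
#'   `p_none`; rows sum to 1.
#' @export
predict_probabilities <- function(model, table) {
  stopifnot(inherits(model, "status_model"))
  X <- build_design(model$terms, table)
  P <- multinomial_probs(model$coef, X)
  colnames(P) <- c("p_incontinent", "p_continent", "p_none")
  P
}

#' Concordance (c-statistic) of predictions against a binary outcome
#'
#' Rank-based (Wilcoxon) AUC with the usual 1/2 credit for ties.
#' @param p predicted probabilities; @param y logical outcome.
#' @export
cstat <- function(p, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop_degenerate("outcome has a single class")
  r <- rank(p)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Integrated calibration index
#'
#' Mean absolute difference between predicted probabilities and a
#' locally-smoothed (lowess) observed event rate evaluated at each
#' prediction.
#' @param p predicted probabilities; @param y logical outcome.
#' @param span lowess smoothing fraction (default 0.75).
#' @export
ici <- function(p, y, span = 0.75) {
  y <- as.numeric(y)
  if (length(unique(p)) < 2L)  # constant predictions: observed rate is flat
    return(mean(abs(p - mean(y))))
  sm <- stats::lowess(p, y, f = span, iter = 0)
  obs <- stats::approx(sm$x, sm$y, xout = p, rule = 2, ties = mean)$y
  mean(abs(p - obs))
}

#' Bootstrap internal validation (optimism correction)
#'
#' For each outcome level (one-vs-rest) computes the apparent c-statistic
#' and integrated calibration index on the full table, then the bootstrap
#' optimism: the model structure is refit on each bootstrap sample and the
#' difference between its performance on the bootstrap sample and on the
#' original table is averaged. Corrected = apparent - mean optimism;
#' percentile confidence intervals come from the per-replicate corrected
#' values. Replicates missing an outcome class are redrawn (up to 25 extra
#' tries each) and logged.
#'
#' @param model a fitted `status_model` (its term structure is refit).
#' @param table the original cohort table.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param span lowess span for the calibration curve.
#' @param log optional log environment.
#' @return object of class `validation_report`.
#' @export
internal_validate <- function(model, table, n_boot = 1000L, seed = 1L,
                              span = 0.75, log = NULL) {
  stopifnot(inherits(model, "status_model"))
  if (n_boot < 2L) stop_spec("n_boot must be >= 2")
  n <- nrow(table)
  Y <- as_outcome_matrix(table$true_status)
  X <- build_design(model$terms, table)
  P_app <- multinomial_probs(model$coef, X)

  apparent <- sapply(1:2, function(k)
    c(c = cstat(P_app[, k], Y[, k] == 1), ici = ici(P_app[, k], Y[, k] == 1, span)))
  colnames(apparent) <- c("incontinent", "continent")

  set.seed(seed)
  opt_c <- matrix(NA_real_, n_boot, 2L)
  opt_i <- matrix(NA_real_, n_boot, 2L)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    tries <- 0L
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- all(colSums(Y[idx, , drop = FALSE]) > 0) &&
        sum(Y[idx, ]) < n  # reference class present too
      if (ok) break
      tries <- tries + 1L; redraws <- redraws + 1L
      if (tries > 25L) stop_degenerate("outcome class absent from bootstrap ",
                                       "samples after repeated redraws")
    }
    fit_b <- fit_multinomial(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                             ridge = model$ridge)
    P_bb <- multinomial_probs(fit_b$coef, X[idx, , drop = FALSE])
    P_bo <- multinomial_probs(fit_b$coef, X)
    for (k in 1:2) {
      yb <- Y[idx, k] == 1
      opt_c[b, k] <- cstat(P_bb[, k], yb) - cstat(P_bo[, k], Y[, k] == 1)
      opt_i[b, k] <- ici(P_bb[, k], yb, span) - ici(P_bo[, k], Y[, k] == 1, span)
    }
  }
  if (redraws > 0) run_log("validation: ", redraws, " replicate redraws", log = log)

  corr_c <- sweep(-opt_c, 2L, apparent["c", ], `+`)
  corr_i <- sweep(-opt_i, 2L, apparent["ici", ], `+`)
  corr_i[corr_i < 0] <- 0  # ICI is nonnegative
  summarize <- function(app, corr_mat) {
    data.frame(
      outcome = c("incontinent", "continent"),
      apparent = app,
      optimism = app - colMeans(corr_mat),
      corrected = colMeans(corr_mat),
      ci_low = apply(corr_mat, 2L, stats::quantile, 0.025),
      ci_high = apply(corr_mat, 2L, stats::quantile, 0.975),
      row.names = NULL
    )
  }
  cal <- lapply(1:2, function(k) {
    sm <- stats::lowess(P_app[, k], Y[, k], f = span, iter = 0)
    data.frame(predicted = sm$x, observed = sm$y)
  })
  names(cal) <- c("incontinent", "continent")
  structure(list(c_statistic = summarize(apparent["c", ], corr_c),
                 ici = summarize(apparent["ici", ], corr_i),
                 calibration = cal, n_boot = n_boot, seed = seed,
                 redraws = redraws),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Internal validation (", x$n_boot, " bootstrap replicates)\n", sep = "")
  cat("c-statistic:\n"); print(x$c_statistic, digits = 4)
  cat("ICI:\n"); print(x$ici, digits = 4)
  invisible(x)
}

#' Save / load a fitted status model as JSON
#' @param model a `status_model`; @param path file path.
#' @export
save_model <- function(model, path) {
  obj <- list(terms = model$terms,
              coef = as.data.frame(model$coef),
              coef_rows = rownames(model$coef),
              trace = model$trace, deviance = model$deviance,
              loglik = model$loglik, converged = model$converged,
              separation = model$separation, ridge = model$ridge,
              n = model$n, allowed_df = model$allowed_df)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- as.matrix(obj$coef)
  rownames(coef) <- obj$coef_rows
  tdf <- as.data.frame(obj$terms)
  terms <- if (NROW(tdf) == 0) list() else lapply(seq_len(nrow(tdf)), function(i)
    list(name = tdf$name[i], kind = tdf$kind[i], power = tdf$power[i],
         shift = tdf$shift[i], scale = tdf$scale[i]))
  structure(list(terms = terms, coef = coef, trace = obj$trace,
                 deviance = obj$deviance, loglik = obj$loglik,
                 converged = obj$converged, separation = obj$separation,
                 ridge = obj$ridge %||% 0, n = obj$n,
                 levels = STATUS_LEVELS, allowed_df = obj$allowed_df),
            class = "status_model")
}
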