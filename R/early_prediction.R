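# 14-day early features and the multinomial logistic early-prediction model.
#
# The multinomial logit log(p_j / p_ref) = x' b_j is fitted by maximum
# likelihood (BFGS on the negative log-likelihood with analytic gradient);
# Wald standard errors come from the inverse of the numerical Hessian at the
# optimum. Predictors are standardized internally and coefficients and their
# covariance are mapped back to the raw scale.

#' Early (first 14 days) predictors per participant
#'
#' `X1` is the early weight-change rate in kg/day, **positive = loss**:
#' the first recorded weight minus the last recorded weight within the window
#' `[t1, t1 + window - 1]`, divided by the window length. `X2` is the number
#' of records in that window and `X3` the participant's total duration
#' (`ttotal`). When only one record falls inside the window, `X1` is 0 and
#' `sparse_window` is flagged.
#'
#' @param records Selected record tibble.
#' @param window Early window length in days (default 14).
#' @return A tibble: `participant_id`, `X1`, `X2`, `X3`, `sparse_window`.
#' @export
early_features <- function(records, window = 14) {
  records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      X1 = {
        inw <- .data$weight_kg[.data$day <= min(.data$day) + window - 1]
        if (length(inw) >= 2) (inw[1] - inw[length(inw)]) / window else 0
      },
      X2 = sum(.data$day <= min(.data$day) + window - 1),
      X3 = max(.data$day) - min(.data$day),
      sparse_window = sum(.data$day <= min(.data$day) + window - 1) < 2,
      .groups = "drop"
    )
}

mlogit_nll <- function(par, X, Ymat) {
  B <- matrix(par, nrow = ncol(X))
  eta <- X %*% B
  m <- pmax(apply(eta, 1, max), 0)
  logden <- m + log(exp(-m) + rowSums(exp(eta - m)))
  -(sum(eta * Ymat) - sum(logden))
}

mlogit_grad <- function(par, X, Ymat) {
  B <- matrix(par, nrow = ncol(X))
  eta <- X %*% B
  m <- pmax(apply(eta, 1, max), 0)
  logden <- m + log(exp(-m) + rowSums(exp(eta - m)))
  P <- exp(eta - logden)
  as.vector(crossprod(X, P - Ymat))
}

#' Fit the multinomial logistic early-prediction model
#'
#' Fits `log(p_j(x) / p_ref(x)) = b0_j + b1_j X1 + b2_j X2 + b3_j X3` by
#' maximum likelihood, with the reference pattern's coefficients fixed at 0.
#' Odds ratios are `exp(b)` and 95% confidence intervals
#' `exp(b +/- 1.96 SE)` (Wald). Optional extra covariates (e.g. age, sex) can
#' be appended without altering the three core predictors.
#'
#' Convergence diagnostics are surfaced rather than hidden: if the optimizer
#' fails, the score is far from zero, or standard errors blow up (a symptom of
#' perfect separation), the fit is flagged (`converged`,
#' `separation_suspected`) and a warning is raised.
#'
#' @param features Early-feature tibble from [early_features()].
#' @param assignments Assignment tibble from [classify_trajectories()]; the
#'   consolidated labels are used as the outcome.
#' @param reference Reference category (default `"1"`, the steady-decrease
#'   pattern).
#' @param covariates Character vector naming extra columns of `features` to
#'   adjust for (optional).
#' @return An object of class `pattern_multinom` with methods [coef()],
#'   [vcov()], [logLik()], [predict()][predict.pattern_multinom],
#'   [tidy()][tidy.pattern_multinom] and [glance()][glance.pattern_multinom].
#' @export
fit_pattern_multinom <- function(features, assignments, reference = "1",
                                 covariates = NULL) {
  df <- dplyr::inner_join(features,
    dplyr::select(assignments, "participant_id", "consolidated"),
    by = "participant_id"
  )
  fit_multinom_impl(
    y = as.character(df$consolidated),
    X = as.matrix(df[, c("X1", "X2", "X3", covariates)]),
    reference = reference
  )
}

# Core fitter on a plain outcome vector and predictor matrix. Used both by
# fit_pattern_multinom() and directly in recovery simulations.
fit_multinom_impl <- function(y, X, reference) {
  lev <- unique(y)
  if (!reference %in% lev) stop("reference category not present in data", call. = FALSE)
  lev <- c(reference, sort(setdiff(lev, reference)))
  cnt <- table(factor(y, levels = lev))
  if (length(lev) < 2 || any(cnt < 2)) {
    stop("need >= 2 categories, each with >= 2 members", call. = FALSE)
  }
  terms <- c("(Intercept)", colnames(X))
  n <- length(y)
  p <- ncol(X) + 1L

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  Ymat <- outer(y, lev[-1], `==`) * 1

  opt <- stats::optim(
    par = rep(0, p * (length(lev) - 1L)),
    fn = mlogit_nll, gr = mlogit_grad, X = Xs, Ymat = Ymat,
    method = "BFGS", hessian = TRUE,
    control = list(maxit = 1000, reltol = 1e-14)
  )
  score <- mlogit_grad(opt$par, Xs, Ymat)
  vcov_z <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, length(opt$par), length(opt$par))
  })

  # back-transform standardized coefficients to the raw predictor scale
  A <- diag(1 / c(1, scl))
  A[1, -1] <- -ctr / scl
  J1 <- length(lev) - 1L
  M <- matrix(0, p * J1, p * J1)
  for (j in seq_len(J1)) {
    idx <- ((j - 1) * p + 1):(j * p)
    M[idx, idx] <- A
  }
  b_raw <- as.vector(M %*% opt$par)
  vcov_raw <- M %*% vcov_z %*% t(M)

  B <- matrix(b_raw, nrow = p, dimnames = list(terms, lev[-1]))
  se <- matrix(sqrt(pmax(diag(vcov_raw), 0)),
    nrow = p, dimnames = list(terms, lev[-1])
  )
  par_names <- as.vector(outer(terms, lev[-1], function(t, l) paste(l, t, sep = ":")))
  dimnames(vcov_raw) <- list(par_names, par_names)

  converged <- opt$convergence == 0 && max(abs(score)) < 1e-4 * max(1, n)
  separation <- any(!is.finite(vcov_z)) ||
    any(sqrt(pmax(diag(vcov_z), 0)) > 50) # on the standardized scale
  if (!converged || separation) {
    warning(
      "multinomial fit flagged: ",
      if (!converged) "optimizer did not converge cleanly; " else "",
      if (separation) "huge standard errors suggest (quasi-)separation" else "",
      call. = FALSE
    )
  }

  structure(
    list(
      coefficients = B, std_errors = se, vcov = vcov_raw,
      logLik = -opt$value, n = n, levels = lev, reference = lev[1],
      terms = terms, converged = converged,
      separation_suspected = separation,
      center = ctr, scale = scl
    ),
    class = "pattern_multinom"
  )
}

#' @export
coef.pattern_multinom <- function(object, ...) object$coefficients

#' @export
vcov.pattern_multinom <- function(object, ...) object$vcov

#' @export
logLik.pattern_multinom <- function(object, ...) {
  structure(object$logLik,
    df = length(object$coefficients), nobs = object$n,
    class = "logLik"
  )
}

#' Predict pattern probabilities
#'
#' @param object A `pattern_multinom` fit.
#' @param newdata Data frame or matrix holding the model's predictor columns.
#' @param ... Unused.
#' @return A matrix of category probabilities (columns in `object$levels`);
#'   rows sum to 1.
#' @export
predict.pattern_multinom <- function(object, newdata, ...) {
  vars <- setdiff(object$terms, "(Intercept)")
  X <- cbind(1, as.matrix(as.data.frame(newdata)[, vars, drop = FALSE]))
  eta <- cbind(0, X %*% object$coefficients)
  m <- apply(eta, 1, max)
  P <- exp(eta - m)
  P <- P / rowSums(P)
  colnames(P) <- object$levels
  P
}

#' @export
print.pattern_multinom <- function(x, ...) {
  cat(
    "Multinomial logistic early-prediction model\n",
    "reference pattern: ", x$reference, "; n = ", x$n,
    "; logLik = ", format(x$logLik, digits = 6), "\n\n",
    sep = ""
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy the multinomial early-prediction fit
#'
#' @param x A `pattern_multinom` object.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per (non-reference pattern, term):
#'   `y.level`, `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `OR = exp(estimate)` and `conf.low`/`conf.high` (exponentiated Wald
#'   bounds).
#' @exportS3Method generics::tidy
tidy.pattern_multinom <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- as.vector(x$coefficients)
  se <- as.vector(x$std_errors)
  tibble::tibble(
    y.level = rep(colnames(x$coefficients), each = nrow(x$coefficients)),
    term = rep(rownames(x$coefficients), ncol(x$coefficients)),
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pnorm(-abs(est / se)),
    OR = exp(est),
    conf.low = exp(est - z * se),
    conf.high = exp(est + z * se)
  )
}

#' Glance at the multinomial early-prediction fit
#'
#' @param x A `pattern_multinom` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `df`, `nobs`, `converged`,
#'   `separation_suspected`.
#' @exportS3Method generics::glance
glance.pattern_multinom <- function(x, ...) {
  k <- length(x$coefficients)
  tibble::tibble(
    logLik = x$logLik,
    AIC = -2 * x$logLik + 2 * k,
    df = k,
    nobs = x$n,
    converged = x$converged,
    separation_suspected = x$separation_suspected
  )
}
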