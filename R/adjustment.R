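# Confounder-adjusted association: per-drug logistic regression of the
# event indicator on drug exposure with age, sex, weight and report year
# as covariates.  The fit is a hand-rolled Newton/IRLS maximization of the
# Bernoulli log-likelihood, with Wald inference from the inverse observed
# information; separation is detected and flagged, not repaired.

#' Build the per-drug regression design
#'
#' One row per report: `outcome` (target event among the reactions),
#' `exposure` (the drug is a primary suspect on the report), and the
#' confounders age (years), sex (male indicator; unknown-sex rows are
#' dropped), weight (kg) and report year.  Complete-case: rows missing
#' any covariate are dropped and counted.  Covariates are centred and
#' scaled by the retained rows' mean/SD (recorded for back-transformation);
#' the exposure odds ratio is invariant to this.
#'
#' @param data a cleaned `faers_data`.
#' @param drug normalized drug name giving the exposure indicator.
#' @param target_pt,target_code target event, as in [event_report_ids()].
#' @return list of class `regression_design`: `rows` (data.frame with
#'   `outcome`, `exposure`, `age_z`, `male`, `weight_z`, `year_z`),
#'   `n_total`, `n_used`, `n_dropped`, `scaling`, `estimable`, `reason`.
#' @export
build_design <- function(data, drug, target_pt, target_code = NULL) {
  r <- data$reports
  ev <- event_report_ids(data, target_pt, target_code)
  ps <- ps_pairs(data)
  exposed_ids <- unique(ps$primaryid[ps$name == drug])
  df <- data.frame(
    outcome = as.integer(r$primaryid %in% ev),
    exposure = as.integer(r$primaryid %in% exposed_ids),
    age = r$age_years,
    male = ifelse(r$sex == "male", 1,
                  ifelse(r$sex == "female", 0, NA_real_)),
    weight = r$weight_kg,
    year = as.numeric(r$report_year)
  )
  n_total <- nrow(df)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  scaling <- lapply(c(age = "age", weight = "weight", year = "year"),
                    function(v) {
                      c(mean = mean(df[[v]]), sd = stats::sd(df[[v]]))
                    })
  zscore <- function(x, s) if (is.na(s["sd"]) || s["sd"] == 0) {
    x * 0
  } else {
    (x - s[["mean"]]) / s[["sd"]]
  }
  rows <- data.frame(
    outcome = df$outcome, exposure = df$exposure,
    age_z = zscore(df$age, scaling$age),
    male = df$male,
    weight_z = zscore(df$weight, scaling$weight),
    year_z = zscore(df$year, scaling$year)
  )
  estimable <- TRUE
  reason <- ""
  if (nrow(rows) < 10) {
    estimable <- FALSE; reason <- "fewer_than_10_rows"
  } else if (length(unique(rows$outcome)) < 2) {
    estimable <- FALSE; reason <- "constant_outcome"
  } else if (length(unique(rows$exposure)) < 2) {
    estimable <- FALSE; reason <- "constant_exposure"
  }
  structure(
    list(rows = rows, n_total = n_total, n_used = nrow(rows),
         n_dropped = n_total - nrow(rows), scaling = scaling,
         estimable = estimable, reason = reason),
    class = "regression_design"
  )
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Newton--Raphson on the Bernoulli log-likelihood, solved each step as a
#' weighted least-squares problem via the QR decomposition.  Convergence:
#' `max |score| < 1e-8` or relative log-likelihood change `< 1e-10`, cap
#' 100 iterations.  Wald standard errors come from the inverse observed
#' information at the optimum.  Complete or quasi-complete separation
#' (fitted probabilities collapsing to 0/1 with diverging coefficients) is
#' detected and returned as a flagged non-converged result.
#'
#' @param y binary response vector.
#' @param x numeric design matrix (no intercept column; one is added).
#' @param term_names optional column labels.
#' @param exposure_term name of the term whose odds ratio is reported
#'   (default `"exposure"`; ignored if absent).
#' @return object of class `logistic_fit`: `coef`, `se`, `vcov`,
#'   `loglik`, `iterations`, `converged`, `separation`, `n`, and --- when
#'   the exposure term exists --- `or_point`, `or_lo95`, `or_hi95`,
#'   `p_value`.
#' @export
fit_logistic <- function(y, x, term_names = colnames(x),
                         exposure_term = "exposure") {
  x <- as.matrix(x)
  if (is.null(term_names)) term_names <- paste0("x", seq_len(ncol(x)))
  X <- cbind(`(intercept)` = 1, x)
  colnames(X) <- c("(intercept)", term_names)
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2) stop("response has a single class")
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  separation <- FALSE
  it <- 0
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    ll <- sum(y * eta - log1p(exp(eta)))
    if (max(abs(score)) < 1e-8 ||
        (is.finite(ll_old) && abs(ll - ll_old) < 1e-10 * (abs(ll) + 1))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # guard against singular information
    winfo <- crossprod(X, X * w)
    ch <- tryCatch(chol(winfo), error = function(e) NULL)
    if (is.null(ch)) {
      stop("singular information matrix; collinear terms among: ",
           paste(colnames(X), collapse = ", "))
    }
    beta <- beta + backsolve(ch, forwardsolve(t(ch), score))
    if (max(abs(beta)) > 30) {  # diverging coefficients: separation
      separation <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  winfo <- crossprod(X, X * (mu * (1 - mu)))
  vcov <- tryCatch(chol2inv(chol(winfo)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  out <- list(coef = beta, se = se, vcov = vcov,
              loglik = sum(y * eta - log1p(exp(eta))),
              iterations = it, converged = converged && !separation,
              separation = separation, n = n)
  if (exposure_term %in% names(beta)) {
    b <- beta[[exposure_term]]; s <- se[[exposure_term]]
    out$or_point <- exp(b)
    out$or_lo95 <- exp(b - 1.96 * s)
    out$or_hi95 <- exp(b + 1.96 * s)
    out$p_value <- 2 * stats::pnorm(-abs(b / s))
  }
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, loglik = %.3f, %d iterations%s\n",
              x$n, x$loglik, x$iterations,
              if (x$separation) " [SEPARATION]" else
                if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- data.frame(coef = x$coef, se = x$se)
  print(round(tab, 4))
  if (!is.null(x$or_point)) {
    cat(sprintf("exposure OR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                x$or_point, x$or_lo95, x$or_hi95, x$p_value))
  }
  invisible(x)
}

#' Adjusted odds ratios for a set of drugs
#'
#' Fits one confounder-adjusted logistic model per drug (exposure = that
#' drug only), flagging each as an independent risk factor when `OR > 1`
#' and `p < 0.05`.  Per-drug failures (inestimable designs, separation)
#' are recorded and the batch continues.
#'
#' @inheritParams build_design
#' @param drugs character vector of drug names (e.g. the consensus-signal
#'   list).
#' @return data.frame: one row per drug with `n_used`, `n_dropped`,
#'   `coef`, `se`, `or`, `or_lo95`, `or_hi95`, `p_value`, `converged`,
#'   `separation`, `independent_risk`, `status`.
#' @export
run_adjustment <- function(data, drugs, target_pt, target_code = NULL) {
  one <- function(drug) {
    des <- build_design(data, drug, target_pt, target_code)
    base <- data.frame(drug = drug, n_used = des$n_used,
                       n_dropped = des$n_dropped, coef = NA_real_,
                       se = NA_real_, or = NA_real_, or_lo95 = NA_real_,
                       or_hi95 = NA_real_, p_value = NA_real_,
                       converged = FALSE, separation = FALSE,
                       independent_risk = FALSE, status = des$reason,
                       stringsAsFactors = FALSE)
    if (!des$estimable) return(base)
    fit <- tryCatch(
      fit_logistic(des$rows$outcome,
                   as.matrix(des$rows[c("exposure", "age_z", "male",
                                        "weight_z", "year_z")])),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      base$status <- fit
      return(base)
    }
    base$coef <- fit$coef[["exposure"]]
    base$se <- fit$se[["exposure"]]
    base$or <- fit$or_point
    base$or_lo95 <- fit$or_lo95
    base$or_hi95 <- fit$or_hi95
    base$p_value <- fit$p_value
    base$converged <- fit$converged
    base$separation <- fit$separation
    base$independent_risk <- isTRUE(fit$converged) &&
      fit$or_point > 1 && fit$p_value < 0.05
    base$status <- if (fit$separation) "separation" else "ok"
    base
  }
  out <- do.call(rbind, lapply(drugs, one))
  if (is.null(out)) {
    out <- data.frame(drug = character(0))
  }
  rownames(out) <- NULL
  out
}
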