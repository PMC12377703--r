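# Disproportionality statistics on per-drug 2x2 contingency tables.
#
# For one drug D and one target event PT over N cleaned reports:
#       a = reports with D (primary suspect) and the event
#       b = reports with D, other events
#       c = reports without D, with the event
#       d = reports with neither
# Four statistics are computed on (a, b, c, d):
#   ROR  = ad/bc with a Wald 95% CI on the log scale;
#   PRR  = [a/(a+b)] / [c/(c+d)] with the Yates-corrected Pearson
#          chi-square of the table;
#   IC   = log2((a+0.5)/(E+0.5)), E = (a+b)(a+c)/N, with the closed-form
#          lower credibility bound IC025 = IC - 3.3(a+0.5)^-1/2
#          - 2(a+0.5)^-3/2 (Noren's BCPNN approximation);
#   EBGM = geometric mean of the posterior relative reporting rate under
#          DuMouchel's two-component gamma mixture prior (MGPS), with
#          EB05 its posterior 5th percentile.
# A drug is called a consensus signal only when all four methods flag it.

#' Reports carrying the target event
#'
#' @param data a cleaned `faers_data`.
#' @param target_pt preferred term (case-insensitive match on `pt`).
#' @param target_code optional MedDRA code accepted as an alternative key.
#' @return numeric vector of `primaryid`s whose reactions include the
#'   target event.
#' @export
event_report_ids <- function(data, target_pt, target_code = NULL) {
  hit <- toupper(data$reactions$pt) == toupper(trimws(target_pt))
  if (!is.null(target_code)) {
    hit <- hit | (!is.na(data$reactions$pt_code) &
                    data$reactions$pt_code == target_code)
  }
  unique(data$reactions$primaryid[hit])
}

# one row per distinct (report, drug) primary-suspect pair
ps_pairs <- function(data) {
  ps <- data$drugs[data$drugs$role == "PS", c("primaryid", "name")]
  ps[!duplicated(paste(ps$primaryid, ps$name)), , drop = FALSE]
}

#' Select target drugs by minimum case count
#'
#' Counts, per drug, the distinct reports in which the drug is a primary
#' suspect and the target event is among the reactions (one report
#' contributes at most 1 to a drug's count).  Drugs at or above
#' `min_cases` become target drugs for disproportionality analysis.
#'
#' @inheritParams event_report_ids
#' @param min_cases minimum number of event cases (default 10).
#' @return data.frame `drug`, `cases`, `rank`, sorted by count descending,
#'   ties alphabetical.
#' @export
select_target_drugs <- function(data, target_pt, min_cases = 10,
                                target_code = NULL) {
  ev <- event_report_ids(data, target_pt, target_code)
  ps <- ps_pairs(data)
  ps <- ps[ps$primaryid %in% ev, , drop = FALSE]
  if (!nrow(ps)) {
    return(data.frame(drug = character(0), cases = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  cnt <- table(ps$name)
  out <- data.frame(drug = names(cnt), cases = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[out$cases >= min_cases, , drop = FALSE]
  out <- out[order(-out$cases, out$drug), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the 2x2 contingency table for one drug
#'
#' The unit of counting is the report: a report is drug-exposed iff it has
#' at least one primary-suspect entry of the drug, event-positive iff at
#' least one reaction equals the target PT.  `a+b+c+d` always equals the
#' total report count.
#'
#' @inheritParams event_report_ids
#' @param drug normalized drug name.
#' @return list with integer counts `a`, `b`, `c`, `d` and `n`.
#' @export
build_table <- function(data, drug, target_pt, target_code = NULL) {
  n <- nrow(data$reports)
  ev <- event_report_ids(data, target_pt, target_code)
  ps <- ps_pairs(data)
  ex <- unique(ps$primaryid[ps$name == drug])
  a <- sum(ex %in% ev)
  b <- length(ex) - a
  c_ <- length(ev) - a
  list(a = as.integer(a), b = as.integer(b), c = as.integer(c_),
       d = as.integer(n - a - b - c_), n = as.integer(n))
}

# All drugs at once (same semantics as build_table, vectorized).
build_tables <- function(data, drugs, target_pt, target_code = NULL) {
  n <- nrow(data$reports)
  ev <- event_report_ids(data, target_pt, target_code)
  ps <- ps_pairs(data)
  ps <- ps[ps$name %in% drugs, , drop = FALSE]
  exp_n <- table(factor(ps$name, levels = drugs))
  a_n <- table(factor(ps$name[ps$primaryid %in% ev], levels = drugs))
  a <- as.integer(a_n)
  exposed <- as.integer(exp_n)
  data.frame(
    drug = drugs,
    a = a, b = exposed - a, c = length(ev) - a,
    d = n - exposed - (length(ev) - a),
    n = n, stringsAsFactors = FALSE
  )
}

# Haldane-Anscombe: +0.5 to every cell when any cell is zero.
ha_correct <- function(a, b, c, d) {
  corr <- (a == 0 | b == 0 | c == 0 | d == 0)
  k <- ifelse(corr, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = corr)
}

#' Reporting odds ratio with Wald 95% CI
#'
#' `ROR = ad/bc`; `CI = exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' When any cell is zero the Haldane--Anscombe +0.5 correction is applied
#' to all four cells and the result flagged `corrected`.  With an empty
#' margin (`a+b = 0` or `c+d = 0`) the estimate is undefined and `NA` is
#' returned with `defined = FALSE`.
#'
#' @param a,b,c,d cell counts (vectorized).
#' @return data.frame `ror`, `ror_lo95`, `ror_hi95`, `corrected`, `defined`.
#' @examples
#' ror_stat(10, 90, 100, 9800)  # ROR 10.89, CI (5.66, 20.94)
#' @export
ror_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  defined <- (a + b) > 0 & (c + d) > 0
  h <- ha_correct(a, b, c, d)
  est <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  lo <- exp(log(est) - 1.96 * se)
  hi <- exp(log(est) + 1.96 * se)
  est[!defined] <- lo[!defined] <- hi[!defined] <- NA_real_
  data.frame(ror = est, ror_lo95 = lo, ror_hi95 = hi,
             corrected = h$corrected & defined, defined = defined)
}

#' Proportional reporting ratio and Yates chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square is the Pearson statistic
#' of the 2x2 table with Yates continuity correction (clamped at zero, as
#' in `chisq.test(correct = TRUE)`), computed on the uncorrected counts.
#' The ratio uses the same zero-cell +0.5 policy as [ror_stat()].
#'
#' @inheritParams ror_stat
#' @return data.frame `prr`, `chi2`, `corrected`, `defined`.
#' @examples
#' prr_stat(10, 90, 100, 9800)  # PRR 9.9
#' @export
prr_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  defined <- (a + b) > 0 & (c + d) > 0
  h <- ha_correct(a, b, c, d)
  prr <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  n <- a + b + c + d
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, n * num^2 / den, 0)
  prr[!defined] <- NA_real_
  data.frame(prr = prr, chi2 = chi2, corrected = h$corrected & defined,
             defined = defined)
}

#' BCPNN information component (closed form)
#'
#' `E = (a+b)(a+c)/N`; `IC = log2((a+0.5)/(E+0.5))`;
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`.
#' The +0.5 shrinkage keeps every input finite, so the statistic is
#' defined for all tables with `N > 0`.
#'
#' @inheritParams ror_stat
#' @return data.frame `ic`, `ic025`, `expected`.
#' @examples
#' bcpnn_ic(10, 90, 100, 9800)  # E = 1.1, IC = log2(10.5/1.6)
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  e <- ifelse(n > 0, (a + b) * (a + c) / n, 0)
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  data.frame(ic = ic, ic025 = ic025, expected = e)
}

# ---- empirical-Bayes gamma-Poisson shrinker (MGPS) ------------------------

# Marginal negative-binomial mixture log-likelihood of observed counts a_i
# with expectations E_i under prior (alpha1, beta1, alpha2, beta2, w).
# Under lambda_i ~ Gamma(alpha, rate beta), a_i | lambda_i ~ Pois(lambda_i
# E_i), the marginal is NB(size = alpha, prob = beta/(beta + E_i)).
gps_marginal_loglik <- function(theta, a, e) {
  a1 <- theta[1]; b1 <- theta[2]; a2 <- theta[3]; b2 <- theta[4]
  w <- theta[5]
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + e), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + e), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
}

#' Fit the DuMouchel two-gamma prior by marginal maximum likelihood
#'
#' The relative reporting rate lambda of each drug--event pair is modelled
#' as a two-component gamma mixture; integrating the Poisson likelihood
#' gives a negative-binomial mixture marginal whose log-likelihood is
#' maximized over the 5 hyperparameters.  Optimization is derivative-free
#' Nelder--Mead from 8 deterministic starts spread over a log/logit
#' transformed parameter cube; the best converged start wins.
#'
#' @param a integer vector of observed counts.
#' @param e numeric vector of expected counts (same length, `E_i > 0`).
#' @param starts optional matrix of starting values on the natural scale
#'   (columns `alpha1, beta1, alpha2, beta2, w`).
#' @return object of class `gps_prior`: list with `alpha1, beta1, alpha2,
#'   beta2, w`, `loglik`, `converged`, `n_pairs`, and the per-start
#'   diagnostics in `trace`.
#' @export
gps_fit <- function(a, e, starts = NULL) {
  stopifnot(length(a) == length(e))
  keep <- e > 0 & !is.na(a)
  a <- a[keep]; e <- e[keep]
  if (length(a) < 2) stop("gps_fit needs at least 2 pairs with E > 0")
  if (is.null(starts)) {
    starts <- rbind(
      c(0.2, 0.1, 2.0, 4.0, 1 / 3),
      c(1.0, 1.0, 1.0, 1.0, 0.5),
      c(0.5, 0.5, 3.0, 3.0, 0.2),
      c(2.0, 0.5, 0.5, 2.0, 0.5),
      c(0.1, 0.1, 5.0, 5.0, 0.5),
      c(1.0, 2.0, 2.0, 1.0, 0.8),
      c(0.3, 0.3, 1.5, 0.5, 0.4),
      c(3.0, 1.0, 0.2, 0.2, 0.6)
    )
  }
  # optimize on (log alpha1, log beta1, log alpha2, log beta2, logit w)
  to_nat <- function(p) c(exp(p[1:4]), stats::plogis(p[5]))
  # hyperparameters are boxed at 1e3: larger shapes/rates describe an
  # effectively degenerate (point-mass) component, which overfits small
  # pair sets and can invert the posterior quantile ordering
  nll <- function(p) {
    th <- to_nat(p)
    if (any(!is.finite(th)) || any(th[1:4] <= 0) || any(th[1:4] > 1e3)) {
      return(1e12)
    }
    -gps_marginal_loglik(th, a, e)
  }
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    p0 <- c(log(starts[i, 1:4]), stats::qlogis(starts[i, 5]))
    fit <- stats::optim(p0, nll, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-10))
    list(start = i, value = fit$value, par = fit$par,
         converged = fit$convergence == 0)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (!any(vapply(runs, `[[`, logical(1), "converged"))) {
    stop("gps_fit: no optimizer start converged; best log-likelihood ",
         -min(vals))
  }
  best <- runs[[which.min(ifelse(
    vapply(runs, `[[`, logical(1), "converged"), vals, Inf))]]
  th <- to_nat(best$par)
  structure(
    list(alpha1 = th[1], beta1 = th[2], alpha2 = th[3], beta2 = th[4],
         w = th[5], loglik = -best$value, converged = best$converged,
         n_pairs = length(a),
         trace = data.frame(start = seq_along(vals), nll = vals)),
    class = "gps_prior"
  )
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(
    "MGPS two-gamma prior: w = %.3f, G(%.3f, %.3f) + G(%.3f, %.3f)\n",
    x$w, x$alpha1, x$beta1, x$alpha2, x$beta2))
  cat(sprintf("  prior mean %.3f; marginal loglik %.3f on %d pairs\n",
              gps_prior_mean(x), x$loglik, x$n_pairs))
  invisible(x)
}

#' @rdname gps_fit
#' @param prior a `gps_prior`.
#' @export
gps_prior_mean <- function(prior) {
  prior$w * prior$alpha1 / prior$beta1 +
    (1 - prior$w) * prior$alpha2 / prior$beta2
}

# Posterior mixture for one (a, E): gamma components (alpha_k + a,
# beta_k + E) with weights Q_k proportional to w_k x marginal NB_k(a).
gps_posterior <- function(a, e, prior) {
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  lw <- c(log(prior$w) + l1, log(1 - prior$w) + l2)
  q <- exp(lw - max(lw))
  q <- q / sum(q)
  list(q1 = q[1], q2 = q[2],
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' Empirical-Bayes geometric mean and its 5th percentile
#'
#' Under the fitted two-gamma prior the posterior of the relative
#' reporting rate is again a two-component gamma mixture; `EBGM =
#' exp(E[log lambda])` via the digamma identity `E[log lambda] =
#' digamma(shape) - log(rate)` per component, and `EB05` is the posterior
#' 5th percentile found by bisection on the mixture CDF.
#'
#' @param a,e observed and expected count (vectorized).
#' @param prior a `gps_prior` (fitted or constructed by hand).
#' @return data.frame `ebgm`, `eb05`, `eb95`, `defined`.
#' @export
ebgm_stat <- function(a, e, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  one <- function(ai, ei) {
    if (is.na(ei) || ei <= 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- gps_posterior(ai, ei, prior)
    elog <- p$q1 * (digamma(p$shape1) - log(p$rate1)) +
      p$q2 * (digamma(p$shape2) - log(p$rate2))
    cdf <- function(x) {
      p$q1 * stats::pgamma(x, p$shape1, rate = p$rate1) +
        p$q2 * stats::pgamma(x, p$shape2, rate = p$rate2)
    }
    c(exp(elog), mix_quantile(cdf, 0.05), mix_quantile(cdf, 0.95))
  }
  out <- t(mapply(one, a, e))
  data.frame(ebgm = out[, 1], eb05 = out[, 2], eb95 = out[, 3],
             defined = !is.na(out[, 1]))
}

# quantile of a mixture CDF by bracketed bisection
mix_quantile <- function(cdf, p, tol = 1e-9) {
  hi <- 1
  while (cdf(hi) < p) hi <- hi * 2
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Per-method signal flags and four-method consensus
#'
#' Default criteria (the conventional published thresholds; all
#' configurable):
#' ROR: `a >= 3` and `ror_lo95 > 1`; PRR: `PRR >= 2`, `chi2 >= 4`,
#' `a >= 3`; BCPNN: `IC025 > 0`; EBGM: `EB05 > 2`.  The consensus signal
#' is the conjunction of all four; any undefined statistic forces the
#' consensus false with a reason code.  The `a >= 3` floors always use the
#' raw count, never the continuity-corrected one.
#'
#' @param stats_df data.frame holding columns `a`, `ror_lo95`, `prr`,
#'   `chi2`, `ic025`, `eb05` (as produced by [signal_table()]).
#' @param thresholds named list overriding any of `ror_min_a`,
#'   `ror_lo95_gt`, `prr_min`, `chi2_min`, `prr_min_a`, `ic025_gt`,
#'   `eb05_gt`.
#' @return data.frame of logical flags `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_ebgm`, `consensus`, plus `reason` for
#'   non-signals.
#' @export
call_signals <- function(stats_df, thresholds = list()) {
  th <- utils::modifyList(
    list(ror_min_a = 3, ror_lo95_gt = 1, prr_min = 2, chi2_min = 4,
         prr_min_a = 3, ic025_gt = 0, eb05_gt = 2),
    thresholds
  )
  f_ror <- !is.na(stats_df$ror_lo95) & stats_df$a >= th$ror_min_a &
    stats_df$ror_lo95 > th$ror_lo95_gt
  f_prr <- !is.na(stats_df$prr) & stats_df$prr >= th$prr_min &
    stats_df$chi2 >= th$chi2_min & stats_df$a >= th$prr_min_a
  f_ic <- !is.na(stats_df$ic025) & stats_df$ic025 > th$ic025_gt
  f_eb <- !is.na(stats_df$eb05) & stats_df$eb05 > th$eb05_gt
  undef <- is.na(stats_df$ror_lo95) | is.na(stats_df$prr) |
    is.na(stats_df$ic025) | is.na(stats_df$eb05)
  consensus <- f_ror & f_prr & f_ic & f_eb & !undef
  reason <- ifelse(undef, "undefined_statistic",
                   ifelse(consensus, "", "below_threshold"))
  data.frame(flag_ror = f_ror, flag_prr = f_prr, flag_bcpnn = f_ic,
             flag_ebgm = f_eb, consensus = consensus, reason = reason,
             stringsAsFactors = FALSE)
}

#' Full disproportionality table for the target event
#'
#' Selects target drugs, builds every 2x2 table, fits the MGPS prior on
#' the target drugs' (observed, expected) pairs, computes all four
#' statistics, and calls per-method and consensus signals.  Rows are
#' sorted by ROR descending (the conventional presentation).
#'
#' @inheritParams select_target_drugs
#' @param thresholds passed to [call_signals()].
#' @param prior optional pre-fitted `gps_prior`; fitted from the data when
#'   `NULL`.
#' @return data.frame with one row per target drug: counts, the four
#'   statistics with interval bounds, flags and consensus.
#' @export
signal_table <- function(data, target_pt, min_cases = 10,
                         target_code = NULL, thresholds = list(),
                         prior = NULL) {
  targets <- select_target_drugs(data, target_pt, min_cases, target_code)
  if (!nrow(targets)) {
    return(data.frame(drug = character(0)))
  }
  tab <- build_tables(data, targets$drug, target_pt, target_code)
  ror <- ror_stat(tab$a, tab$b, tab$c, tab$d)
  prr <- prr_stat(tab$a, tab$b, tab$c, tab$d)
  ic <- bcpnn_ic(tab$a, tab$b, tab$c, tab$d)
  if (is.null(prior)) prior <- gps_fit(tab$a, ic$expected)
  eb <- ebgm_stat(tab$a, ic$expected, prior)
  out <- cbind(
    tab,
    data.frame(cases = targets$cases[match(tab$drug, targets$drug)]),
    ror[c("ror", "ror_lo95", "ror_hi95")],
    prr[c("prr", "chi2")],
    ic[c("expected", "ic", "ic025")],
    eb[c("ebgm", "eb05")]
  )
  out <- cbind(out, call_signals(out, thresholds))
  out <- out[order(-out$ror, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gps_prior") <- prior
  out
}
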