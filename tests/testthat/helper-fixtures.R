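# Shared fixtures, built in code at test time.

# Write one handcrafted quarter of FAERS-dialect files and return the
# directory.  `demo`, `drug`, `reac`, `ther`, `indi` are data.frames whose
# columns are written verbatim ($-delimited).
write_fixture_quarter <- function(dir, quarter, demo, drug, reac, ther,
                                  indi) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  put <- function(df, stem) {
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                              sep = "$")))
    writeLines(lines, file.path(dir, paste0(stem, quarter, ".txt")))
  }
  put(demo, "DEMO"); put(drug, "DRUG"); put(reac, "REAC")
  put(ther, "THER"); put(indi, "INDI")
  invisible(dir)
}

# A hand-enumerable 10-report quarter exercising every cohort filter:
#   reports 1..10 (caseid 101..110, primaryid = caseid*10 + 1)
#   occupations: MD MD MD PH OT RN CN LW MD <blank>
#   target-event reports: 1 2 3 4 5 6 9 (PT "Pulmonary Edema")
#   DRUGX: PS on 1 2 3 4 9 10; C on 5.  DRUGY: PS on 5 6 7 8.
#   report 9's suspect-drug indication is the target PT (pre-existing).
ten_report_fixture <- function(dir = tempfile("fixture")) {
  pid <- (101:110) * 10 + 1
  demo <- data.frame(
    primaryid = pid, caseid = 101:110,
    event_dt = "20150215", fda_dt = "20150301",
    age = c(72, 30, 45, 80, 66, 25, 50, 61, 70, 40), age_cod = "YR",
    sex = c("F", "M", "F", "M", "F", "M", "F", "M", "F", "M"),
    wt = 70, wt_cod = "KG",
    occp_cod = c("MD", "MD", "MD", "PH", "OT", "RN", "CN", "LW", "MD", "")
  )
  ps_x <- c(1, 2, 3, 4, 9, 10)
  drug <- rbind(
    data.frame(primaryid = pid[ps_x], drug_seq = 1, role_cod = "PS",
               drugname = "DRUGX"),
    data.frame(primaryid = pid[5], drug_seq = 2, role_cod = "C",
               drugname = "DRUGX"),
    data.frame(primaryid = pid[c(5, 6, 7, 8)], drug_seq = 1,
               role_cod = "PS", drugname = "DRUGY")
  )
  ev <- c(1, 2, 3, 4, 5, 6, 9)
  reac <- rbind(
    data.frame(primaryid = pid[ev], pt = "Pulmonary Edema",
               pt_cod = 10037375),
    data.frame(primaryid = pid, pt = "Nausea", pt_cod = 10028813)
  )
  ther <- data.frame(primaryid = pid, dsg_drug_seq = 1,
                     start_dt = "20150110")
  indi <- data.frame(primaryid = pid[9], indi_drug_seq = 1,
                     indi_pt = "Pulmonary edema")
  write_fixture_quarter(dir, "2015Q1", demo, drug, reac, ther, indi)
}

# Expand a 2x2 table into individual-level outcome/exposure rows.
expand_table <- function(a, b, c, d) {
  data.frame(
    y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c, d))
  )
}

# Independent quadrature oracle for the gamma-mixture posterior of the
# relative reporting rate: returns EBGM and EB05 by numerical integration
# of the unnormalized posterior density.
quadrature_ebgm <- function(a, e, prior) {
  dens <- function(l) {
    (prior$w * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$w) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)) *
      stats::dpois(a, l * e)
  }
  # finite integration bound far beyond any posterior mass (the posterior
  # components are gamma(alpha_k + a, beta_k + E))
  ub <- max(stats::qgamma(1 - 1e-13, prior$alpha1 + a,
                          rate = prior$beta1 + e),
            stats::qgamma(1 - 1e-13, prior$alpha2 + a,
                          rate = prior$beta2 + e))
  z <- stats::integrate(dens, 0, ub, rel.tol = 1e-10,
                        subdivisions = 500L)$value
  elog <- stats::integrate(function(l) log(l) * dens(l) / z, 0, ub,
                           rel.tol = 1e-9, subdivisions = 500L)$value
  q05 <- stats::uniroot(function(q) {
    stats::integrate(dens, 0, q, rel.tol = 1e-10,
                     subdivisions = 500L)$value / z - 0.05
  }, c(1e-12, ub), tol = 1e-10)$root
  list(ebgm = exp(elog), eb05 = q05)
}

# Fixed small prior used by several EBGM checks.
test_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                 w = 1 / 3, loglik = NA, converged = TRUE, n_pairs = 0),
            class = "gps_prior")
}
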