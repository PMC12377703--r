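# Synthetic FAERS generator: writes quarterly $-delimited DEMO/DRUG/REAC/
# THER/INDI files from a generative model with a known ground-truth
# manifest, so every pipeline stage can be exercised and checked against
# truth without the multi-gigabyte public download.
#
# Generative model, per case:
#   demographics  age ~ N(62, 18) clipped to [1, 95]; sex M/F/unknown;
#                 weight ~ N(80, 15) male / N(67, 14) female, kg.
#   exposure      exactly one primary-suspect drug, drawn from the catalog
#                 with weights  p_d * exp(g_age,d * age_z + g_male,d * male)
#                 (the g's create demographic channeling = confounding);
#                 plus Poisson-many concomitant drugs (role C).
#   event         target PT occurs with probability
#                 plogis(qlogis(p0) + log OR_d + b_age age_z + b_male male
#                        + b_wt weight_z)  -- a logistic model, so the
#                 injected per-drug effects are odds ratios (~relative
#                 risks at these background rates).
#   reactions     the target PT when the event fires, plus 1+Pois(0.8)
#                 background PTs from a Zipf-weighted catalog.
#   onset         days from therapy start to event ~ logNormal(mu_d +
#                 age_shift_d * 1[age >= 65] + sex_shift_d * male, sigma_d).
#   noise         a fraction of cases is emitted as two case versions
#                 (distinct primaryid, shared caseid); a fraction of dates
#                 is degraded to month/year precision or dropped; ages and
#                 weights are written in mixed FAERS unit codes.

.noise_pts <- c(
  "Nausea", "Headache", "Dizziness", "Vomiting", "Fatigue", "Diarrhoea",
  "Rash", "Pruritus", "Pyrexia", "Dyspnoea", "Cough", "Insomnia",
  "Anaemia", "Hypotension", "Hypertension", "Tachycardia", "Bradycardia",
  "Syncope", "Tremor", "Arthralgia", "Myalgia", "Back pain",
  "Abdominal pain", "Constipation", "Decreased appetite", "Weight decreased",
  "Oedema peripheral", "Chest pain", "Palpitations", "Malaise",
  "Asthenia", "Somnolence", "Confusional state", "Anxiety", "Depression",
  "Renal impairment", "Hepatotoxicity", "Thrombocytopenia", "Neutropenia",
  "Leukopenia", "Hyperkalaemia", "Hyponatraemia", "Hypoglycaemia",
  "Hyperglycaemia", "Alopecia", "Dry mouth", "Dysgeusia", "Paraesthesia",
  "Hypoaesthesia", "Vision blurred", "Tinnitus", "Vertigo", "Epistaxis",
  "Haematuria", "Urinary retention", "Fall", "Contusion", "Pain",
  "Drug ineffective", "Device malfunction"
)

.indication_pool <- c(
  "Hypertension", "Diabetes mellitus", "Atrial fibrillation", "Pain",
  "Depression", "Rheumatoid arthritis", "Multiple myeloma",
  "Chronic myeloid leukaemia", "Pulmonary arterial hypertension",
  "Opioid overdose", "Anaesthesia", "Infection", "Asthma", "Epilepsy",
  "Hyperlipidaemia", "Osteoporosis", "Insomnia", "Anxiety"
)

#' Configuration of the synthetic-FAERS generator
#'
#' @param n_reports number of unique cases to simulate.
#' @param quarter_range inclusive pair of quarter labels.
#' @param drug_catalog data.frame with columns `name` and `prob` (marginal
#'   exposure weights; normalized internally).
#' @param background_event_prob probability of the target PT for an
#'   unexposed-reference report (all confounders at reference).
#' @param injected_effects named numeric: per-drug event odds ratio (>= 0);
#'   drugs absent from the map get 1.
#' @param confounder_spec list with `event` (named numeric `age`, `male`,
#'   `weight`: log-odds per SD age / male indicator / SD weight) and
#'   optional `exposure` data.frame (`drug`, `age`, `male`: log selection
#'   tilts creating confounding by channeling).
#' @param onset_spec data.frame (`drug`, `meanlog`, `sdlog`, `age_shift`,
#'   `sex_shift`): log-normal onset in days; shifts are added to `meanlog`
#'   for the high-age stratum / male stratum.  Drugs absent get the
#'   defaults `meanlog = log(45)`, `sdlog = 0.8`, shifts 0.
#' @param reporter_mix named probabilities over occupation codes
#'   (`MD`, `PH`, `OT`, `RN`, `CN`, `LW`).
#' @param duplicate_rate fraction of cases emitted as two case versions.
#' @param partial_date_rate fraction of therapy-start / event dates
#'   degraded below day precision (or dropped).
#' @param indication_pe_rate fraction of reports whose suspect-drug
#'   indication is the target PT itself (these are the pre-existing-
#'   diagnosis reports the cleaning stage must exclude).
#' @param concomitant_mean mean number of concomitant (role C) drug rows
#'   per report.
#' @param target_pt,target_pt_code the simulated target event.
#' @param seed integer seed; generation is deterministic given the config.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_reports,
                       quarter_range = c("2004Q1", "2024Q2"),
                       drug_catalog,
                       background_event_prob = 0.04,
                       injected_effects = c(),
                       confounder_spec = list(
                         event = c(age = 0, male = 0, weight = 0)),
                       onset_spec = NULL,
                       reporter_mix = c(MD = 0.40, PH = 0.18, OT = 0.15,
                                        RN = 0.07, CN = 0.17, LW = 0.03),
                       duplicate_rate = 0.05,
                       partial_date_rate = 0.12,
                       indication_pe_rate = 0.01,
                       concomitant_mean = 0.6,
                       target_pt = "Pulmonary Edema",
                       target_pt_code = 10037375L,
                       seed = 1L) {
  stopifnot(
    n_reports >= 1,
    is.data.frame(drug_catalog),
    all(c("name", "prob") %in% names(drug_catalog)),
    all(drug_catalog$prob > 0),
    background_event_prob > 0, background_event_prob < 1,
    all(injected_effects >= 0),
    duplicate_rate >= 0, duplicate_rate <= 1,
    partial_date_rate >= 0, partial_date_rate <= 1,
    indication_pe_rate >= 0, indication_pe_rate <= 1,
    abs(sum(reporter_mix) - 1) < 1e-8
  )
  drug_catalog$name <- normalize_drug_name(drug_catalog$name)
  drug_catalog$prob <- drug_catalog$prob / sum(drug_catalog$prob)
  eff <- rep(1, nrow(drug_catalog))
  names(eff) <- drug_catalog$name
  if (length(injected_effects)) {
    names(injected_effects) <- normalize_drug_name(names(injected_effects))
    unknown <- setdiff(names(injected_effects), drug_catalog$name)
    if (length(unknown)) {
      stop("injected_effects for drugs not in the catalog: ",
           paste(unknown, collapse = ", "))
    }
    eff[names(injected_effects)] <- injected_effects
  }
  os <- data.frame(drug = drug_catalog$name, meanlog = log(45), sdlog = 0.8,
                   age_shift = 0, sex_shift = 0, stringsAsFactors = FALSE)
  if (!is.null(onset_spec)) {
    onset_spec$drug <- normalize_drug_name(onset_spec$drug)
    if (any(onset_spec$sdlog <= 0)) stop("onset sdlog must be positive")
    i <- match(onset_spec$drug, os$drug)
    if (anyNA(i)) stop("onset_spec for drugs not in the catalog")
    for (col in c("meanlog", "sdlog", "age_shift", "sex_shift")) {
      if (col %in% names(onset_spec)) os[[col]][i] <- onset_spec[[col]]
    }
  }
  expo <- data.frame(drug = drug_catalog$name, age = 0, male = 0,
                     stringsAsFactors = FALSE)
  if (!is.null(confounder_spec$exposure)) {
    ce <- confounder_spec$exposure
    ce$drug <- normalize_drug_name(ce$drug)
    i <- match(ce$drug, expo$drug)
    if (anyNA(i)) stop("exposure confounders for drugs not in the catalog")
    if ("age" %in% names(ce)) expo$age[i] <- ce$age
    if ("male" %in% names(ce)) expo$male[i] <- ce$male
  }
  ev <- c(age = 0, male = 0, weight = 0)
  ev[names(confounder_spec$event)] <- confounder_spec$event
  structure(
    list(n_reports = as.integer(n_reports), quarter_range = quarter_range,
         drug_catalog = drug_catalog, background_event_prob =
           background_event_prob, injected_effects = eff,
         event_confounders = ev, exposure_confounders = expo,
         onset_spec = os, reporter_mix = reporter_mix,
         duplicate_rate = duplicate_rate,
         partial_date_rate = partial_date_rate,
         indication_pe_rate = indication_pe_rate,
         concomitant_mean = concomitant_mean,
         target_pt = target_pt, target_pt_code = as.integer(target_pt_code),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# degrade a vector of Dates into FAERS partial-date strings:
# keep | month | year | missing
degrade_dates <- function(dates, rate) {
  n <- length(dates)
  u <- stats::runif(n)
  full <- format(dates, "%Y%m%d")
  out <- full
  out[u < rate * 0.7] <- substr(full[u < rate * 0.7], 1, 6)
  mid <- u >= rate * 0.7 & u < rate * 0.9
  out[mid] <- substr(full[mid], 1, 4)
  out[u >= rate * 0.9 & u < rate] <- ""
  out
}

#' Generate synthetic FAERS quarterly files
#'
#' Deterministic given the config (including its seed).  Writes
#' `DEMO<q>.txt` ... `INDI<q>.txt` per quarter into `dir`, plus
#' `manifest.tsv` holding the ground truth (per-drug injected odds ratio,
#' confounding status, onset parameters and per-stratum true medians).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).  When `NULL`, no files
#'   are written and the typed dataset is returned in memory instead
#'   (element `data`), which is what replicate simulations use.
#' @return invisibly, a list: `manifest` (data.frame), `seed`, `truth`
#'   (the per-case latent table, useful for tests), and either `files` +
#'   `dir` or `data` (a `faers_data`).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_reports
  cat_n <- nrow(config$drug_catalog)
  drugs <- config$drug_catalog$name

  caseid <- 10000000 + seq_len(n)
  quarters <- quarter_seq(config$quarter_range[1], config$quarter_range[2])
  q <- sample(quarters, n, replace = TRUE)

  age <- pmin(pmax(stats::rnorm(n, 62, 18), 1), 95)
  age_z <- (age - 62) / 18
  sexc <- sample(c("M", "F", ""), n, replace = TRUE,
                 prob = c(0.52, 0.46, 0.02))
  male <- as.numeric(sexc == "M")
  weight <- ifelse(sexc == "M", stats::rnorm(n, 80, 15),
                   stats::rnorm(n, 67, 14))
  weight <- pmin(pmax(weight, 35), 160)
  weight_z <- (weight - 73) / 16

  # primary-suspect drug: Gumbel-max categorical draw with confounder tilts
  lw <- matrix(log(config$drug_catalog$prob), n, cat_n, byrow = TRUE) +
    outer(age_z, config$exposure_confounders$age) +
    outer(male, config$exposure_confounders$male)
  gumbel <- -log(-log(stats::runif(n * cat_n)))
  di <- max.col(lw + gumbel, ties.method = "first")
  ps_drug <- drugs[di]

  # target event from the logistic model
  ev <- config$event_confounders
  lp <- stats::qlogis(config$background_event_prob) +
    log(config$injected_effects[di]) +
    ev[["age"]] * age_z + ev[["male"]] * male + ev[["weight"]] * weight_z
  event <- stats::runif(n) < stats::plogis(lp)

  # onset (days), drawn for every report (non-target events also onset)
  os <- config$onset_spec[match(ps_drug, config$onset_spec$drug), ]
  mu <- os$meanlog + os$age_shift * (age >= 65) + os$sex_shift * male
  onset <- pmax(round(stats::rlnorm(n, mu, os$sdlog)), 0)

  # calendar: receipt inside the assigned quarter; event before receipt;
  # therapy start = event - onset
  qstart <- quarter_start_date(q)
  fda_date <- qstart + floor(stats::runif(n) * quarter_ndays(q))
  event_date <- fda_date - sample(0:45, n, replace = TRUE)
  start_date <- event_date - onset

  occ <- sample(names(config$reporter_mix), n, replace = TRUE,
                prob = config$reporter_mix)

  # recorded demographics in FAERS unit codes
  age_cod <- ifelse(stats::runif(n) < 0.08, "",
                    ifelse(stats::runif(n) < 0.06, "DEC", "YR"))
  age_cod[age_cod == "DEC" & age < 10] <- "YR"
  age_val <- ifelse(age_cod == "YR", as.character(round(age)),
                    ifelse(age_cod == "DEC", as.character(round(age / 10, 1)),
                           ""))
  wt_missing <- stats::runif(n) < 0.15
  wt_lbs <- stats::runif(n) < 0.45
  wt_cod <- ifelse(wt_missing, "", ifelse(wt_lbs, "LBS", "KG"))
  wt_val <- ifelse(wt_missing, "",
                   ifelse(wt_lbs, as.character(round(weight / 0.45359237, 1)),
                          as.character(round(weight, 1))))

  primaryid <- caseid * 10 + 1

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid,
    event_dt = degrade_dates(event_date, config$partial_date_rate),
    fda_dt = format(fda_date, "%Y%m%d"),
    age = age_val, age_cod = age_cod, sex = sexc,
    wt = wt_val, wt_cod = wt_cod, occp_cod = occ,
    quarter = q, stringsAsFactors = FALSE
  )

  # drug rows: PS (seq 1) + Poisson-many concomitants
  indi_pe <- stats::runif(n) < config$indication_pe_rate
  indication <- ifelse(indi_pe, config$target_pt,
                       ifelse(stats::runif(n) < 0.7,
                              sample(.indication_pool, n, replace = TRUE),
                              ""))
  drug_rows <- data.frame(
    primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
    drugname = ps_drug, indi = indication, stringsAsFactors = FALSE
  )
  ncon <- stats::rpois(n, config$concomitant_mean)
  if (sum(ncon) > 0) {
    rid <- rep(seq_len(n), ncon)
    conc <- data.frame(
      primaryid = primaryid[rid],
      drug_seq = unlist(lapply(ncon[ncon > 0], function(k) 1L + seq_len(k))),
      role_cod = "C",
      drugname = sample(drugs, sum(ncon), replace = TRUE),
      indi = "", stringsAsFactors = FALSE
    )
    drug_rows <- rbind(drug_rows, conc)
  }

  # reactions: Zipf-weighted background PTs, plus the target when it fires
  zipf <- (1 / seq_along(.noise_pts))
  nnoise <- 1L + stats::rpois(n, 0.8)
  rid <- rep(seq_len(n), nnoise)
  reac_rows <- data.frame(
    primaryid = primaryid[rid],
    pt = sample(.noise_pts, sum(nnoise), replace = TRUE, prob = zipf),
    stringsAsFactors = FALSE
  )
  reac_rows$pt_cod <- as.character(10000000L + match(reac_rows$pt, .noise_pts))
  if (any(event)) {
    reac_rows <- rbind(
      data.frame(primaryid = primaryid[event], pt = config$target_pt,
                 pt_cod = as.character(config$target_pt_code),
                 stringsAsFactors = FALSE),
      reac_rows
    )
  }

  ther_rows <- data.frame(
    primaryid = primaryid, dsg_drug_seq = 1L,
    start_dt = degrade_dates(start_date, config$partial_date_rate),
    stringsAsFactors = FALSE
  )

  # duplicate case versions: an earlier version (primaryid ...1 stays the
  # later one? no -- emit version 2 as the later record to keep) --------
  # convention: the kept version is the max primaryid; duplicates add a
  # *lower* extra version (caseid*10 + 0) of the same case.
  dup <- stats::runif(n) < config$duplicate_rate
  if (any(dup)) {
    dd <- which(dup)
    dup_id <- caseid[dd] * 10
    demo_dup <- demo[dd, , drop = FALSE]
    demo_dup$primaryid <- dup_id
    demo_dup$wt <- ""   # earlier, less complete version
    demo_dup$wt_cod <- ""
    demo <- rbind(demo, demo_dup)
    d2 <- drug_rows[drug_rows$primaryid %in% primaryid[dd], , drop = FALSE]
    d2$primaryid <- caseid[match(d2$primaryid, primaryid)] * 10
    drug_rows <- rbind(drug_rows, d2)
    r2 <- reac_rows[reac_rows$primaryid %in% primaryid[dd], , drop = FALSE]
    r2$primaryid <- caseid[match(r2$primaryid, primaryid)] * 10
    reac_rows <- rbind(reac_rows, r2)
    t2 <- ther_rows[ther_rows$primaryid %in% primaryid[dd], , drop = FALSE]
    t2$primaryid <- caseid[match(t2$primaryid, primaryid)] * 10
    ther_rows <- rbind(ther_rows, t2)
  }

  manifest <- ground_truth_manifest(config)
  truth <- data.frame(caseid = caseid, drug = ps_drug, event = event,
                      age = age, male = male, weight = weight,
                      onset = onset, quarter = q, occp_cod = occ,
                      stringsAsFactors = FALSE)

  if (is.null(dir)) {
    indi_rows <- drug_rows[nzchar(drug_rows$indi),
                           c("primaryid", "drug_seq", "indi")]
    names(indi_rows) <- c("primaryid", "indi_drug_seq", "indi_pt")
    data <- tables_to_faers(
      demo, stats::setNames(drug_rows[c("primaryid", "drug_seq", "role_cod",
                                        "drugname")],
                            c("primaryid", "drug_seq", "role_cod",
                              "drugname")),
      reac_rows, ther_rows, indi_rows, quarter = demo$quarter
    )
    return(invisible(list(manifest = manifest, data = data,
                          seed = config$seed, truth = truth)))
  }

  # write per-quarter files
  qmap <- stats::setNames(demo$quarter, demo$primaryid)
  drug_rows$quarter <- unname(qmap[as.character(drug_rows$primaryid)])
  reac_rows$quarter <- unname(qmap[as.character(reac_rows$primaryid)])
  ther_rows$quarter <- unname(qmap[as.character(ther_rows$primaryid)])
  files <- character(0)
  for (qq in sort(unique(demo$quarter))) {
    dsub <- demo[demo$quarter == qq,
                 c("primaryid", "caseid", "event_dt", "fda_dt", "age",
                   "age_cod", "sex", "wt", "wt_cod", "occp_cod")]
    dr <- drug_rows[drug_rows$quarter == qq,
                    c("primaryid", "drug_seq", "role_cod", "drugname")]
    re <- reac_rows[reac_rows$quarter == qq,
                    c("primaryid", "pt", "pt_cod")]
    th <- ther_rows[ther_rows$quarter == qq,
                    c("primaryid", "dsg_drug_seq", "start_dt")]
    ind <- drug_rows[drug_rows$quarter == qq & nzchar(drug_rows$indi),
                     c("primaryid", "drug_seq", "indi")]
    names(ind) <- c("primaryid", "indi_drug_seq", "indi_pt")
    paths <- file.path(dir, paste0(c("DEMO", "DRUG", "REAC", "THER", "INDI"),
                                   qq, ".txt"))
    write_dollar_table(dsub, paths[1])
    write_dollar_table(dr, paths[2])
    write_dollar_table(re, paths[3])
    write_dollar_table(th, paths[4])
    write_dollar_table(ind, paths[5])
    files <- c(files, paths)
  }

  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, files = files, dir = dir,
                 seed = config$seed, truth = truth))
}

#' Ground-truth manifest implied by a generator config
#'
#' @param config a [sim_config()].
#' @return data.frame keyed exactly by the drug catalog: injected odds
#'   ratio, confounding tilts, confounded flag (non-zero channeling with a
#'   null drug effect), onset parameters, and per-stratum true onset
#'   medians (reference = female / the named stratum).
#' @export
ground_truth_manifest <- function(config) {
  os <- config$onset_spec
  data.frame(
    drug = config$drug_catalog$name,
    exposure_prob = config$drug_catalog$prob,
    true_or = unname(config$injected_effects),
    exposure_age_tilt = config$exposure_confounders$age,
    exposure_male_tilt = config$exposure_confounders$male,
    confounded = (config$exposure_confounders$age != 0 |
                    config$exposure_confounders$male != 0),
    meanlog = os$meanlog, sdlog = os$sdlog,
    age_shift = os$age_shift, sex_shift = os$sex_shift,
    true_median_age_low = exp(os$meanlog),
    true_median_age_high = exp(os$meanlog + os$age_shift),
    true_median_male = exp(os$meanlog + os$sex_shift),
    true_median_female = exp(os$meanlog),
    seed = config$seed,
    stringsAsFactors = FALSE
  )
}

#' The bundled scenario shaped after published DIPE findings
#'
#' A 45-drug catalog: five strong injected signals (odds ratios 6--12,
#' echoing the naloxone / dasatinib / nifedipine / anti-thymocyte-globulin
#' pattern), a methadone-like moderate signal, three weak signals, one
#' age-confounded null (a pioglitazone-shaped drug channeled to the
#' elderly while age independently raises the event risk), and 35 true
#' nulls; several drugs carry short onsets (median ~12 days) and two carry
#' built-in stratum shifts (dasatinib-like: longer onset in the elderly;
#' nifedipine-like: longer onset in males).
#'
#' @param n_reports simulated unique cases (default 40000).
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
paper_shaped_scenario <- function(n_reports = 40000, seed = 1L) {
  strong <- c("NALOXONE", "DASATINIB", "NIFEDIPINE",
              "ANTI-THYMOCYTE GLOBULIN")
  weak <- c("FENTANYL", "METHADONE", "ROSIGLITAZONE", "BOSENTAN")
  confounded <- "PIOGLITAZONE"
  shifted <- c("DILTIAZEM", "TADALAFIL")
  nulls <- c(
    "AMOXICILLIN", "LISINOPRIL", "ATORVASTATIN", "METFORMIN", "OMEPRAZOLE",
    "LEVOTHYROXINE", "SERTRALINE", "IBUPROFEN", "GABAPENTIN", "LOSARTAN",
    "HYDROCHLOROTHIAZIDE", "SIMVASTATIN", "AMLODIPINE", "ALPRAZOLAM",
    "AZITHROMYCIN", "CIPROFLOXACIN", "PREDNISONE", "WARFARIN", "CLOPIDOGREL",
    "PANTOPRAZOLE", "DULOXETINE", "VENLAFAXINE", "CETIRIZINE", "MONTELUKAST",
    "RANITIDINE", "TAMSULOSIN", "FINASTERIDE", "ALLOPURINOL", "CELECOXIB",
    "ESCITALOPRAM", "FLUOXETINE", "PAROXETINE", "RISPERIDONE", "QUETIAPINE"
  )
  name <- c(strong, weak, confounded, shifted, nulls)
  # Effect drugs are kept rare, as in the real database where risk drugs
  # are a sliver of all reports: every drug's adjusted regression uses all
  # other reports as its comparator, so prevalent strong signals would
  # contaminate the reference group and bias the null drug's adjusted OR
  # downward.
  # the confounded drug's nominal weight is small because the age tilt
  # renormalizes per report and raises its realized prevalence ~6-fold
  prob <- c(rep(0.0018, length(strong)), rep(0.0027, length(weak)),
            0.0013, rep(0.024, length(shifted)), rep(0.024, length(nulls)))
  effects <- c(
    NALOXONE = 12, DASATINIB = 10, NIFEDIPINE = 9,
    `ANTI-THYMOCYTE GLOBULIN` = 8,
    FENTANYL = 3, METHADONE = 3, ROSIGLITAZONE = 2.5, BOSENTAN = 2
  )
  onset <- data.frame(
    drug = c("NALOXONE", "METHADONE", "NIFEDIPINE",
             "ANTI-THYMOCYTE GLOBULIN", "DASATINIB", "FENTANYL",
             "DILTIAZEM", "TADALAFIL", "PIOGLITAZONE"),
    meanlog = c(log(3), log(12), log(12), log(12), log(40), log(8),
                log(12), log(25), log(60)),
    sdlog = c(0.9, 0.8, 0.8, 0.8, 0.8, 0.9, 0.8, 0.8, 0.8),
    age_shift = c(0, 0, 0, 0, 0.8, -0.8, 1.2, 0, 0.5),
    sex_shift = c(0, 0, 0.8, 0, 0, -0.6, 0, -1.2, 0.4),
    stringsAsFactors = FALSE
  )
  sim_config(
    n_reports = n_reports,
    quarter_range = c("2004Q1", "2024Q2"),
    drug_catalog = data.frame(name = name, prob = prob,
                              stringsAsFactors = FALSE),
    background_event_prob = 0.04,
    injected_effects = effects,
    confounder_spec = list(
      event = c(age = 0.7, male = 0.15, weight = 0.1),
      exposure = data.frame(drug = confounded, age = 2.5, male = 0,
                            stringsAsFactors = FALSE)
    ),
    onset_spec = onset,
    duplicate_rate = 0.05,
    partial_date_rate = 0.12,
    indication_pe_rate = 0.01,
    seed = seed
  )
}
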