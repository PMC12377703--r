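# FAERS-schema quarterly ASCII ingestion: $-delimited DEMO/DRUG/REAC/THER/
# INDI tables -> a typed in-memory dataset, plus the cohort filters used in
# spontaneous-report signal detection (deduplication, reporter occupation,
# pre-existing-diagnosis exclusion).

#' Column layouts for FAERS ASCII dialects
#'
#' FAERS changed its quarterly ASCII layout in 2012Q4: earlier ("legacy")
#' files key rows by `ISR`/`CASE`, later ("current") files by
#' `primaryid`/`caseid`.  A dialect names each table's key columns and the
#' reporter-occupation code map.  Registered nurses have no dedicated
#' occupation code in most FAERS years, so `RN` folds into
#' other-health-professional by default; the map is user-configurable.
#'
#' @param name `"current"` or `"legacy"`.
#' @param occupation_map named character vector mapping `occp_cod` values to
#'   occupation labels (`physician`, `pharmacist`,
#'   `other-health-professional`, `nurse`, `lawyer`, `consumer`); codes
#'   absent from the map become `"unknown"`.
#' @return a list describing per-table column names, usable by
#'   [parse_faers_quarter()] and [write_faers_quarter()].
#' @export
faers_dialect <- function(name = c("current", "legacy"),
                          occupation_map = NULL) {
  name <- match.arg(name)
  if (is.null(occupation_map)) {
    occupation_map <- c(
      MD = "physician", PH = "pharmacist", OT = "other-health-professional",
      RN = "other-health-professional", HP = "other-health-professional",
      LW = "lawyer", CN = "consumer"
    )
  }
  id <- if (name == "current") "primaryid" else "isr"
  case <- if (name == "current") "caseid" else "case"
  sexcol <- if (name == "current") "sex" else "gndr_cod"
  list(
    name = name,
    id = id,
    demo = list(
      required = c(id, case, "event_dt", "fda_dt", "age", "age_cod",
                   sexcol, "wt", "wt_cod", "occp_cod"),
      sex_col = sexcol
    ),
    drug = list(required = c(id, "drug_seq", "role_cod", "drugname")),
    reac = list(required = c(id, "pt"), optional = "pt_cod"),
    ther = list(required = c(id, "dsg_drug_seq", "start_dt")),
    indi = list(required = c(id, "indi_drug_seq", "indi_pt")),
    occupation_map = occupation_map
  )
}

# Read one $-delimited table; all columns as character.  Missing mandatory
# column is a configuration error naming the column; an empty file yields
# an empty table with a warning.
read_dollar_table <- function(path, required, optional = character(0)) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty FAERS table: ", path)
    out <- as.data.frame(
      matrix(character(0), 0, length(c(required, optional)),
             dimnames = list(NULL, c(required, optional))),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  tab <- utils::read.table(path,
    sep = "$", header = TRUE, quote = "", comment.char = "",
    stringsAsFactors = FALSE, colClasses = "character",
    na.strings = character(0), fill = TRUE
  )
  names(tab) <- tolower(names(tab))
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("FAERS table ", basename(path),
         " is missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  for (col in setdiff(optional, names(tab))) tab[[col]] <- NA_character_
  tab
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

map_occupation <- function(code, map) {
  out <- unname(map[toupper(trimws(code))])
  out[is.na(out)] <- "unknown"
  out
}

map_sex <- function(code) {
  code <- toupper(trimws(code))
  ifelse(code == "F", "female", ifelse(code == "M", "male", "unknown"))
}

#' Parse one FAERS quarter into a typed dataset
#'
#' Reads the five $-delimited tables of a single quarterly release.  Each
#' input line becomes one typed row; unparseable numeric fields become
#' missing values, never errors.  Drug indications (INDI) are joined onto
#' the drug table by `(primaryid, drug_seq)`.
#'
#' @param demo_file,drug_file,reac_file,ther_file,indi_file paths to the
#'   quarter's tables.
#' @param quarter quarter label, e.g. `"2015Q2"`.
#' @param dialect a [faers_dialect()].
#' @return a `faers_data` object: list of data.frames `reports`, `drugs`,
#'   `reactions`, `therapies`, and a `provenance` log.
#' @export
parse_faers_quarter <- function(demo_file, drug_file, reac_file, ther_file,
                                indi_file, quarter,
                                dialect = faers_dialect()) {
  demo <- read_dollar_table(demo_file, dialect$demo$required)
  drug <- read_dollar_table(drug_file, dialect$drug$required)
  reac <- read_dollar_table(reac_file, dialect$reac$required,
                            dialect$reac$optional)
  ther <- read_dollar_table(ther_file, dialect$ther$required)
  indi <- read_dollar_table(indi_file, dialect$indi$required)
  tables_to_faers(demo, drug, reac, ther, indi, quarter, dialect)
}

# Typed conversion of raw (character) FAERS tables; `quarter` may be a
# scalar label or a per-demo-row vector.
tables_to_faers <- function(demo, drug, reac, ther, indi, quarter,
                            dialect = faers_dialect()) {
  id <- dialect$id
  ev <- parse_partial_date(demo$event_dt)
  fda <- parse_partial_date(demo$fda_dt)
  reports <- data.frame(
    primaryid = as_num(demo[[id]]),
    caseid = as_num(demo[[if (dialect$name == "current") "caseid" else "case"]]),
    quarter = if (length(quarter) == 1L) rep(quarter, nrow(demo)) else quarter,
    occupation = map_occupation(demo$occp_cod, dialect$occupation_map),
    age_years = convert_age(demo$age, demo$age_cod),
    sex = map_sex(demo[[dialect$demo$sex_col]]),
    weight_kg = convert_weight(demo$wt, demo$wt_cod),
    event_date = ev$date,
    event_precision = ev$precision,
    report_year = as_int(substr(fda$date, 1, 4)),
    stringsAsFactors = FALSE
  )

  drugs <- data.frame(
    primaryid = as_num(drug[[id]]),
    seq = as_int(drug$drug_seq),
    name = normalize_drug_name(drug$drugname),
    role = toupper(trimws(drug$role_cod)),
    stringsAsFactors = FALSE
  )
  # attach indication PT by (primaryid, seq); first indication wins
  if (nrow(indi)) {
    key <- paste(as_num(indi[[id]]), as_int(indi$indi_drug_seq))
    first <- !duplicated(key)
    ind_map <- stats::setNames(trimws(indi$indi_pt)[first], key[first])
    drugs$indication_pt <- unname(ind_map[paste(drugs$primaryid, drugs$seq)])
    drugs$indication_pt[drugs$indication_pt == ""] <- NA_character_
  } else {
    drugs$indication_pt <- NA_character_
  }

  reactions <- data.frame(
    primaryid = as_num(reac[[id]]),
    pt = trimws(reac$pt),
    pt_code = as_int(reac$pt_cod),
    stringsAsFactors = FALSE
  )
  reactions <- reactions[!is.na(reactions$pt) & nzchar(reactions$pt), ,
                         drop = FALSE]

  st <- parse_partial_date(ther$start_dt)
  therapies <- data.frame(
    primaryid = as_num(ther[[id]]),
    drug_seq = as_int(ther$dsg_drug_seq),
    start_date = st$date,
    start_precision = st$precision,
    stringsAsFactors = FALSE
  )

  out <- faers_data(reports, drugs, reactions, therapies)
  step <- if (length(quarter) == 1L) paste0("parse:", quarter) else "parse"
  add_provenance(out, step, nrow(demo), nrow(reports),
                 kv_string(c(drug_rows = nrow(drugs),
                             reac_rows = nrow(reactions),
                             ther_rows = nrow(therapies))))
}

#' Construct a FAERS dataset container
#'
#' @param reports,drugs,reactions,therapies data.frames as produced by
#'   [parse_faers_quarter()].
#' @param provenance optional existing provenance log.
#' @return object of class `faers_data`.
#' @export
faers_data <- function(reports, drugs, reactions, therapies,
                       provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- data.frame(step = character(0), rows_in = integer(0),
                             rows_out = integer(0), detail = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         therapies = therapies, provenance = provenance),
    class = "faers_data"
  )
}

#' @export
print.faers_data <- function(x, ...) {
  cat("FAERS dataset:", nrow(x$reports), "reports,",
      nrow(x$drugs), "drug rows,", nrow(x$reactions), "reaction rows,",
      nrow(x$therapies), "therapy rows\n")
  if (nrow(x$provenance)) {
    cat("provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("  %-28s %8d -> %8d  %s\n", x$provenance$step[i],
                  x$provenance$rows_in[i], x$provenance$rows_out[i],
                  x$provenance$detail[i]))
    }
  }
  invisible(x)
}

add_provenance <- function(data, step, rows_in, rows_out, detail = "") {
  data$provenance <- rbind(
    data$provenance,
    data.frame(step = step, rows_in = as.integer(rows_in),
               rows_out = as.integer(rows_out), detail = detail,
               stringsAsFactors = FALSE)
  )
  data
}

# Drop child rows whose primaryid no longer exists in reports.
restrict_children <- function(data) {
  keep <- data$reports$primaryid
  data$drugs <- data$drugs[data$drugs$primaryid %in% keep, , drop = FALSE]
  data$reactions <-
    data$reactions[data$reactions$primaryid %in% keep, , drop = FALSE]
  data$therapies <-
    data$therapies[data$therapies$primaryid %in% keep, , drop = FALSE]
  rownames(data$drugs) <- rownames(data$reactions) <-
    rownames(data$therapies) <- NULL
  data
}

#' Combine parsed quarters into one dataset
#'
#' @param ... `faers_data` objects (or a single list of them).
#' @return one `faers_data` with concatenated tables and provenance.
#' @export
bind_faers <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "faers_data")) {
    parts <- parts[[1]]
  }
  faers_data(
    do.call(rbind, lapply(parts, `[[`, "reports")),
    do.call(rbind, lapply(parts, `[[`, "drugs")),
    do.call(rbind, lapply(parts, `[[`, "reactions")),
    do.call(rbind, lapply(parts, `[[`, "therapies")),
    do.call(rbind, lapply(parts, `[[`, "provenance"))
  )
}

#' Read a directory of FAERS quarterly files
#'
#' Expects files named `DEMO<q>.txt`, `DRUG<q>.txt`, `REAC<q>.txt`,
#' `THER<q>.txt`, `INDI<q>.txt` for each quarter label `<q>` (the layout
#' [generate_faers()] writes).
#'
#' @param dir directory holding the quarterly files.
#' @param quarters quarter labels to read; default: every quarter with a
#'   DEMO file present.
#' @inheritParams parse_faers_quarter
#' @return a combined `faers_data`.
#' @export
read_faers <- function(dir, quarters = NULL, dialect = faers_dialect()) {
  if (is.null(quarters)) {
    demo <- list.files(dir, pattern = "^DEMO[0-9]{4}Q[1-4]\\.txt$")
    quarters <- sort(sub("^DEMO([0-9]{4}Q[1-4])\\.txt$", "\\1", demo))
  }
  if (!length(quarters)) stop("no FAERS quarterly files found in ", dir)
  parts <- lapply(quarters, function(q) {
    parse_faers_quarter(
      file.path(dir, paste0("DEMO", q, ".txt")),
      file.path(dir, paste0("DRUG", q, ".txt")),
      file.path(dir, paste0("REAC", q, ".txt")),
      file.path(dir, paste0("THER", q, ".txt")),
      file.path(dir, paste0("INDI", q, ".txt")),
      quarter = q, dialect = dialect
    )
  })
  bind_faers(parts)
}

#' Keep one report per case
#'
#' FAERS cases are resubmitted as corrected versions sharing a `caseid`;
#' counting each version would double-count cases.  Retains the version
#' with the highest `primaryid` per case (FDA guidance: the latest case
#' version), breaking improbable ties by latest quarter then latest report
#' year.
#'
#' @param data a `faers_data`.
#' @return the dataset with exactly one report per `caseid`; child rows of
#'   dropped versions removed; a `deduplicate` provenance line appended.
#' @export
deduplicate_reports <- function(data) {
  r <- data$reports
  n_in <- nrow(r)
  if (n_in) {
    qidx <- quarter_index(r$quarter)
    yr <- ifelse(is.na(r$report_year), -1L, r$report_year)
    ord <- order(r$caseid, -r$primaryid, -qidx, -yr)
    r <- r[ord, , drop = FALSE]
    r <- r[!duplicated(r$caseid), , drop = FALSE]
    r <- r[order(r$primaryid), , drop = FALSE]
    rownames(r) <- NULL
  }
  data$reports <- r
  data <- restrict_children(data)
  add_provenance(data, "deduplicate", n_in, nrow(r),
                 kv_string(c(versions_dropped = n_in - nrow(r))))
}

#' Restrict to a reporting window
#'
#' @param data a `faers_data`.
#' @param from,to inclusive quarter bounds (defaults `2004Q1`--`2024Q2`).
#' @return filtered dataset with provenance.
#' @export
filter_quarter_window <- function(data, from = "2004Q1", to = "2024Q2") {
  n_in <- nrow(data$reports)
  qi <- quarter_index(data$reports$quarter)
  keep <- qi >= quarter_index(from) & qi <= quarter_index(to)
  data$reports <- data$reports[keep, , drop = FALSE]
  rownames(data$reports) <- NULL
  data <- restrict_children(data)
  add_provenance(data, "quarter_window", n_in, nrow(data$reports),
                 kv_string(c(from = from, to = to)))
}

#' Keep reports from selected reporter occupations
#'
#' Spontaneous reports from consumers and lawyers are noisier than those
#' from healthcare professionals; the conventional cohort keeps physicians,
#' pharmacists and other health professionals (which absorbs registered
#' nurses under the default occupation-code map).
#'
#' @param data a deduplicated `faers_data`.
#' @param allowed character vector of occupation labels to retain.
#' @return filtered dataset; warns (not errors) if nothing survives.
#' @export
filter_reporters <- function(data,
                             allowed = c("physician", "pharmacist",
                                         "other-health-professional")) {
  n_in <- nrow(data$reports)
  keep <- data$reports$occupation %in% allowed
  data$reports <- data$reports[keep, , drop = FALSE]
  rownames(data$reports) <- NULL
  if (n_in > 0L && nrow(data$reports) == 0L) {
    warning("reporter filter removed every report")
  }
  data <- restrict_children(data)
  add_provenance(data, "filter_reporters", n_in, nrow(data$reports),
                 kv_string(c(allowed = paste(allowed, collapse = "|"))))
}

#' Exclude reports with a pre-existing diagnosis of the target event
#'
#' A report whose drug was *indicated for* the target event (e.g. a drug
#' given to treat pulmonary edema) is a false positive for causation; such
#' reports are removed entirely.  Matching is case-insensitive string
#' equality on the indication preferred term.
#'
#' @param data a `faers_data`.
#' @param target_pt preferred term, e.g. `"Pulmonary Edema"`.
#' @param synonyms extra PT spellings treated as the same event (MedDRA
#'   spelling varies, e.g. "Pulmonary oedema").
#' @return filtered dataset with provenance.
#' @export
exclude_preexisting_event <- function(data, target_pt,
                                      synonyms = character(0)) {
  n_in <- nrow(data$reports)
  targets <- toupper(trimws(c(target_pt, synonyms)))
  hit <- !is.na(data$drugs$indication_pt) &
    toupper(trimws(data$drugs$indication_pt)) %in% targets
  bad_ids <- unique(data$drugs$primaryid[hit])
  data$reports <- data$reports[!data$reports$primaryid %in% bad_ids, ,
                               drop = FALSE]
  rownames(data$reports) <- NULL
  data <- restrict_children(data)
  add_provenance(data, "exclude_preexisting", n_in, nrow(data$reports),
                 kv_string(c(excluded_cases = length(bad_ids))))
}

#' Normalize a drug name
#'
#' Uppercases, trims, collapses internal whitespace, then applies an
#' optional exact-key synonym map (brand name to generic).  Unmapped names
#' pass through unchanged.
#'
#' @param x character vector of raw drug names.
#' @param synonym_map named character vector, e.g.
#'   `c(SPRYCEL = "DASATINIB")`; keys are matched after normalization.
#' @return normalized character vector.
#' @examples
#' normalize_drug_name("  dasatinib ")                      # "DASATINIB"
#' normalize_drug_name("Sprycel", c(SPRYCEL = "DASATINIB")) # "DASATINIB"
#' @export
normalize_drug_name <- function(x, synonym_map = NULL) {
  out <- gsub("[[:space:]]+", " ", trimws(toupper(as.character(x))))
  if (!is.null(synonym_map) && length(synonym_map)) {
    names(synonym_map) <- gsub("[[:space:]]+", " ",
                               trimws(toupper(names(synonym_map))))
    hit <- out %in% names(synonym_map)
    out[hit] <- unname(synonym_map[out[hit]])
  }
  out
}

#' Run the full cohort-construction sequence
#'
#' Window restriction, case deduplication, reporter-occupation filter, and
#' pre-existing-diagnosis exclusion, in that order, with one provenance
#' line per step.  (The reporter and indication filters commute; the order
#' here is the conventional narrative order.)
#'
#' @param data a raw `faers_data` from [read_faers()].
#' @param target_pt target event preferred term.
#' @param window inclusive quarter window, length-2 character.
#' @param allowed_occupations passed to [filter_reporters()].
#' @param pt_synonyms passed to [exclude_preexisting_event()].
#' @param drug_synonyms optional brand-to-generic map applied to drug names.
#' @return cleaned `faers_data`.
#' @export
clean_faers <- function(data, target_pt = "Pulmonary Edema",
                        window = c("2004Q1", "2024Q2"),
                        allowed_occupations = c("physician", "pharmacist",
                                                "other-health-professional"),
                        pt_synonyms = "Pulmonary Oedema",
                        drug_synonyms = NULL) {
  if (!is.null(drug_synonyms)) {
    data$drugs$name <- normalize_drug_name(data$drugs$name, drug_synonyms)
  }
  data <- filter_quarter_window(data, window[1], window[2])
  data <- deduplicate_reports(data)
  data <- filter_reporters(data, allowed_occupations)
  exclude_preexisting_event(data, target_pt, pt_synonyms)
}

# ---- writing --------------------------------------------------------------

fmt_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

write_dollar_table <- function(df, path) {
  lines <- c(
    paste(names(df), collapse = "$"),
    do.call(paste, c(lapply(df, fmt_chr), sep = "$"))
  )
  writeLines(lines, path)
}

# day/month/year partial date back to its FAERS digit string
fmt_partial <- function(date, precision) {
  out <- fmt_chr(date)
  out[precision == "missing"] <- ""
  out
}

#' Write a dataset back to FAERS-dialect quarterly files
#'
#' Inverse of [parse_faers_quarter()]/[read_faers()]: emits
#' `DEMO<q>.txt` ... `INDI<q>.txt` per quarter present in the data.  Ages
#' are written in years, weights in kilograms, so a write/parse round trip
#' reproduces the dataset field for field.
#'
#' @param data a `faers_data`.
#' @param dir output directory (created if needed).
#' @param dialect a [faers_dialect()] (only `"current"` supported for
#'   writing).
#' @return invisibly, the vector of files written.
#' @export
write_faers_quarter <- function(data, dir, dialect = faers_dialect()) {
  stopifnot(dialect$name == "current")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inv_occ <- c(physician = "MD", pharmacist = "PH",
               `other-health-professional` = "OT", nurse = "RN",
               lawyer = "LW", consumer = "CN", unknown = "")
  inv_sex <- c(female = "F", male = "M", unknown = "")
  files <- character(0)
  for (q in sort(unique(data$reports$quarter))) {
    r <- data$reports[data$reports$quarter == q, , drop = FALSE]
    ids <- r$primaryid
    demo <- data.frame(
      primaryid = r$primaryid, caseid = r$caseid,
      event_dt = fmt_partial(r$event_date, r$event_precision),
      fda_dt = ifelse(is.na(r$report_year), "",
                      sprintf("%04d0101", r$report_year)),
      age = ifelse(is.na(r$age_years), "",
                   formatC(r$age_years, format = "fg", digits = 15)),
      age_cod = ifelse(is.na(r$age_years), "", "YR"),
      sex = unname(inv_sex[r$sex]),
      wt = ifelse(is.na(r$weight_kg), "",
                  formatC(r$weight_kg, format = "fg", digits = 15)),
      wt_cod = ifelse(is.na(r$weight_kg), "", "KG"),
      occp_cod = unname(inv_occ[r$occupation]),
      stringsAsFactors = FALSE
    )
    dsub <- data$drugs[data$drugs$primaryid %in% ids, , drop = FALSE]
    drug <- data.frame(primaryid = dsub$primaryid, drug_seq = dsub$seq,
                       role_cod = dsub$role, drugname = dsub$name,
                       stringsAsFactors = FALSE)
    rsub <- data$reactions[data$reactions$primaryid %in% ids, , drop = FALSE]
    reac <- data.frame(primaryid = rsub$primaryid, pt = rsub$pt,
                       pt_cod = rsub$pt_code, stringsAsFactors = FALSE)
    tsub <- data$therapies[data$therapies$primaryid %in% ids, , drop = FALSE]
    ther <- data.frame(primaryid = tsub$primaryid,
                       dsg_drug_seq = tsub$drug_seq,
                       start_dt = fmt_partial(tsub$start_date,
                                              tsub$start_precision),
                       stringsAsFactors = FALSE)
    isub <- dsub[!is.na(dsub$indication_pt), , drop = FALSE]
    indi <- data.frame(primaryid = isub$primaryid,
                       indi_drug_seq = isub$seq,
                       indi_pt = isub$indication_pt,
                       stringsAsFactors = FALSE)
    paths <- file.path(dir, paste0(c("DEMO", "DRUG", "REAC", "THER", "INDI"),
                                   q, ".txt"))
    write_dollar_table(demo, paths[1])
    write_dollar_table(drug, paths[2])
    write_dollar_table(reac, paths[3])
    write_dollar_table(ther, paths[4])
    write_dollar_table(indi, paths[5])
    files <- c(files, paths)
  }
  invisible(files)
}

#' Write the cleaned dataset as tab-separated tables plus a provenance log
#'
#' @param data a `faers_data`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_clean_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, c("reports.tsv", "drugs.tsv", "reactions.tsv",
                            "therapies.tsv", "provenance.log"))
  utils::write.table(data$reports, files[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(data$drugs, files[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(data$reactions, files[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(data$therapies, files[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  writeLines(sprintf("%s\t%d\t%d\t%s", data$provenance$step,
                     data$provenance$rows_in, data$provenance$rows_out,
                     data$provenance$detail), files[5])
  invisible(files)
}
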