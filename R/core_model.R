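#' @import data.table
#' @importFrom stats median sd qnorm rexp rbinom rpois runif setNames pnorm
#'   quantile uniroot optimize
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

# Factor levels used throughout; these are the row labels of the source
# database's groupings, plus an explicit "missing" level where the field can
# be absent in real records.
mr_levels <- list(
  sex               = c("male", "female", "missing"),
  ethnicity         = c("asian", "black", "mixed", "other", "white", "missing"),
  region            = c("scotland", "wales", "northern_ireland", "london",
                        "rest_of_england"),
  consultation_type = c("face_to_face", "telephone", "other", "missing"),
  staff_role        = c("pharmacist", "gp", "nurse", "admin", "other",
                        "missing"),
  count_band        = c("0", "1", "2-4", "5-9", "10-14", "15-19", "20+"),
  age_band          = c("65-74", "75-84", "85-94", "95+")
)

# Data dictionary for the flat tables. type: c=character, i=integer,
# n=numeric, d=ISO date, l=logical, f:<enum>=factor-coded enum.
mr_schemas <- list(
  patients = list(
    required = c("patient_id", "sex", "birth_year", "practice_id",
                 "registration_date", "uts_date", "transfer_out_date",
                 "death_date", "care_home", "ethnicity", "townsend_quintile",
                 "person_level_townsend"),
    types = c(patient_id = "c", sex = "f:sex", birth_year = "i",
              practice_id = "c", registration_date = "d", uts_date = "d",
              transfer_out_date = "d", death_date = "d", care_home = "l",
              ethnicity = "f:ethnicity", townsend_quintile = "i",
              person_level_townsend = "l"),
    key = "patient_id"
  ),
  practices = list(
    required = c("practice_id", "region", "last_collection_date",
                 "townsend_quintile"),
    types = c(practice_id = "c", region = "f:region",
              last_collection_date = "d", townsend_quintile = "i"),
    key = "practice_id"
  ),
  events = list(
    required = c("patient_id", "event_date", "code", "consultation_type",
                 "staff_role"),
    types = c(patient_id = "c", event_date = "d", code = "c",
              consultation_type = "f:consultation_type",
              staff_role = "f:staff_role"),
    key = NULL
  ),
  prescriptions = list(
    required = c("patient_id", "issue_date", "substance", "formulation",
                 "bnf_chapter", "bnf_paragraph", "quantity", "daily_dose",
                 "repeat_flag"),
    types = c(patient_id = "c", issue_date = "d", substance = "c",
              formulation = "c", bnf_chapter = "i", bnf_paragraph = "c",
              quantity = "n", daily_dose = "n", repeat_flag = "l"),
    key = NULL
  )
)

mr_parse_col <- function(x, type) {
  x <- as.character(x)
  x[x %in% c("", "NA")] <- NA_character_
  if (type == "c") return(x)
  if (type == "i") return(suppressWarnings(as.integer(x)))
  if (type == "n") return(suppressWarnings(as.numeric(x)))
  if (type == "d") return(as.Date(suppressWarnings(
    as.Date(x, format = "%Y-%m-%d")), origin = "1970-01-01"))
  if (type == "l") {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    return(out)
  }
  if (startsWith(type, "f:")) {
    lev <- mr_levels[[sub("^f:", "", type)]]
    x <- tolower(trimws(x))
    if ("missing" %in% lev) x[is.na(x) | !(x %in% lev)] <- "missing"
    else x[!(x %in% lev) & !is.na(x)] <- NA_character_
    return(factor(x, levels = lev))
  }
  stop("unknown column type: ", type)
}

#' Read one of the flat record tables
#'
#' Parses a delimited text file into a typed `data.table` according to the
#' package's data dictionary. Unparseable dates and numbers become `NA` (the
#' missing sentinel); enum fields outside their declared level set collapse to
#' the `"missing"` level where one exists. Row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"patients"`, `"practices"`, `"events"`,
#'   `"prescriptions"`.
#' @return A `data.table` with one typed column per dictionary field.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(mr_schemas))
  sch <- mr_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, colClasses = "character", na.strings = NULL,
                           keepLeadingZeros = TRUE)
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols)) {
    stop("schema error in ", schema, " table: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.table::as.data.table(
    lapply(sch$required, function(col) mr_parse_col(raw[[col]],
                                                    sch$types[[col]])))
  data.table::setnames(out, sch$required)
  if (!is.null(sch$key) && anyDuplicated(out[[sch$key]])) {
    stop("integrity error: duplicate ", sch$key, " in ", schema, " table")
  }
  out[]
}

#' Write one of the flat record tables
#'
#' Inverse of [read_table()]: dates are written as ISO-8601 strings, logicals
#' as `true`/`false`, missing values as empty fields.
#'
#' @param dt Typed table as returned by [read_table()].
#' @param path Output file path.
#' @param schema Table name (see [read_table()]).
#' @return `path`, invisibly.
#' @export
write_table <- function(dt, path, schema) {
  schema <- match.arg(schema, names(mr_schemas))
  sch <- mr_schemas[[schema]]
  out <- data.table::as.data.table(dt)[, sch$required, with = FALSE]
  for (col in sch$required) {
    type <- sch$types[[col]]
    v <- out[[col]]
    if (type == "d") v <- format(v, "%Y-%m-%d")
    else if (type == "l") v <- c("false", "true")[as.integer(v) + 1L]
    else v <- as.character(v)
    v[is.na(v)] <- ""
    data.table::set(out, j = col, value = v)
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' Load a clinical code list
#'
#' Reads a two-or-three-column delimited file (`code`, `label`, optional
#' `flags`) into a code-list object. Entries are deduplicated by code; a code
#' repeated with conflicting flags is an integrity error. Review lists mark,
#' via the `conservative_excluded` flag, codes that denote reviews of specific
#' medicines or conditions and are dropped under the conservative review
#' definition.
#'
#' @param path Path to the delimited file.
#' @param name List name; defaults to the file name without extension.
#' @param kind One of `"review"`, `"diagnosis"`, `"drug_group"`.
#' @return An object of class `mr_codelist` with elements `name`, `kind` and
#'   `entries` (a `data.table` with columns `code`, `label`,
#'   `conservative_excluded`).
#' @export
load_codelist <- function(path, name = NULL,
                          kind = c("review", "diagnosis", "drug_group")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("code list file not found: ", path)
  raw <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L) stop("code list must have at least code and label columns")
  if (!"code" %in% names(raw)) data.table::setnames(raw, 1:2, c("code", "label"))
  entries <- data.table::data.table(
    code = trimws(raw$code),
    label = trimws(raw$label),
    conservative_excluded =
      if ("flags" %in% names(raw))
        grepl("conservative_excluded", raw$flags, fixed = TRUE)
      else FALSE
  )
  entries <- unique(entries)
  if (anyDuplicated(entries$code)) {
    bad <- unique(entries$code[duplicated(entries$code)])
    stop("integrity error: code(s) with conflicting entries: ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = if (is.null(name))
    sub("\\.[^.]+$", "", basename(path)) else name,
    kind = kind, entries = entries),
    class = "mr_codelist")
}

#' @export
print.mr_codelist <- function(x, ...) {
  cat(sprintf("<mr_codelist '%s' (%s): %d codes, %d conservative-excluded>\n",
              x$name, x$kind, nrow(x$entries),
              sum(x$entries$conservative_excluded)))
  invisible(x)
}

#' Medicine identity key
#'
#' Medicines are identified by drug substance and formulation jointly: the
#' same substance in different formulations counts as different medicines.
#' The key is case-folded and whitespace-normalised so that cosmetic
#' differences in source strings do not split one medicine into several.
#'
#' @param substance Character vector of drug-substance names (must be
#'   non-empty).
#' @param formulation Character vector of formulation names.
#' @return Character vector of normalised `substance|formulation` keys.
#' @export
medicine_key <- function(substance, formulation) {
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(as.character(x))))
  s <- norm(substance)
  f <- norm(formulation)
  if (any(is.na(s) | s == "")) stop("invalid record: empty drug substance")
  f[is.na(f)] <- ""
  paste(s, f, sep = "|")
}

# medicine_key evaluated once per distinct (substance, formulation) pair and
# broadcast by hashing -- identical output, far cheaper on multi-million-row
# prescription tables.
mr_medicine_key <- function(substance, formulation) {
  comb <- paste0(substance, "\x1f", formulation)
  u <- !duplicated(comb)
  medicine_key(substance[u], formulation[u])[match(comb, comb[u])]
}

# same trick for any expensive per-string transformation
mr_by_unique <- function(x, fn) {
  u <- !duplicated(x)
  fn(x[u])[match(x, x[u])]
}

#' Drop non-medicinal and immunological/anaesthetic products
#'
#' Removes prescription rows that never enter exposure computation: BNF
#' chapters 14 (immunological products and vaccines) and 15 (anaesthesia),
#' rows with no BNF chapter (the non-medicinal sentinel), and rows whose
#' substance or formulation matches a term list of non-medicinal products
#' (dressings, devices, garments).
#'
#' @param rx Prescriptions `data.table`.
#' @param nonmedicinal_terms Character vector of lower-case terms; defaults to
#'   the bundled list.
#' @return Filtered copy of `rx`.
#' @export
filter_medicinal <- function(rx, nonmedicinal_terms = mr_nonmedicinal_terms()) {
  rx <- data.table::as.data.table(rx)
  txt <- paste(rx$substance, rx$formulation)
  hit <- mr_by_unique(txt, function(tt) {
    tt <- tolower(tt)
    Reduce(`|`, lapply(nonmedicinal_terms,
                       function(t) grepl(t, tt, fixed = TRUE)),
           init = logical(length(tt)))
  })
  keep <- !is.na(rx$bnf_chapter) & !(rx$bnf_chapter %in% c(14L, 15L)) & !hit
  rx[keep]
}

#' Bundled non-medicinal term list
#' @return Character vector of terms flagging non-medicinal products.
#' @export
mr_nonmedicinal_terms <- function() {
  path <- mr_extdata("nonmedicinal_terms.csv")
  data.table::fread(path, colClasses = "character", sep = ",")$term
}

#' Path to a bundled data file
#'
#' @param ... Path components below the package's `extdata` directory; with no
#'   arguments, the `extdata` directory itself.
#' @return Absolute file path.
#' @export
mr_extdata <- function(...) {
  system.file("extdata", ..., package = "medrev", mustWork = TRUE)
}
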