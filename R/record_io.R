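#' Hemodynamic trend records
#'
#' A `hemodynamic_record` holds one ICU stay's minute-by-minute trend data:
#' heart rate (beats/min) and systolic, diastolic and mean arterial blood
#' pressure (mmHg), on a uniform 1-minute grid starting at minute 0, plus the
#' patient's age and any timed doses of hemodynamically active medications.
#' Missing minutes are explicit `NA`s; the grid is never compacted, so series
#' index `i` always corresponds to minute `i - 1` (minute `i` in 0-based
#' terms).
#'
#' Medications are grouped by their expected effect on blood pressure:
#' pressors and positive inotropes (`"raising"`) versus vasodilators,
#' diuretics and sedatives (`"lowering"`). Group membership is resolved
#' case-insensitively against two closed drug lists; unknown drug names are
#' rejected so that dose features are never silently miscategorised.
#'
#' @param record_id Single string identifying the record.
#' @param hr,sbp,dbp,map Numeric vectors of equal length: one value per
#'   minute, `NA` for missing minutes.
#' @param age Patient age in years; must be at least 18 (adult ICU stays).
#' @param medications A data frame with columns `minute` (0-based minute
#'   index), `drug` (name, matched case-insensitively) and
#'   `dose_mcg_per_kg`. May have zero rows.
#'
#' @return `hemodynamic_record()` returns an object of class
#'   `"hemodynamic_record"`: a list with fields `record_id`, `hr`, `sbp`,
#'   `dbp`, `map`, `age` and `medications` (the medications gain a derived
#'   `group` column).
#' @examples
#' rec <- hemodynamic_record("r1", hr = c(80, 82, NA, 81),
#'                           sbp = c(120, 118, NA, 121),
#'                           dbp = c(70, 69, NA, 70),
#'                           map = c(87, 85, NA, 87), age = 63)
#' record_length(rec)
#' validate_record(rec)
#' @export
hemodynamic_record <- function(record_id, hr, sbp, dbp, map, age,
                               medications = empty_medications()) {
  medications <- as.data.frame(medications)
  medications$minute <- as.integer(medications$minute)
  if (nrow(medications) > 0) {
    medications$group <- medication_group(medications$drug)
    medications <- medications[order(medications$minute), , drop = FALSE]
    rownames(medications) <- NULL
  } else if (is.null(medications$group)) {
    medications$group <- character(0)
  }
  rec <- structure(
    list(record_id = as.character(record_id),
         hr = as.numeric(hr), sbp = as.numeric(sbp),
         dbp = as.numeric(dbp), map = as.numeric(map),
         age = as.numeric(age), medications = medications),
    class = "hemodynamic_record")
  issues <- validate_record(rec)
  if (length(issues) > 0) {
    stop("invalid hemodynamic record: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  rec
}

#' @rdname hemodynamic_record
#' @param record A `hemodynamic_record`.
#' @export
record_length <- function(record) length(record$map)

#' @export
print.hemodynamic_record <- function(x, ...) {
  n <- record_length(x)
  miss <- sum(is.na(x$map))
  cat(sprintf("<hemodynamic_record> %s: %d min (%.1f h), age %g, %d med events, %d missing MAP min\n",
              x$record_id, n, n / 60, x$age, nrow(x$medications), miss))
  invisible(x)
}

# Closed drug lists defining the two medication groups.
RAISING_DRUGS <- c("neosynephrine", "norepinephrine", "vasopressin",
                   "dopamine", "dobutamine", "epinephrine", "milrinone",
                   "isuprel")
LOWERING_DRUGS <- c("nitroglycerine", "nitroprusside", "diltiazem",
                    "esmolol", "labetalol", "lasix")

#' Resolve medication names to their blood-pressure effect group
#'
#' @param drug Character vector of drug names (matched case-insensitively).
#' @return Character vector, `"raising"` or `"lowering"` per drug.
#'   Unrecognised names are an error: the two lists are closed.
#' @examples
#' medication_group(c("Dopamine", "lasix"))
#' @export
medication_group <- function(drug) {
  d <- tolower(trimws(as.character(drug)))
  out <- ifelse(d %in% RAISING_DRUGS, "raising",
                ifelse(d %in% LOWERING_DRUGS, "lowering", NA_character_))
  if (anyNA(out)) {
    bad <- unique(drug[is.na(out)])
    stop("unknown medication name(s): ", paste(bad, collapse = ", "),
         "; not in the raising or lowering drug list", call. = FALSE)
  }
  out
}

empty_medications <- function() {
  data.frame(minute = integer(0), drug = character(0),
             dose_mcg_per_kg = numeric(0), group = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a hemodynamic record
#'
#' Checks every structural invariant of the record data model and reports all
#' violations rather than stopping at the first. Used internally by the
#' constructor and the reader; also exported for checking records assembled
#' by hand.
#'
#' @param record An object shaped like a `hemodynamic_record`.
#' @return Character vector of issue descriptions; empty when the record is
#'   valid. Each issue names the offending field and, where relevant, the
#'   minute index.
#' @export
validate_record <- function(record) {
  issues <- character(0)
  n <- length(record$map)
  for (f in c("hr", "sbp", "dbp")) {
    if (length(record[[f]]) != n) {
      issues <- c(issues, sprintf(
        "series length mismatch: %s has %d minutes but map has %d",
        f, length(record[[f]]), n))
    }
  }
  if (n < 1) issues <- c(issues, "record has zero length")
  if (!is.character(record$record_id) || length(record$record_id) != 1 ||
      is.na(record$record_id) || !nzchar(record$record_id)) {
    issues <- c(issues, "record_id must be a non-empty string")
  }
  if (!is.numeric(record$age) || length(record$age) != 1 ||
      is.na(record$age)) {
    issues <- c(issues, "age must be a single number")
  } else if (record$age < 18) {
    issues <- c(issues, sprintf(
      "age %g violates the adult-patient constraint (age >= 18)", record$age))
  }
  meds <- record$medications
  if (!is.data.frame(meds) ||
      !all(c("minute", "drug", "dose_mcg_per_kg") %in% names(meds))) {
    issues <- c(issues,
                "medications must have columns minute, drug, dose_mcg_per_kg")
  } else if (nrow(meds) > 0) {
    bad_dose <- which(is.na(meds$dose_mcg_per_kg) | meds$dose_mcg_per_kg < 0)
    for (i in bad_dose) {
      issues <- c(issues, sprintf(
        "medication row %d (%s, minute %d): dose must be >= 0",
        i, meds$drug[i], meds$minute[i]))
    }
    oob <- which(meds$minute < 0 | meds$minute >= n)
    for (i in oob) {
      issues <- c(issues, sprintf(
        "medication row %d (%s): minute %d outside record bounds [0, %d)",
        i, meds$drug[i], meds$minute[i], n))
    }
    grp <- tryCatch(medication_group(meds$drug), error = conditionMessage)
    if (is.character(grp) && length(grp) == 1 && grepl("unknown", grp)) {
      issues <- c(issues, grp)
    }
  }
  issues
}

#' Read and write record bundles
#'
#' A record is stored as three plain-text files sharing a path prefix:
#' `<prefix>.vitals.csv` (columns `minute,hr,sbp,dbp,map`, one row per
#' present minute), `<prefix>.meds.csv` (columns
#' `minute,drug,dose_mcg_per_kg`) and `<prefix>.meta.json` (keys `record_id`,
#' `age`, `n_minutes`). Minutes absent from the vitals file become `NA` on
#' the uniform grid, so write-then-read reproduces a record exactly,
#' missing markers included.
#'
#' @param record A `hemodynamic_record`.
#' @param dir Directory in which to write the bundle; created if needed.
#' @param path Path prefix of an existing bundle (the part before
#'   `.vitals.csv`), as returned by `write_record()`.
#' @return `write_record()` invisibly returns the bundle path prefix;
#'   `read_record()` returns the reconstructed `hemodynamic_record`.
#' @examples
#' rec <- hemodynamic_record("r1", hr = c(80, NA, 82), sbp = c(120, NA, 119),
#'                           dbp = c(70, NA, 68), map = c(86, NA, 85),
#'                           age = 70)
#' p <- write_record(rec, tempdir())
#' identical(read_record(p), rec)
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "hemodynamic_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- file.path(dir, record$record_id)
  n <- record_length(record)
  present <- !(is.na(record$hr) & is.na(record$sbp) &
                 is.na(record$dbp) & is.na(record$map))
  vit <- data.frame(minute = (0:(n - 1))[present],
                    hr = fmt_num(record$hr[present]),
                    sbp = fmt_num(record$sbp[present]),
                    dbp = fmt_num(record$dbp[present]),
                    map = fmt_num(record$map[present]))
  utils::write.csv(vit, paste0(prefix, ".vitals.csv"), row.names = FALSE,
                   quote = FALSE)
  meds <- record$medications
  med_out <- data.frame(minute = meds$minute, drug = meds$drug,
                        dose_mcg_per_kg = fmt_num(meds$dose_mcg_per_kg))
  utils::write.csv(med_out, paste0(prefix, ".meds.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(record_id = record$record_id, age = record$age, n_minutes = n)
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

# 17 significant digits round-trip IEEE doubles through text exactly.
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- NA_character_
  trimws(out)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  files <- paste0(path, c(".vitals.csv", ".meds.csv", ".meta.json"))
  missing_files <- files[!file.exists(files)]
  if (length(missing_files) > 0) {
    stop("record bundle incomplete at '", path, "': missing ",
         paste(basename(missing_files), collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(files[3], simplifyVector = TRUE)
  vit <- tryCatch(
    utils::read.csv(files[1], colClasses = "numeric"),
    error = function(e) stop("malformed vitals file '", files[1], "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("minute", "hr", "sbp", "dbp", "map")
  if (!all(need %in% names(vit))) {
    stop("vitals file '", files[1], "' line 1: expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (anyNA(vit$minute) || any(vit$minute != floor(vit$minute)) ||
      any(vit$minute < 0)) {
    bad <- which(is.na(vit$minute) | vit$minute != floor(vit$minute) |
                   vit$minute < 0)[1]
    stop("vitals file '", files[1], "' line ", bad + 1,
         ": minute index must be a non-negative integer", call. = FALSE)
  }
  if (anyDuplicated(vit$minute)) {
    dup <- vit$minute[duplicated(vit$minute)][1]
    stop("vitals file '", files[1], "': duplicated minute index ", dup,
         call. = FALSE)
  }
  n <- meta$n_minutes %||% (max(vit$minute) + 1)
  if (any(vit$minute >= n)) {
    stop("vitals file '", files[1], "': minute index beyond declared record ",
         "length ", n, call. = FALSE)
  }
  grid <- function(col) {
    out <- rep(NA_real_, n)
    out[vit$minute + 1] <- col
    out
  }
  med_raw <- tryCatch(
    utils::read.csv(files[2],
                    colClasses = c("integer", "character", "numeric")),
    error = function(e) stop("malformed medications file '", files[2], "': ",
                             conditionMessage(e), call. = FALSE))
  hemodynamic_record(record_id = meta$record_id,
                     hr = grid(vit$hr), sbp = grid(vit$sbp),
                     dbp = grid(vit$dbp), map = grid(vit$map),
                     age = meta$age, medications = med_raw)
}

#' Read every record bundle in a directory
#'
#' @param dir Directory containing `*.vitals.csv` bundles.
#' @return Named list of `hemodynamic_record`s, keyed by record id.
#' @export
read_cohort <- function(dir) {
  vitals <- list.files(dir, pattern = "\\.vitals\\.csv$", full.names = TRUE)
  prefixes <- sub("\\.vitals\\.csv$", "", vitals)
  recs <- lapply(prefixes, read_record)
  names(recs) <- vapply(recs, function(r) r$record_id, character(1))
  recs
}
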