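#' Cohort manifests and subject-level splitting
#'
#' A cohort is the scan-level table driving every pipeline stage: one row per
#' scan with subject id, path to the NIfTI file, age at scan (years), sex code
#' and diagnosis (`CN` or `AD`).  Repeated scans of one subject share a
#' `subject_id` and differ in `scan_path` (and possibly age).  Splitting into
#' train/validation/test is always by subject, never by scan, so no subject
#' contributes scans to two partitions.
#'
#' @name cohort
NULL

.sex_codes <- c("0" = 0, "1" = 1,
                "f" = 0, "m" = 1,
                "female" = 0, "male" = 1)

# Map the accepted sex aliases to the {0, 1} code (female = 0, male = 1).
parse_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.sex_codes[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unrecognised sex code(s): ", paste(bad, collapse = ", "),
         " (accepted: 0/1, F/M, female/male)")
  }
  as.integer(out)
}

#' Construct a cohort from scan-level records
#'
#' @param records data.frame with columns `subject_id`, `scan_path`, `age`,
#'   `sex`, `diagnosis`.
#' @param split optional character vector (values in `train`/`val`/`test`)
#'   named by `subject_id`, or a `split` column already present in `records`.
#' @param age_range plausible age bounds in years; rows outside are rejected.
#' @return An object of class `cohort` wrapping the validated records.
#' @export
cohort <- function(records, split = NULL, age_range = c(0, 120)) {
  required <- c("subject_id", "scan_path", "age", "sex", "diagnosis")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$subject_id <- as.character(records$subject_id)
  records$scan_path <- as.character(records$scan_path)
  records$age <- as.numeric(records$age)
  bad_age <- which(!is.finite(records$age) | records$age < age_range[1] |
                     records$age > age_range[2])
  if (length(bad_age)) {
    stop("row ", bad_age[1], ": age ", records$age[bad_age[1]],
         " is missing or outside the plausible range [",
         age_range[1], ", ", age_range[2], "]")
  }
  records$sex <- parse_sex(records$sex)
  records$diagnosis <- toupper(trimws(as.character(records$diagnosis)))
  bad_dx <- which(!records$diagnosis %in% c("CN", "AD"))
  if (length(bad_dx)) {
    stop("row ", bad_dx[1], ": diagnosis must be CN or AD, got '",
         records$diagnosis[bad_dx[1]], "'")
  }
  dup <- duplicated(records[c("subject_id", "scan_path")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (subject_id, scan_path) row(s) kept as-is")
  }
  if (!is.null(split)) {
    if (!all(names(split) %in% records$subject_id) ||
        !all(records$subject_id %in% names(split))) {
      stop("split labels must cover exactly the subjects present")
    }
    records$split <- unname(split[records$subject_id])
  }
  if (!is.null(records$split)) {
    ok <- tapply(records$split, records$subject_id,
                 function(s) length(unique(s)) == 1L)
    if (!all(ok)) {
      stop("subject(s) with scans in more than one partition: ",
           paste(names(ok)[!ok], collapse = ", "))
    }
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  r <- x$records
  cat("<cohort> ", nrow(r), " scans, ", length(unique(r$subject_id)),
      " subjects; ages ", round(min(r$age), 1), "-", round(max(r$age), 1),
      "; ", sum(r$diagnosis == "AD"), " AD scans", sep = "")
  if (!is.null(r$split)) {
    tab <- table(r$split)
    cat("; split ", paste(names(tab), tab, sep = "=", collapse = " "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read a cohort manifest CSV
#'
#' Expects a header with columns `subject_id`, `scan_path`, `age`, `sex`,
#' `diagnosis` (a `split` column, if present, is honoured).  `sex` accepts
#' `0/1`, `F/M` or `female/male` (female = 0, male = 1).  Row order is
#' preserved; duplicated (subject_id, scan_path) rows raise a warning but are
#' kept.
#'
#' @param path CSV file path.
#' @param age_range plausible age bounds in years.
#' @return A [cohort].
#' @export
load_manifest <- function(path, age_range = c(0, 120)) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort(df, age_range = age_range)
}

#' Write a cohort manifest CSV
#'
#' @param x a [cohort].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$records, path, row.names = FALSE)
  invisible(path)
}

#' Subject-level train/validation/test split
#'
#' Partitions the distinct subjects (never individual scans) so that all scans
#' of one subject share a partition.  `round(test_fraction * n_subjects)`
#' subjects go to the test set and `round(val_fraction * n_subjects)` of the
#' remainder to validation; the rest train.  Deterministic for a fixed seed.
#'
#' @param x a [cohort].
#' @param test_fraction fraction of subjects held out for testing (default
#'   0.25, the held-out share used for final evaluation).
#' @param val_fraction fraction of subjects used for validation (default 0.10).
#' @param seed integer seed.
#' @return The cohort with a `split` column added to its records.
#' @export
split_subjects <- function(x, test_fraction = 0.25, val_fraction = 0.10,
                           seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (test_fraction <= 0 || test_fraction >= 1 || val_fraction < 0 ||
      test_fraction + val_fraction >= 1) {
    stop("need 0 < test_fraction, 0 <= val_fraction and test_fraction + val_fraction < 1")
  }
  subjects <- unique(x$records$subject_id)
  n <- length(subjects)
  if (n < 3L) stop("need at least 3 distinct subjects to split; got ", n)
  n_test <- round(test_fraction * n)
  n_val <- round(val_fraction * n)
  perm <- with_seed(seed, sample(subjects))
  lab <- rep("train", n)
  names(lab) <- perm
  if (n_test > 0) lab[seq_len(n_test)] <- "test"
  if (n_val > 0) lab[n_test + seq_len(n_val)] <- "val"
  x$records$split <- unname(lab[x$records$subject_id])
  x
}

#' Extract the scans of one partition
#'
#' @param x a split [cohort].
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return A [cohort] restricted to that partition.
#' @export
cohort_partition <- function(x, which = c("train", "val", "test")) {
  which <- match.arg(which)
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$records$split)) stop("cohort has not been split yet")
  cohort(x$records[x$records$split == which, , drop = FALSE])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
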