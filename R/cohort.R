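#' Construct a growth cohort
#'
#' A cohort is a long-format table of growth records — one row per
#' (child, visit) — plus an optional nominal visit schedule. Records are
#' validated (age and BMI bounds, uniqueness of (child, age) pairs) and
#' sorted by child then age. BMI is derived from weight and height when
#' absent.
#'
#' @param records A data frame with columns `child_id`, `sex`
#'   (`"female"`/`"male"`), `age_years`, and at least one of `bmi` or the
#'   pair `weight_kg`, `height_cm`.
#' @param schedule Optional numeric vector of nominal visit ages (years);
#'   metadata only — observations may sit at arbitrary ages.
#' @param age_range Allowed age interval in years (closed).
#' @param bmi_range Allowed BMI interval in kg/m^2 (open); a sanity bound.
#' @param quiet Suppress the dropped-row message.
#' @return An object of class `growth_cohort`: a list with elements
#'   `records` (tibble), `schedule`, and `n_dropped` (rows removed by
#'   validation, by reason).
#' @export
growth_cohort <- function(records, schedule = NULL,
                          age_range = c(0, 10), bmi_range = c(5, 60),
                          quiet = FALSE) {
  records <- tibble::as_tibble(records)
  req <- c("child_id", "sex", "age_years")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("cohort has no records", call. = FALSE)
  if (!("bmi" %in% names(records)) &&
      !all(c("weight_kg", "height_cm") %in% names(records))) {
    stop("need either `bmi` or both `weight_kg` and `height_cm`", call. = FALSE)
  }

  records$child_id <- as.character(records$child_id)
  records$sex <- map_sex(records$sex)
  for (num in intersect(c("age_years", "bmi", "weight_kg", "height_cm"),
                        names(records))) {
    if (!is.numeric(records[[num]])) {
      records[[num]] <- suppressWarnings(as.numeric(records[[num]]))
    }
  }
  if (!("bmi" %in% names(records))) records$bmi <- NA_real_
  if (all(c("weight_kg", "height_cm") %in% names(records))) {
    derive <- is.na(records$bmi) & !is.na(records$weight_kg) &
      !is.na(records$height_cm)
    records$bmi[derive] <- records$weight_kg[derive] /
      (records$height_cm[derive] / 100)^2
  }

  dropped <- c(invalid = 0L, age = 0L, bmi = 0L, duplicate = 0L)
  ok <- !is.na(records$child_id) & !is.na(records$sex) &
    is.finite(records$age_years) & is.finite(records$bmi)
  dropped["invalid"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  in_age <- records$age_years >= age_range[1] & records$age_years <= age_range[2]
  dropped["age"] <- sum(!in_age)
  records <- records[in_age, , drop = FALSE]

  in_bmi <- records$bmi > bmi_range[1] & records$bmi < bmi_range[2]
  dropped["bmi"] <- sum(!in_bmi)
  records <- records[in_bmi, , drop = FALSE]

  dup <- duplicated(records[, c("child_id", "age_years")])
  dropped["duplicate"] <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  if (nrow(records) == 0L) stop("no records survive validation", call. = FALSE)
  records <- records[order(records$child_id, records$age_years), , drop = FALSE]

  if (!quiet && sum(dropped) > 0) {
    message(sum(dropped), " record(s) dropped during validation (",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), ")")
  }
  structure(list(records = records, schedule = schedule, n_dropped = dropped),
            class = "growth_cohort")
}

map_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("female", "f", "girl", "2")] <- "female"
  out[x %in% c("male", "m", "boy", "1")] <- "male"
  bad <- unique(x[is.na(out) & !is.na(x)])
  if (length(bad) > 0) {
    stop("unmappable sex value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.growth_cohort <- function(x, ...) {
  ids <- unique(x$records$child_id)
  cat(sprintf("growth_cohort: %d children, %d records, ages %.2f-%.2f y\n",
              length(ids), nrow(x$records),
              min(x$records$age_years), max(x$records$age_years)))
  invisible(x)
}

#' Number of children in a cohort
#' @param cohort A `growth_cohort`.
#' @return Integer count of distinct children.
#' @export
n_children <- function(cohort) {
  length(unique(cohort$records$child_id))
}

#' Child identifiers of a cohort
#' @param cohort A `growth_cohort`.
#' @return Character vector of ids in sorted order.
#' @export
child_ids <- function(cohort) {
  sort(unique(cohort$records$child_id))
}

#' One child's observations
#' @param cohort A `growth_cohort`.
#' @param id A child id present in the cohort.
#' @return Tibble of that child's records, sorted by age.
#' @export
child_obs <- function(cohort, id) {
  out <- cohort$records[cohort$records$child_id == id, , drop = FALSE]
  if (nrow(out) == 0L) stop("unknown child id: ", id, call. = FALSE)
  out
}

#' Read a cohort from a long-format CSV file
#'
#' One row per (child, visit); default column names
#' `child_id,sex,age_years,bmi,weight_kg,height_cm` (the last three optional
#' as a group) can be remapped through `columns`. Rows failing validation are
#' dropped and counted in the returned object's `n_dropped`.
#'
#' @param path Path to a CSV file with a header row.
#' @param columns Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(child_id = "subjid", age_years = "age")`.
#' @param ... Passed to [growth_cohort()] (validation bounds, `schedule`).
#' @return A `growth_cohort`.
#' @export
read_cohort <- function(path, columns = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read as character so that sex codes like "F" survive type conversion
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (!(src %in% names(raw))) {
        stop("mapped column not found in file: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  growth_cohort(raw, ...)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] on validated cohorts (round-trip identity).
#'
#' @param cohort A `growth_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "growth_cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Child-level train/test split
#'
#' Randomly partitions the children (not the rows) of a cohort into a
#' training and a test cohort; reproducible given `seed`.
#'
#' @param cohort A `growth_cohort`.
#' @param n_train Number of children in the training part; must be smaller
#'   than the number of children.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both `growth_cohort`s.
#' @export
split_train_test <- function(cohort, n_train, seed) {
  ids <- child_ids(cohort)
  if (n_train >= length(ids)) {
    stop("`n_train` must be smaller than the number of children (",
         length(ids), ")", call. = FALSE)
  }
  train_ids <- local_seed(seed, sample(ids, n_train))
  take <- function(sel) {
    structure(list(records = cohort$records[cohort$records$child_id %in% sel, ,
                                            drop = FALSE],
                   schedule = cohort$schedule,
                   n_dropped = c(invalid = 0L, age = 0L, bmi = 0L,
                                 duplicate = 0L)),
              class = "growth_cohort")
  }
  list(train = take(train_ids), test = take(setdiff(ids, train_ids)))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
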