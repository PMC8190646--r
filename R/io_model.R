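#' Ingredient name normalization table
#'
#' The default lookup mapping raw ingredient / brand names to the three
#' antipyretic ingredient codes used throughout the package: `ACE`
#' (acetaminophen / paracetamol), `IBU` (ibuprofen) and `DEX`
#' (dexibuprofen). The table ships as a plain CSV
#' (`system.file("extdata", "ingredient_map.csv", package = "feverpghd")`)
#' so deployments can extend it with local brand names.
#'
#' @return A tibble with columns `name` (lower-case raw name) and `code`.
#' @export
#' @examples
#' default_ingredient_map()
default_ingredient_map <- function() {
  path <- system.file("extdata", "ingredient_map.csv", package = "feverpghd")
  readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), code = readr::col_character()
  ))
}

#' Normalize antipyretic ingredient names
#'
#' Case-insensitive mapping of ingredient or brand names to the codes
#' `ACE`, `IBU`, `DEX`. Unknown names are an error (never guessed), carrying
#' the offending raw strings.
#'
#' @param raw_name Character vector of raw names.
#' @param map Lookup table as returned by [default_ingredient_map()].
#' @return Character vector of ingredient codes, same length as `raw_name`.
#' @export
#' @examples
#' normalize_ingredient(c("Acetaminophen", "dexibuprofen"))
normalize_ingredient <- function(raw_name, map = default_ingredient_map()) {
  stopifnot(is.character(raw_name), length(raw_name) >= 1)
  key <- tolower(trimws(raw_name))
  idx <- match(key, map$name)
  bad <- is.na(idx) | !nzchar(key)
  if (any(bad)) {
    stop("unknown ingredient name(s): ",
         paste(unique(raw_name[bad]), collapse = ", "),
         call. = FALSE)
  }
  map$code[idx]
}

.empty_children <- function() {
  tibble::tibble(child_id = character(), sex = character(),
                 birth_date = as.Date(character()), weight_kg = numeric())
}

.empty_temps <- function() {
  tibble::tibble(child_id = character(),
                 time = as.POSIXct(character(), tz = "UTC"),
                 temp_c = numeric())
}

.empty_meds <- function() {
  tibble::tibble(child_id = character(),
                 time = as.POSIXct(character(), tz = "UTC"),
                 ingredient = character(), dose_mg = numeric())
}

#' Construct a cohort object
#'
#' Bundles child profiles with their per-child, time-sorted temperature and
#' antipyretic records. Records referencing a `child_id` absent from
#' `children` are rejected (counted, not silently dropped). Duplicate
#' (child, time) temperature rows keep the last occurrence.
#'
#' @param children Tibble: `child_id`, `sex` (`"male"`/`"female"`),
#'   `birth_date` (Date), `weight_kg`.
#' @param temperatures Tibble: `child_id`, `time` (POSIXct), `temp_c`.
#' @param antipyretics Tibble: `child_id`, `time` (POSIXct), `ingredient`
#'   (`ACE`/`IBU`/`DEX`), optional `dose_mg`.
#' @param rejections Named integer vector of row-rejection counts carried
#'   from upstream validation.
#' @return An object of class `fever_cohort`: a list with elements
#'   `children`, `temperatures`, `antipyretics` plus a `rejections`
#'   attribute.
#' @export
fever_cohort <- function(children = .empty_children(),
                         temperatures = .empty_temps(),
                         antipyretics = .empty_meds(),
                         rejections = integer()) {
  stopifnot(all(c("child_id", "sex", "birth_date", "weight_kg") %in% names(children)),
            all(c("child_id", "time", "temp_c") %in% names(temperatures)),
            all(c("child_id", "time", "ingredient") %in% names(antipyretics)))
  if (anyDuplicated(children$child_id)) {
    stop("duplicate child_id in children table", call. = FALSE)
  }
  if (!"dose_mg" %in% names(antipyretics)) antipyretics$dose_mg <- NA_real_

  orphan_t <- !temperatures$child_id %in% children$child_id
  orphan_m <- !antipyretics$child_id %in% children$child_id
  if (any(orphan_t)) rejections["temp_unknown_child"] <-
      sum(orphan_t) + .count0(rejections, "temp_unknown_child")
  if (any(orphan_m)) rejections["med_unknown_child"] <-
      sum(orphan_m) + .count0(rejections, "med_unknown_child")
  temperatures <- temperatures[!orphan_t, , drop = FALSE]
  antipyretics <- antipyretics[!orphan_m, , drop = FALSE]

  # stable sort: per child ascending time, ties keep input order
  temperatures <- dplyr::arrange(temperatures, .data$child_id, .data$time)
  antipyretics <- dplyr::arrange(antipyretics, .data$child_id, .data$time)

  # duplicate (child, minute) temperature readings: keep the last entered
  dup <- duplicated(temperatures[, c("child_id", "time")], fromLast = TRUE)
  if (any(dup)) {
    rejections["temp_duplicate_time"] <-
      sum(dup) + .count0(rejections, "temp_duplicate_time")
    temperatures <- temperatures[!dup, , drop = FALSE]
  }

  structure(
    list(children = tibble::as_tibble(children),
         temperatures = tibble::as_tibble(temperatures),
         antipyretics = tibble::as_tibble(antipyretics)),
    rejections = rejections,
    class = "fever_cohort"
  )
}

.count0 <- function(x, nm) if (nm %in% names(x)) x[[nm]] else 0L

#' @export
print.fever_cohort <- function(x, ...) {
  cat("<fever_cohort>\n")
  cat("  children:     ", nrow(x$children), "\n")
  cat("  temperatures: ", nrow(x$temperatures), "\n")
  cat("  antipyretics: ", nrow(x$antipyretics), "\n")
  rej <- attr(x, "rejections")
  if (length(rej) && sum(rej) > 0) {
    cat("  rejected rows:", sum(rej),
        paste0("(", paste(names(rej), rej, sep = "=", collapse = ", "), ")\n"))
  }
  excl <- attr(x, "exclusions")
  if (!is.null(excl)) {
    cat("  children excluded by filter:", excl$excluded_total, "\n")
  }
  invisible(x)
}

.parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
}

#' Read a cohort from the three canonical CSV files
#'
#' Expects `children.csv` (`child_id,sex,birth_date,weight_kg`),
#' `temperatures.csv` (`child_id,timestamp,temp_c`) and
#' `antipyretics.csv` (`child_id,timestamp,ingredient,dose_mg`), ISO-8601
#' dates/datetimes, dot decimal. Malformed rows (unparseable timestamp or
#' temperature, out-of-range temperature, unknown ingredient, non-positive
#' weight) are counted per reason in the `rejections` attribute and reported
#' with a message; a missing required column is an error naming the column.
#'
#' @param children_path,temps_path,meds_path File paths.
#' @param ingredient_map Lookup table for [normalize_ingredient()].
#' @param quiet Suppress the rejection-count message.
#' @return A [fever_cohort()] with validated, per-child time-sorted records.
#' @export
read_cohort <- function(children_path, temps_path, meds_path,
                        ingredient_map = default_ingredient_map(),
                        quiet = FALSE) {
  rej <- integer()

  chd <- .read_checked(children_path, c("child_id", "sex", "birth_date", "weight_kg"))
  chd$child_id <- as.character(chd$child_id)
  chd$sex <- tolower(as.character(chd$sex))
  chd$birth_date <- as.Date(as.character(chd$birth_date))
  chd$weight_kg <- suppressWarnings(as.numeric(chd$weight_kg))
  bad <- !nzchar(chd$child_id) | is.na(chd$child_id) |
    !chd$sex %in% c("male", "female") |
    is.na(chd$birth_date) | is.na(chd$weight_kg) | chd$weight_kg <= 0
  if (any(bad)) rej["child_invalid"] <- sum(bad)
  chd <- chd[!bad, , drop = FALSE]

  tmp <- .read_checked(temps_path, c("child_id", "timestamp", "temp_c"))
  tmp$child_id <- as.character(tmp$child_id)
  time <- suppressWarnings(.parse_time(tmp$timestamp))
  temp_c <- suppressWarnings(as.numeric(tmp$temp_c))
  bad <- is.na(time) | is.na(temp_c) | temp_c < 30 | temp_c > 43
  if (any(bad)) rej["temp_invalid"] <- sum(bad)
  temps <- tibble::tibble(child_id = tmp$child_id, time = time, temp_c = temp_c)[!bad, ]

  med <- .read_checked(meds_path, c("child_id", "timestamp", "ingredient"))
  med$child_id <- as.character(med$child_id)
  time <- suppressWarnings(.parse_time(med$timestamp))
  key <- tolower(trimws(as.character(med$ingredient)))
  code <- ingredient_map$code[match(key, ingredient_map$name)]
  dose <- if ("dose_mg" %in% names(med)) {
    suppressWarnings(as.numeric(med$dose_mg))
  } else {
    rep(NA_real_, nrow(med))
  }
  bad <- is.na(time) | is.na(code)
  if (any(bad)) rej["med_invalid"] <- sum(bad)
  meds <- tibble::tibble(child_id = med$child_id, time = time,
                         ingredient = code, dose_mg = dose)[!bad, ]

  cohort <- fever_cohort(chd, temps, meds, rejections = rej)
  total_rej <- sum(attr(cohort, "rejections"))
  if (!quiet && total_rej > 0) {
    message("read_cohort: rejected ", total_rej, " malformed row(s): ",
            paste(names(attr(cohort, "rejections")),
                  attr(cohort, "rejections"), sep = "=", collapse = ", "))
  }
  cohort
}

.read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a cohort to the three canonical CSV files
#'
#' Emits UTF-8, header row, newline-terminated `children.csv`,
#' `temperatures.csv` and `antipyretics.csv` under `dir`, in the format
#' [read_cohort()] reads back bit-identically.
#'
#' @param cohort A [fever_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fever_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, c("children.csv", "temperatures.csv", "antipyretics.csv"))

  chd <- cohort$children
  chd$birth_date <- format(chd$birth_date, "%Y-%m-%d")
  chd$weight_kg <- .num_chr(chd$weight_kg)
  readr::write_csv(chd, p[1])

  tmp <- tibble::tibble(child_id = cohort$temperatures$child_id,
                        timestamp = .time_chr(cohort$temperatures$time),
                        temp_c = .num_chr(cohort$temperatures$temp_c))
  readr::write_csv(tmp, p[2])

  med <- tibble::tibble(child_id = cohort$antipyretics$child_id,
                        timestamp = .time_chr(cohort$antipyretics$time),
                        ingredient = cohort$antipyretics$ingredient,
                        dose_mg = .num_chr(cohort$antipyretics$dose_mg))
  readr::write_csv(med, p[3], na = "")
  invisible(p)
}

.time_chr <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
.num_chr <- function(x) ifelse(is.na(x), NA_character_, format(x, trim = TRUE, scientific = FALSE))

#' Apply the child-level eligibility filters
#'
#' Retains children with weight in `weight_range` kg (closed interval), age
#' at their first record in `age_range_days` days, at least one antipyretic
#' record, and at least one fever-range temperature record
#' (>= `fever_threshold_c`). Exclusion counts are reported both per
#' criterion (overlapping — a child can fail several) and as
#' mutually-exclusive first-reason counts, in the `exclusions` attribute of
#' the returned cohort. Filtering is idempotent.
#'
#' @param cohort A [fever_cohort()].
#' @param weight_range,age_range_days Closed retention intervals.
#' @param fever_threshold_c Fever threshold defining a "fever record".
#' @return The filtered cohort; `attr(, "exclusions")` holds the counts.
#' @export
filter_children <- function(cohort, weight_range = c(2, 50),
                            age_range_days = c(0, 7000),
                            fever_threshold_c = 38) {
  stopifnot(inherits(cohort, "fever_cohort"))
  chd <- cohort$children

  first_rec <- rbind(
    data.frame(child_id = cohort$temperatures$child_id,
               time = cohort$temperatures$time),
    data.frame(child_id = cohort$antipyretics$child_id,
               time = cohort$antipyretics$time)
  )
  first_time <- tapply(first_rec$time, first_rec$child_id, min)
  age_days <- as.numeric(
    as.Date(.as_time(unname(first_time[chd$child_id]) / 3600)) - chd$birth_date
  )

  has_med <- chd$child_id %in% cohort$antipyretics$child_id
  fever_ids <- unique(cohort$temperatures$child_id[
    cohort$temperatures$temp_c >= fever_threshold_c])
  has_fever <- chd$child_id %in% fever_ids

  fail_weight <- chd$weight_kg < weight_range[1] | chd$weight_kg > weight_range[2]
  # children with no records at all have undefined age; they already fail the
  # record-presence criteria, so age does not additionally count them
  fail_age <- !is.na(age_days) &
    (age_days < age_range_days[1] | age_days > age_range_days[2])
  fail_med <- !has_med
  fail_fever <- !has_fever

  fails <- cbind(weight = fail_weight, age = fail_age,
                 no_antipyretic = fail_med, no_fever_record = fail_fever)
  keep <- rowSums(fails) == 0

  first_reason <- apply(fails, 1, function(f) {
    i <- which(f)
    if (length(i)) colnames(fails)[i[1]] else NA_character_
  })
  exclusions <- list(
    input_children = nrow(chd),
    retained = sum(keep),
    excluded_total = sum(!keep),
    by_criterion = colSums(fails),
    first_reason = table(factor(first_reason[!keep], levels = colnames(fails)))
  )

  kept_ids <- chd$child_id[keep]
  out <- fever_cohort(
    chd[keep, , drop = FALSE],
    cohort$temperatures[cohort$temperatures$child_id %in% kept_ids, , drop = FALSE],
    cohort$antipyretics[cohort$antipyretics$child_id %in% kept_ids, , drop = FALSE],
    rejections = attr(cohort, "rejections")
  )
  attr(out, "exclusions") <- exclusions
  out
}
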