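#' Age-gender-year demographic table
#'
#' The universal container for demographic quantities: a numeric array indexed
#' by single age (integer years), gender (`"male"`/`"female"`) and calendar
#' year.  Rates and prevalences are annual probabilities/proportions in
#' \[0, 1\], population is persons, life expectancy is years.  The index is
#' rectangular: every age x gender x year combination holds exactly one value.
#'
#' @param value numeric, recycled over the full index (age varies fastest,
#'   then gender, then year).
#' @param ages integer vector of single ages, within \[0, 99\].
#' @param years integer vector of calendar years.
#' @param genders character, kept as `c("male", "female")` in practice.
#' @return a 3-d numeric array with dimnames `age`, `gender`, `year`.
#' @export
#' @examples
#' mu <- agy_table(0.01, ages = 18:99, years = 2012:2060)
#' dim(mu)
agy_table <- function(value, ages, years, genders = c("male", "female")) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (any(ages < 0L | ages > 99L)) stop("ages must lie in [0, 99]")
  arr <- array(as.numeric(value),
               dim = c(length(ages), length(genders), length(years)),
               dimnames = list(age = as.character(ages),
                               gender = genders,
                               year = as.character(years)))
  arr
}

#' @rdname agy_table
#' @param x an age-gender-year array or age-gender matrix.
#' @export
agy_ages <- function(x) as.integer(dimnames(x)[["age"]])

#' @rdname agy_table
#' @export
agy_years <- function(x) as.integer(dimnames(x)[["year"]])

#' @rdname agy_table
#' @export
agy_genders <- function(x) dimnames(x)[["gender"]]

#' Age-gender matrix for base-year quantities
#'
#' Base-year-only quantities (initial life expectancy, initial prevalence) are
#' age x gender matrices sharing the age/gender dimnames of [agy_table()].
#'
#' @inheritParams agy_table
#' @return an age x gender numeric matrix.
#' @export
ag_matrix <- function(value, ages, genders = c("male", "female")) {
  ages <- as.integer(ages)
  matrix(as.numeric(value), nrow = length(ages), ncol = length(genders),
         dimnames = list(age = as.character(ages), gender = genders))
}

# Bounds/shape checks shared by the bundle validators.  `what` picks the
# admissible range; counts and life expectancy are unbounded above.
validate_agy <- function(x, what = c("rate", "count", "le"), name = "table") {
  what <- match.arg(what)
  if (!is.numeric(x) || anyNA(x)) {
    stop(name, ": values must be numeric and complete (no NA)")
  }
  if (any(x < 0)) stop(name, ": values must be >= 0")
  if (what == "rate" && any(x > 1)) {
    stop(name, ": rates/prevalences must lie in [0, 1]")
  }
  dn <- dimnames(x)
  if (is.null(dn) || is.null(dn[["age"]]) || is.null(dn[["gender"]])) {
    stop(name, ": missing age/gender dimnames")
  }
  invisible(x)
}

# Stop unless two tables share an identical age/gender(/year) index.
check_same_index <- function(x, y, xname = "x", yname = "y") {
  if (!identical(dim(x), dim(y)) || !identical(dimnames(x), dimnames(y))) {
    stop("index mismatch between ", xname, " and ", yname)
  }
  invisible(TRUE)
}

#' Convert between long data frames and demographic arrays
#'
#' Long format uses columns `age`, `gender`, `value` and (for year-indexed
#' tables) `year` — the same layout the delimited input files use.
#'
#' @param x an array from [agy_table()] or matrix from [ag_matrix()].
#' @return `agy_to_df()`: a long data frame; `df_to_agy()`/`df_to_ag()`: the
#'   corresponding array/matrix, erroring if the index is not rectangular.
#' @export
agy_to_df <- function(x) {
  if (length(dim(x)) == 3L) {
    df <- expand.grid(age = agy_ages(x), gender = agy_genders(x),
                      year = agy_years(x),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$value <- as.vector(x)
  } else {
    df <- expand.grid(age = agy_ages(x), gender = agy_genders(x),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$value <- as.vector(x)
  }
  df
}

#' @rdname agy_to_df
#' @param df a long data frame with columns `age`, `gender`, `year`, `value`.
#' @export
df_to_agy <- function(df) {
  need <- c("age", "gender", "year", "value")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  ages <- sort(unique(as.integer(df$age)))
  years <- sort(unique(as.integer(df$year)))
  genders <- c("male", "female")
  if (!all(df$gender %in% genders)) stop("gender must be 'male' or 'female'")
  if (nrow(df) != length(ages) * length(years) * length(genders)) {
    stop("index is not rectangular: expected every age x gender x year once")
  }
  arr <- agy_table(NA_real_, ages, years, genders)
  arr[cbind(as.character(df$age), df$gender, as.character(df$year))] <- df$value
  if (anyNA(arr)) stop("index is not rectangular: duplicated or missing cells")
  arr
}

#' @rdname agy_to_df
#' @export
df_to_ag <- function(df) {
  need <- c("age", "gender", "value")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  ages <- sort(unique(as.integer(df$age)))
  genders <- c("male", "female")
  if (!all(df$gender %in% genders)) stop("gender must be 'male' or 'female'")
  if (nrow(df) != length(ages) * length(genders)) {
    stop("index is not rectangular: expected every age x gender once")
  }
  m <- ag_matrix(NA_real_, ages)
  m[cbind(as.character(df$age), df$gender)] <- df$value
  if (anyNA(m)) stop("index is not rectangular: duplicated or missing cells")
  m
}

# Broadcast a base-year age x gender matrix across a span of years.
ag_to_agy <- function(m, years) {
  arr <- agy_table(rep(as.vector(m), times = length(years)),
                   ages = agy_ages(m), years = years,
                   genders = agy_genders(m))
  arr
}
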