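#' Expand an age-grouped table to single ages (uniform within group)
#'
#' National statistics often publish mortality in five-year age groups.  The
#' model works on single ages, assuming the same value for every age inside a
#' group.  Groups are closed integer intervals `[age_lo, age_hi]` and must
#' cover every requested age without overlapping.
#'
#' @param grouped data frame with columns `age_lo`, `age_hi`, `gender`,
#'   `value`, and optionally `year`.
#' @param ages integer vector of single ages to produce.
#' @return an age x gender matrix, or an age x gender x year array when the
#'   input carries a `year` column.
#' @export
#' @examples
#' g <- data.frame(age_lo = c(60, 65), age_hi = c(64, 99),
#'                 gender = rep(c("male", "female"), each = 2),
#'                 value = c(0.012, 0.05, 0.008, 0.04))
#' expand_groups_uniform(g[c(1, 3), ], ages = 60:64)
expand_groups_uniform <- function(grouped, ages) {
  check_grouped(grouped)
  ages <- as.integer(ages)
  has_year <- "year" %in% names(grouped)
  genders <- c("male", "female")
  if (has_year) {
    years <- sort(unique(as.integer(grouped$year)))
    out <- agy_table(NA_real_, ages, years)
    for (g in genders) {
      for (y in years) {
        sub <- grouped[grouped$gender == g & grouped$year == y, , drop = FALSE]
        out[, g, as.character(y)] <- assign_groups(sub, ages)
      }
    }
  } else {
    out <- ag_matrix(NA_real_, ages)
    for (g in genders) {
      sub <- grouped[grouped$gender == g, , drop = FALSE]
      out[, g] <- assign_groups(sub, ages)
    }
  }
  out
}

# Map each single age onto its (unique) covering group's value.
assign_groups <- function(sub, ages) {
  if (nrow(sub) == 0L) stop("no groups for one gender/year stratum")
  vals <- rep(NA_real_, length(ages))
  for (i in seq_len(nrow(sub))) {
    hit <- ages >= sub$age_lo[i] & ages <= sub$age_hi[i]
    vals[hit] <- sub$value[i]
  }
  if (anyNA(vals)) {
    stop("coverage error: ages ", paste(ages[is.na(vals)], collapse = ", "),
         " fall in no group")
  }
  vals
}

check_grouped <- function(grouped) {
  need <- c("age_lo", "age_hi", "gender", "value")
  if (!all(need %in% names(grouped))) {
    stop("grouped table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(grouped) == 0L) stop("grouped table is empty")
  if (any(grouped$age_lo > grouped$age_hi)) {
    stop("schema error: age_lo > age_hi in a group")
  }
  key <- if ("year" %in% names(grouped)) {
    paste(grouped$gender, grouped$year)
  } else {
    grouped$gender
  }
  for (k in unique(key)) {
    sub <- grouped[key == k, , drop = FALSE]
    sub <- sub[order(sub$age_lo), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$age_lo[-1L] <= sub$age_hi[-nrow(sub)])) {
      stop("schema error: overlapping age groups (", k, ")")
    }
  }
  invisible(grouped)
}

#' Smooth age-group prevalence into single-age prevalence
#'
#' Places each group's value at the group midpoint `floor((lo + hi) / 2)`,
#' interpolates linearly between consecutive midpoints, and holds the value
#' flat below the first and above the last midpoint.  For the German group
#' structure 18-29 / 30-44 / 45-64 / 65-99 this gives ages 18-22 the value at
#' midpoint 23 and ages 83-99 the value at midpoint 82.
#'
#' @param grouped data frame with columns `age_lo`, `age_hi`, `gender`,
#'   `value` (a base-year quantity: no `year` column).
#' @param ages integer vector of single ages to produce.
#' @return an age x gender matrix of smoothed prevalence.
#' @seealso [expand_groups_uniform()] for the step-function alternative used
#'   for mortality.
#' @export
smooth_group_prevalence <- function(grouped, ages) {
  check_grouped(grouped)
  if ("year" %in% names(grouped)) {
    stop("smoothing applies to base-year prevalence; drop the year column")
  }
  ages <- as.integer(ages)
  out <- ag_matrix(NA_real_, ages)
  for (g in c("male", "female")) {
    sub <- grouped[grouped$gender == g, , drop = FALSE]
    sub <- sub[order(sub$age_lo), , drop = FALSE]
    mid <- floor((sub$age_lo + sub$age_hi) / 2)
    if (nrow(sub) == 1L) {
      out[, g] <- sub$value
    } else {
      # rule = 2 extends the end values flat beyond the outer midpoints
      out[, g] <- stats::approx(mid, sub$value, xout = ages, rule = 2)$y
    }
  }
  out
}
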