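#' Read and write demographic tables as delimited text
#'
#' All inputs and outputs use comma-separated UTF-8 text with a header row.
#' Year-indexed tables use columns `age`, `gender`, `year`, `value`;
#' base-year tables drop `year`; grouped tables use `age_lo`, `age_hi`;
#' the base-year prevalence table adds a `status` column
#' (never/current/former).
#'
#' @param x table to write.
#' @param path file path.
#' @return readers return the array/matrix/data frame; writers return the
#'   path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_agy_csv <- function(x, path) {
  utils::write.csv(agy_to_df(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_agy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("year" %in% names(df)) df_to_agy(df) else df_to_ag(df)
}

#' @rdname table_io
#' @export
write_grouped_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_grouped_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_grouped(df)
  df
}

prevalence_to_df <- function(prev) {
  df <- expand.grid(age = as.integer(dimnames(prev)$age),
                    gender = dimnames(prev)$gender,
                    status = dimnames(prev)$status,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- as.vector(prev)
  df
}

df_to_prevalence <- function(df) {
  ages <- sort(unique(as.integer(df$age)))
  statuses <- c("never", "current", "former")
  prev <- array(NA_real_, dim = c(length(ages), 2L, 3L),
                dimnames = list(age = as.character(ages),
                                gender = c("male", "female"),
                                status = statuses))
  prev[cbind(as.character(df$age), df$gender, df$status)] <- df$value
  if (anyNA(prev)) stop("prevalence table is not rectangular")
  prev
}

#' Write a country/reference bundle pair to a directory
#'
#' One CSV per quantity plus a `manifest.yaml` naming each file, its units
#' and age convention — the same format [read_bundles()] consumes
#' (round-trip safe).
#'
#' @param bundles list with `country` and `reference` as returned by
#'   [generate_bundles()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_bundles <- function(bundles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- bundles$country; re <- bundles$reference
  files <- list(
    population = "population.csv", mortality = "mortality.csv",
    le_base = "life_expectancy_base.csv",
    prevalence_base = "smoking_prevalence_base.csv",
    ref_init = "ref_initiation.csv", ref_cess = "ref_cessation.csv",
    ref_mu_never = "ref_mortality_never.csv",
    ref_mu_current = "ref_mortality_current.csv",
    ref_mu_former = "ref_mortality_former.csv",
    ref_le_never = "ref_life_expectancy_never.csv",
    ref_prev_base = "ref_prevalence_base.csv",
    ref_le_overall_base = "ref_life_expectancy_overall_base.csv",
    ref_mu_overall = "ref_mortality_overall.csv")
  p <- function(f) file.path(dir, f)
  write_agy_csv(co$population, p(files$population))
  write_agy_csv(co$mortality, p(files$mortality))
  write_agy_csv(co$le_base, p(files$le_base))
  utils::write.csv(prevalence_to_df(co$prevalence_base),
                   p(files$prevalence_base), row.names = FALSE, quote = FALSE)
  write_agy_csv(re$init, p(files$ref_init))
  write_agy_csv(re$cess, p(files$ref_cess))
  write_agy_csv(re$mu_never, p(files$ref_mu_never))
  write_agy_csv(re$mu_current, p(files$ref_mu_current))
  write_agy_csv(re$mu_former, p(files$ref_mu_former))
  write_agy_csv(re$le_never, p(files$ref_le_never))
  write_agy_csv(re$prev_base, p(files$ref_prev_base))
  write_agy_csv(re$le_overall_base, p(files$ref_le_overall_base))
  write_agy_csv(re$mu_overall, p(files$ref_mu_overall))
  manifest <- list(
    files = files,
    units = list(population = "persons", mortality = "probability/yr",
                 life_expectancy = "years", prevalence = "proportion",
                 rates = "probability/yr"),
    age_convention = "single",
    window = list(base_year = co$base_year, end_year = co$end_year,
                  min_age = co$min_age, max_age = co$max_age))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

#' Read a country/reference bundle pair from a manifest
#'
#' @param manifest path to a `manifest.yaml` written by [write_bundles()].
#' @return list with `country` and `reference` bundles.
#' @export
read_bundles <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  p <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("manifest names a missing file: ", f)
    path
  }
  f <- m$files
  w <- m$window
  country <- country_bundle(
    population = read_agy_csv(p(f$population)),
    mortality = read_agy_csv(p(f$mortality)),
    le_base = read_agy_csv(p(f$le_base)),
    prevalence_base = df_to_prevalence(
      utils::read.csv(p(f$prevalence_base), stringsAsFactors = FALSE)),
    base_year = w$base_year, end_year = w$end_year,
    min_age = w$min_age, max_age = w$max_age)
  reference <- reference_bundle(
    init = read_agy_csv(p(f$ref_init)),
    cess = read_agy_csv(p(f$ref_cess)),
    mu_never = read_agy_csv(p(f$ref_mu_never)),
    mu_current = read_agy_csv(p(f$ref_mu_current)),
    mu_former = read_agy_csv(p(f$ref_mu_former)),
    le_never = read_agy_csv(p(f$ref_le_never)),
    prev_base = read_agy_csv(p(f$ref_prev_base)),
    le_overall_base = read_agy_csv(p(f$ref_le_overall_base)),
    mu_overall = read_agy_csv(p(f$ref_mu_overall)))
  list(country = country, reference = reference)
}
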