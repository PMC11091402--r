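# Accessors for the bundled summary tables of a 12-year immunogenetics EQA
# programme (2011-2022): yearly success rates, result volumes and
# participation by scheme. Used as regression fixtures and as defaults for
# the synthetic-data generator.

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "immunoEQA", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published yearly success rates by scheme
#'
#' @return data.frame with columns `scheme`, `family`, `year`, `rate`
#'   (percent).
#' @export
reference_success_rates <- function() read_extdata("reference_success_rates.csv")

#' Published per-scheme mean success rates
#'
#' The printed per-scheme means; recomputing them from
#' [reference_success_rates()] with [scheme_mean()] reproduces every row
#' except B57, whose printed mean appears to have been taken over unrounded
#' yearly inputs (printed 99.4 vs 99.3 recomputed).
#'
#' @return data.frame with columns `scheme`, `family`, `printed_mean`.
#' @export
reference_scheme_means <- function() read_extdata("reference_scheme_means.csv")

#' Published result volumes by scheme and year
#'
#' @return data.frame with columns `scheme`, `year`, `n`.
#' @export
reference_result_counts <- function() read_extdata("reference_result_counts.csv")

#' Published per-scheme result totals
#'
#' @return data.frame with columns `scheme`, `total`.
#' @export
reference_result_totals <- function() read_extdata("reference_result_totals.csv")

#' Published participation counts by scheme and year
#'
#' @return data.frame with columns `scheme`, `year`, `n_labs`.
#' @export
reference_participation <- function() read_extdata("reference_participation.csv")
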