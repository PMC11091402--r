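# Roll-ups: success rates by scheme-year, scheme and family means, result
# volume totals, error-category breakdowns, method frequencies and the
# pass-all-schemes statistic.

#' Scheme registry
#'
#' The thirteen schemes of the programme and their analytical families.
#'
#' @return data.frame with columns `scheme`, `family`.
#' @export
scheme_registry <- function() {
  data.frame(
    scheme = c("SER", "B27", "B57", "CD", "XM", "XMFC", "ALO",
               "LOW", "HI", "CHM", "KIR", "HPA", "AHPA"),
    family = c("Serology", "Molecular typing", "Molecular typing",
               "Molecular typing", "Crossmatch", "Crossmatch", "Antibodies",
               "Molecular typing", "Molecular typing", "Chimerism",
               "Molecular typing", "Molecular typing", "Antibodies"),
    stringsAsFactors = FALSE
  )
}

as_status_vector <- function(evals) {
  if (is.data.frame(evals)) evals$status else evals
}

#' Success rate over valid results
#'
#' 100 times the number of error-free results over valid data; not-evaluable
#' results are excluded from both numerator and denominator. Returned
#' unrounded; presentation tables round half-up to one decimal.
#'
#' @param evals data.frame with a `status` column, or a status character
#'   vector.
#' @return success rate in percent.
#' @export
success_rate <- function(evals) {
  status <- as_status_vector(evals)
  valid <- status %in% c("CORRECT", "ERROR")
  if (!any(valid)) stop_eqa("no_valid_results", "no valid results")
  100 * sum(status == "CORRECT") / sum(valid)
}

#' Mean of yearly success rates for one scheme
#'
#' Unweighted arithmetic mean over the years the scheme ran, rounded half-up
#' to one decimal unless `round = FALSE` (family means should be computed over
#' unrounded scheme means).
#'
#' @param yearly_rates numeric vector of yearly success rates in percent.
#' @param round round the result for presentation.
#' @return mean rate in percent.
#' @export
scheme_mean <- function(yearly_rates, round = TRUE) {
  if (length(yearly_rates) == 0L) stop_eqa("empty_input", "no yearly rates")
  m <- mean(yearly_rates)
  if (round) round_half_up(m, 1) else m
}

#' Mean success rate of an analytical family
#'
#' Unweighted mean of the family's scheme means (not a result-count-weighted
#' pool), rounded half-up to one decimal.
#'
#' @param scheme_means numeric vector of scheme mean rates in percent.
#' @return family mean in percent.
#' @export
family_mean <- function(scheme_means) {
  if (length(scheme_means) == 0L) stop_eqa("empty_input", "no scheme means")
  round_half_up(mean(scheme_means), 1)
}

#' Result-volume totals by scheme and year
#'
#' @param counts data.frame with columns `scheme`, `year`, `n` (one row per
#'   scheme-year).
#' @return data.frame, one row per scheme, one column per year plus a `Total`
#'   column; schemes ordered by descending total.
#' @export
totals_table <- function(counts) {
  stopifnot(all(c("scheme", "year", "n") %in% names(counts)))
  wide <- as.data.frame.matrix(stats::xtabs(n ~ scheme + year, data = counts))
  out <- data.frame(scheme = rownames(wide), wide, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$Total <- rowSums(wide)
  out[order(-out$Total), , drop = FALSE]
}

#' Result-volume totals by analytical family
#'
#' @param counts data.frame with columns `scheme`, `n`.
#' @param registry scheme-to-family mapping, default [scheme_registry()].
#' @return data.frame with columns `family`, `total`.
#' @export
family_totals <- function(counts, registry = scheme_registry()) {
  stopifnot(all(c("scheme", "n") %in% names(counts)))
  fam <- registry$family[match(counts$scheme, registry$scheme)]
  if (anyNA(fam)) {
    stop_eqa("unknown_scheme", "counts contain schemes outside the registry")
  }
  agg <- stats::aggregate(list(total = counts$n), by = list(family = fam), sum)
  agg[order(-agg$total), , drop = FALSE]
}

#' Error-category breakdown
#'
#' Percentage of errors in each category, over the error count only.
#'
#' @param evals data.frame with `status` and `category` columns.
#' @return data.frame with columns `category`, `n`, `percent` (half-up, one
#'   decimal), sorted by descending share.
#' @export
error_breakdown <- function(evals) {
  err <- evals[evals$status == "ERROR", , drop = FALSE]
  if (nrow(err) == 0L) stop_eqa("no_errors", "no errors to break down")
  tab <- table(err$category)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    percent = round_half_up(100 * as.integer(tab) / nrow(err), 1),
                    stringsAsFactors = FALSE)
  out[order(-out$n, out$category), , drop = FALSE]
}

#' Fraction of laboratories passing every scheme
#'
#' Denominator: laboratories with at least one scheme outcome that year.
#'
#' @param outcomes data.frame with columns `lab` and `outcome`
#'   (`"PASS"`/`"FAIL"`), one row per lab-scheme.
#' @return percent of laboratories with zero failed schemes (half-up, one
#'   decimal).
#' @export
labs_passing_all <- function(outcomes) {
  stopifnot(all(c("lab", "outcome") %in% names(outcomes)))
  if (nrow(outcomes) == 0L) stop_eqa("no_labs", "no laboratory outcomes")
  all_pass <- tapply(outcomes$outcome == "PASS", outcomes$lab, all)
  round_half_up(100 * mean(all_pass), 1)
}

#' Most performed method by scheme and year
#'
#' Modal method tag and its share among reporting laboratories; ties are
#' broken lexicographically and flagged.
#'
#' @param reports data.frame with columns `scheme`, `year`, `lab`, `method`
#'   (method tags; one tag per laboratory per scheme-year is counted once).
#' @return data.frame with columns `scheme`, `year`, `method`, `share`
#'   (percent, half-up one decimal), `tie`.
#' @export
method_frequency <- function(reports) {
  stopifnot(all(c("scheme", "year", "lab", "method") %in% names(reports)))
  key <- unique(reports[, c("scheme", "year", "lab", "method")])
  groups <- split(key, list(key$scheme, key$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    tab <- sort(table(g$method), decreasing = TRUE)
    tie <- sum(tab == tab[1L]) > 1L
    winner <- sort(names(tab)[tab == tab[1L]])[1L]
    data.frame(scheme = g$scheme[1L], year = g$year[1L], method = winner,
               share = round_half_up(100 * tab[[winner]] / nrow(g), 1),
               tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scheme, out$year), , drop = FALSE]
}

#' Scheme-year summary statistics
#'
#' Counts and success rate for each scheme-year present in the evaluations.
#'
#' @param evals evaluations data.frame with columns `lab`, `scheme`, `year`,
#'   `status`.
#' @param registry scheme-to-family mapping, default [scheme_registry()].
#' @return data.frame with columns `scheme`, `family`, `year`, `n_labs`,
#'   `n_results`, `n_valid`, `n_errors`, `success_rate` (half-up, one
#'   decimal). Scheme-years with no valid result carry `NA` rates.
#' @export
scheme_year_stats <- function(evals, registry = scheme_registry()) {
  stopifnot(all(c("lab", "scheme", "year", "status") %in% names(evals)))
  groups <- split(evals, list(evals$scheme, evals$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    n_valid <- sum(g$status != "NOT_EVALUABLE")
    rate <- if (n_valid > 0) {
      round_half_up(100 * sum(g$status == "CORRECT") / n_valid, 1)
    } else {
      NA_real_
    }
    data.frame(scheme = g$scheme[1L],
               family = registry$family[match(g$scheme[1L], registry$scheme)],
               year = g$year[1L],
               n_labs = length(unique(g$lab)),
               n_results = nrow(g),
               n_valid = n_valid,
               n_errors = sum(g$status == "ERROR"),
               success_rate = rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scheme, out$year), , drop = FALSE]
}
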