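# Per-result scoring against assigned values and classification into the
# error taxonomy, plus the per-laboratory scheme-year pass rule.

ERROR_CATEGORIES <- c("NULL_ALLELE", "HOMOZYGOSITY", "ALLELE_MISMATCH",
                      "NOMENCLATURE", "FALSE_POSITIVE_SPECIFICITY",
                      "FALSE_NEGATIVE_SPECIFICITY", "SCREENING",
                      "QUANTIFICATION", "QUALITATIVE_MISMATCH",
                      "RISK_INTERPRETATION")

#' Construct a single evaluation
#'
#' @param status one of `"CORRECT"`, `"ERROR"`, `"NOT_EVALUABLE"`.
#' @param category error category; required exactly when `status == "ERROR"`.
#' @return an object of class `eqa_evaluation` (list with `status`,
#'   `category`).
#' @export
evaluation <- function(status, category = NA_character_) {
  status <- match.arg(status, c("CORRECT", "ERROR", "NOT_EVALUABLE"))
  if (status == "ERROR") {
    if (is.na(category) || !category %in% ERROR_CATEGORIES) {
      stop_eqa("invalid_evaluation", "an ERROR needs a known category")
    }
  } else if (!is.na(category)) {
    stop_eqa("invalid_evaluation", "only ERROR evaluations carry a category")
  }
  structure(list(status = status, category = category),
            class = "eqa_evaluation")
}

#' @export
print.eqa_evaluation <- function(x, ...) {
  cat("<evaluation> ", x$status,
      if (!is.na(x$category)) paste0("/", x$category), "\n", sep = "")
  invisible(x)
}

truth_has_null <- function(genotype) {
  any(vapply(genotype$calls, function(cl) {
    any(vapply(cl$alternatives, is_null_allele, logical(1)))
  }, logical(1)))
}

# Has the laboratory effectively reported a single distinct allele call,
# either as one call or by doubling the same allele?
single_allele_claim <- function(genotype) {
  if (length(genotype$calls) == 1L) return(genotype$calls[[1L]])
  if (identical(render_call(genotype$calls[[1L]]),
                render_call(genotype$calls[[2L]]))) {
    return(genotype$calls[[1L]])
  }
  NULL
}

truth_is_homozygous <- function(genotype) {
  if (length(genotype$calls) == 1L) return(TRUE)
  call_matches(genotype$calls[[1L]], genotype$calls[[2L]]) &&
    call_matches(genotype$calls[[2L]], genotype$calls[[1L]])
}

#' Score a typing result
#'
#' Decision order (each result counted once, so the taxonomy partitions):
#' 1. unparseable payload or wrong locus: ERROR/NOMENCLATURE;
#' 2. any reported call still encompassing an unexcluded null allele while the
#'    assigned genotype carries only expressed alleles: ERROR/NULL_ALLELE;
#' 3. concordant with the assigned genotype (at the reported resolution):
#'    CORRECT;
#' 4. a single distinct reported allele (single call or doubled) against a
#'    heterozygous assigned genotype, concordant with one assigned copy:
#'    ERROR/HOMOZYGOSITY;
#' 5. anything else: ERROR/ALLELE_MISMATCH.
#'
#' @param report a genotype string or `eqa_genotype`; strings that fail to
#'   parse score as nomenclature errors.
#' @param assigned an [assigned_value()] carrying a genotype (REFERENCE or
#'   CONSENSUS); a NOT_EVALUABLE assigned value yields a NOT_EVALUABLE
#'   evaluation.
#' @param excluded_nulls exclusions accompanying a string `report`.
#' @param params an [consensus_params()] object (unused by the default rules,
#'   kept for signature stability).
#' @return an [evaluation()].
#' @examples
#' truth <- typing_assigned_value(list(), parse_genotype("A*02:01+A*68:01"))
#' evaluate_typing("A*02:01+A*02:01", truth)
#' @export
evaluate_typing <- function(report, assigned, excluded_nulls = character(),
                            params = consensus_params()) {
  stopifnot(inherits(assigned, "eqa_assigned"))
  if (assigned$mode == "NOT_EVALUABLE") return(evaluation("NOT_EVALUABLE"))
  truth <- assigned$payload
  stopifnot(inherits(truth, "eqa_genotype"))

  if (is.character(report)) {
    report <- tryCatch(parse_genotype(report, excluded_nulls),
                       immunoEQA_error = function(e) NULL)
    if (is.null(report)) return(evaluation("ERROR", "NOMENCLATURE"))
  }
  stopifnot(inherits(report, "eqa_genotype"))
  if (report$locus != truth$locus) {
    return(evaluation("ERROR", "NOMENCLATURE"))
  }

  if (!truth_has_null(truth) &&
      any(vapply(report$calls, unexcluded_null, logical(1)))) {
    return(evaluation("ERROR", "NULL_ALLELE"))
  }

  if (genotype_concordant(report, truth)) return(evaluation("CORRECT"))

  claim <- single_allele_claim(report)
  if (!is.null(claim) && !truth_is_homozygous(truth) &&
      any(vapply(truth$calls, function(tc) call_matches(claim, tc),
                 logical(1)))) {
    return(evaluation("ERROR", "HOMOZYGOSITY"))
  }

  evaluation("ERROR", "ALLELE_MISMATCH")
}

#' Score an antibody specificity panel
#'
#' Each panel specificity is scored against its consensus status: an assigned
#' POSITIVE that the laboratory omitted is a false-negative identification
#' error; an assigned NEGATIVE that the laboratory reported is a
#' false-positive; NON_ASSESSABLE and NO_CONSENSUS specificities are not
#' evaluable (not penalized). Screening (class I/II positive-negative) calls
#' are qualitative results; score them with
#' `evaluate_qualitative(..., mismatch_category = "SCREENING")`.
#'
#' @param reported_positive character vector of specificities the laboratory
#'   reported positive.
#' @param assigned_map named character vector of consensus statuses from
#'   [antibody_consensus()], one entry per panel specificity.
#' @return data.frame with columns `specificity`, `status`, `category`.
#' @export
evaluate_antibody <- function(reported_positive, assigned_map) {
  panel <- names(assigned_map)
  if (is.null(panel)) {
    stop_eqa("unknown_specificity", "assigned_map must be named by specificity")
  }
  unknown <- setdiff(reported_positive, panel)
  if (length(unknown) > 0L) {
    stop_eqa("unknown_specificity",
             paste("specificities not in the panel:",
                   paste(unknown, collapse = ", ")))
  }
  reported <- panel %in% reported_positive
  status <- character(length(panel))
  category <- rep(NA_character_, length(panel))
  for (i in seq_along(panel)) {
    a <- assigned_map[[i]]
    if (a %in% c("NON_ASSESSABLE", "NO_CONSENSUS")) {
      status[i] <- "NOT_EVALUABLE"
    } else if (a == "POSITIVE" && !reported[i]) {
      status[i] <- "ERROR"
      category[i] <- "FALSE_NEGATIVE_SPECIFICITY"
    } else if (a == "NEGATIVE" && reported[i]) {
      status[i] <- "ERROR"
      category[i] <- "FALSE_POSITIVE_SPECIFICITY"
    } else {
      status[i] <- "CORRECT"
    }
  }
  data.frame(specificity = panel, status = status, category = category,
             stringsAsFactors = FALSE)
}

#' Score a quantitative chimerism result
#'
#' With a positive robust scale the result is acceptable when
#' `|value - x*| / s* <= z_limit`; with a degenerate scale (`s* = 0`) an
#' absolute window of `abs_tol` percentage points applies. Unacceptable
#' results are quantification errors.
#'
#' @param value reported percent recipient, in \[0, 100\].
#' @param assigned an [assigned_value()] wrapping `eqa_robust` statistics, or
#'   the `eqa_robust` itself.
#' @param params an [consensus_params()] object (`z_limit`, `abs_tol`).
#' @return an [evaluation()].
#' @export
evaluate_chimerism <- function(value, assigned, params = consensus_params()) {
  if (is.na(value) || value < 0 || value > 100) {
    stop_eqa("out_of_range", "chimerism values must lie in [0, 100]")
  }
  if (inherits(assigned, "eqa_assigned")) {
    if (assigned$mode == "NOT_EVALUABLE") return(evaluation("NOT_EVALUABLE"))
    assigned <- assigned$payload
  }
  stopifnot(inherits(assigned, "eqa_robust"))
  ok <- if (assigned$s_star > 0) {
    abs(value - assigned$x_star) / assigned$s_star <= params$z_limit
  } else {
    abs(value - assigned$x_star) <= params$abs_tol
  }
  if (ok) evaluation("CORRECT") else evaluation("ERROR", "QUANTIFICATION")
}

#' Score a qualitative (positive/negative) result
#'
#' A whole-blood crossmatch is scored against the whole-blood consensus only,
#' never against the OR of the T- and B-lymphocyte consensuses; pass the
#' matching assigned value. Screening calls take
#' `mismatch_category = "SCREENING"`.
#'
#' @param reported `"POSITIVE"` or `"NEGATIVE"`.
#' @param assigned an [assigned_value()] from [qualitative_consensus()].
#' @param mismatch_category category recorded on mismatch.
#' @return an [evaluation()].
#' @export
evaluate_qualitative <- function(reported, assigned,
                                 mismatch_category = "QUALITATIVE_MISMATCH") {
  stopifnot(reported %in% c("POSITIVE", "NEGATIVE"),
            inherits(assigned, "eqa_assigned"))
  if (assigned$mode == "NOT_EVALUABLE") return(evaluation("NOT_EVALUABLE"))
  if (identical(reported, assigned$payload)) {
    evaluation("CORRECT")
  } else {
    evaluation("ERROR", mismatch_category)
  }
}

# ---- disease-risk interpretation -------------------------------------------

#' Genotype-to-risk mapping
#'
#' A lookup from canonical genotype rendering to an ordered risk-category
#' label, with an optional default for genotypes outside the listed patterns.
#' Maps ship as editable configuration: disease-association scoring depends on
#' local guidelines, so no mapping is hard-coded into the scoring rules.
#'
#' @param patterns named character vector: names are genotype strings (any
#'   parseable form; stored canonically), values are risk labels.
#' @param default label for unlisted genotypes, or `NULL` to make them
#'   unmappable (risk component scored not evaluable).
#' @return an object of class `eqa_risk_map`.
#' @export
risk_map <- function(patterns, default = NULL) {
  stopifnot(is.character(patterns), !is.null(names(patterns)),
            all(nzchar(names(patterns))))
  canon <- vapply(names(patterns), function(p) {
    render_genotype(parse_genotype(p))
  }, character(1))
  if (anyDuplicated(canon)) {
    stop_eqa("invalid_risk_map", "risk-map patterns must be disjoint")
  }
  map <- stats::setNames(unname(patterns), canon)
  structure(list(map = map, default = default), class = "eqa_risk_map")
}

#' Look up the risk category of a genotype
#'
#' @param map an [risk_map()].
#' @param genotype an `eqa_genotype` (or string).
#' @return the risk label, or `NA_character_` when the genotype is unmapped
#'   and the map has no default.
#' @export
risk_lookup <- function(map, genotype) {
  stopifnot(inherits(map, "eqa_risk_map"))
  if (is.character(genotype)) genotype <- parse_genotype(genotype)
  key <- render_genotype(genotype)
  if (key %in% names(map$map)) return(map$map[[key]])
  if (!is.null(map$default)) return(map$default)
  NA_character_
}

#' Default coeliac-disease risk map
#'
#' Literature-informed default mapping from HLA-DQB1 genotypes to ordered risk
#' categories for the coeliac-disease scheme (DQ2.5-homozygous-like genotypes
#' highest; a single DQB1*02 copy lower; everything else the default
#' category). Intended as an editable starting point, not a clinical
#' guideline.
#'
#' @return an [risk_map()].
#' @export
cd_risk_map <- function() {
  risk_map(c(
    "DQB1*02:01+DQB1*02:01" = "HIGH",
    "DQB1*02:01+DQB1*03:02" = "HIGH",
    "DQB1*03:02+DQB1*03:02" = "MODERATE",
    "DQB1*02:01+DQB1*03:01" = "MODERATE",
    "DQB1*02:01+DQB1*05:01" = "LOW",
    "DQB1*03:02+DQB1*03:01" = "LOW"
  ), default = "VERY_LOW")
}

#' Score a disease-association result (genotype + risk interpretation)
#'
#' The genotype component is scored with [evaluate_typing()]; the reported
#' risk label is additionally compared to the risk category implied by the
#' assigned genotype. Misinterpretation of a correctly typed genotype is
#' penalized on the risk component only.
#'
#' @param report_genotype genotype string or `eqa_genotype`.
#' @param report_risk the laboratory's risk label.
#' @param assigned an [assigned_value()] carrying the assigned genotype.
#' @param map an [risk_map()].
#' @param excluded_nulls exclusions accompanying a string genotype report.
#' @param params an [consensus_params()] object.
#' @return list with elements `typing` and `risk`, each an [evaluation()];
#'   the risk component is NOT_EVALUABLE when the assigned genotype is
#'   unmapped.
#' @export
evaluate_risk <- function(report_genotype, report_risk, assigned, map,
                          excluded_nulls = character(),
                          params = consensus_params()) {
  typing <- evaluate_typing(report_genotype, assigned, excluded_nulls, params)
  if (assigned$mode == "NOT_EVALUABLE") {
    return(list(typing = typing, risk = evaluation("NOT_EVALUABLE")))
  }
  expected <- risk_lookup(map, assigned$payload)
  risk <- if (is.na(expected)) {
    evaluation("NOT_EVALUABLE")
  } else if (identical(report_risk, expected)) {
    evaluation("CORRECT")
  } else {
    evaluation("ERROR", "RISK_INTERPRETATION")
  }
  list(typing = typing, risk = risk)
}

#' Laboratory pass/fail for one scheme-year
#'
#' Default rule: a laboratory passes a scheme-year when at most
#' `max_error_samples` of its samples contain at least one error (not
#' evaluable results are ignored). A laboratory with no valid result has no
#' outcome.
#'
#' @param evals data.frame of this laboratory's evaluations for one
#'   scheme-year, with at least columns `sample` and `status`.
#' @param params an [consensus_params()] object (`max_error_samples`).
#' @return `"PASS"` or `"FAIL"`.
#' @export
scheme_pass <- function(evals, params = consensus_params()) {
  stopifnot(all(c("sample", "status") %in% names(evals)))
  valid <- evals$status != "NOT_EVALUABLE"
  if (!any(valid)) {
    stop_eqa("no_valid_results", "laboratory has no valid results")
  }
  errored <- unique(evals$sample[evals$status == "ERROR"])
  if (length(errored) <= params$max_error_samples) "PASS" else "FAIL"
}
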