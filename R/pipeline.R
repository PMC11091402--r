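# Table-level pipeline: assign values for every (scheme, year, sample,
# parameter), evaluate every report row against them, and summarize.

eqa_key <- function(scheme, year, sample, parameter) {
  paste(scheme, year, sample, parameter, sep = "|")
}

render_assigned_payload <- function(av) {
  if (av$mode == "NOT_EVALUABLE") return("")
  p <- av$payload
  if (inherits(p, "eqa_genotype")) return(render_genotype(p))
  if (inherits(p, "eqa_robust")) return(sprintf("%.4g", p$x_star))
  if (is.character(p) && length(p) > 1L) {
    return(paste(names(p), p, sep = ":", collapse = ";"))
  }
  as.character(p)
}

#' Assign values to every parameter in a report table
#'
#' Reference mode is used for typing parameters whenever an organizer truth
#' table is supplied (the organizer's typing results are considered correct);
#' all other parameters are assigned by participant consensus: the 75%/95%
#' antibody rules per specificity, majority consensus for qualitative calls,
#' and the robust location/scale estimator for quantitative chimerism.
#'
#' @param reports report data.frame (see [generate_reports()] for the schema).
#' @param truth optional truth/reference data.frame (see [generate_truth()]).
#' @param panel antibody panel; defaults to the union of reported and true
#'   specificities.
#' @param params an [consensus_params()] object.
#' @return list with `index` (named list of [assigned_value()] objects keyed
#'   by `scheme|year|sample|parameter`) and `summary` (one row per parameter:
#'   mode, rendered payload, support, n, x_star, s_star).
#' @export
assign_values <- function(reports, truth = NULL, panel = NULL,
                          params = consensus_params()) {
  stopifnot(all(c("lab", "scheme", "year", "sample", "parameter", "type",
                  "payload") %in% names(reports)))
  truth_key <- if (!is.null(truth)) {
    stats::setNames(truth$payload,
                    eqa_key(truth$scheme, truth$year, truth$sample,
                            truth$parameter))
  }
  if (is.null(panel)) {
    spec_rows <- reports$type == "specificities"
    panel <- sort(unique(c(
      unlist(strsplit(reports$payload[spec_rows], ";", fixed = TRUE)),
      if (!is.null(truth)) {
        unlist(strsplit(truth$payload[truth$type == "specificities"], ";",
                        fixed = TRUE))
      }
    )))
  }

  groups <- split(reports,
                  eqa_key(reports$scheme, reports$year, reports$sample,
                          reports$parameter))
  index <- vector("list", length(groups))
  names(index) <- names(groups)
  summary_rows <- vector("list", length(groups))

  for (j in seq_along(groups)) {
    g <- groups[[j]]
    key <- names(groups)[j]
    type <- g$type[1L]
    av <- switch(
      type,
      genotype = {
        ref <- if (!is.null(truth_key) && key %in% names(truth_key)) {
          parse_genotype(truth_key[[key]])
        }
        genos <- lapply(g$payload, function(p) {
          tryCatch(parse_genotype(p), immunoEQA_error = function(e) NULL)
        })
        typing_assigned_value(Filter(Negate(is.null), genos), ref, params)
      },
      quantitative = chimerism_assigned(as.numeric(g$payload), params),
      specificities = {
        sets <- strsplit(g$payload, ";", fixed = TRUE)
        n_pos <- vapply(panel, function(sp) {
          sum(vapply(sets, function(x) sp %in% x, logical(1)))
        }, integer(1))
        statuses <- antibody_consensus(n_pos, nrow(g), params)
        assigned_value("CONSENSUS", statuses, n = nrow(g))
      },
      risk = assigned_value("NOT_EVALUABLE", n = nrow(g)),
      qualitative_consensus(g$payload, params) # qualitative, screening, ...
    )
    index[[j]] <- av
    summary_rows[[j]] <- data.frame(
      scheme = g$scheme[1L], year = g$year[1L], sample = g$sample[1L],
      parameter = g$parameter[1L], mode = av$mode,
      payload = render_assigned_payload(av),
      support = av$support, n = av$n,
      x_star = if (inherits(av$payload, "eqa_robust")) av$payload$x_star else NA_real_,
      s_star = if (inherits(av$payload, "eqa_robust")) av$payload$s_star else NA_real_,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(index = index,
       summary = summary[order(summary$scheme, summary$year, summary$sample,
                               summary$parameter), , drop = FALSE])
}

#' Evaluate every report row against its assigned value
#'
#' Typing rows go through [evaluate_typing()] (risk rows of
#' disease-association schemes are compared to the risk category implied by
#' the sample's assigned genotype); antibody specificity rows expand to one
#' evaluation per panel specificity via [evaluate_antibody()]; screening and
#' other qualitative rows go through [evaluate_qualitative()]; quantitative
#' rows through [evaluate_chimerism()].
#'
#' @param reports report data.frame.
#' @param assigned output of [assign_values()].
#' @param map an [risk_map()] for risk rows (default [cd_risk_map()]).
#' @param params an [consensus_params()] object.
#' @return data.frame with columns `lab`, `scheme`, `year`, `sample`,
#'   `parameter`, `method`, `status`, `category` -- one row per scored
#'   parameter, specificity rows expanded per specificity.
#' @export
evaluate_reports <- function(reports, assigned, map = cd_risk_map(),
                             params = consensus_params()) {
  index <- assigned$index
  keys <- eqa_key(reports$scheme, reports$year, reports$sample,
                  reports$parameter)
  out <- vector("list", nrow(reports))

  base_row <- function(i, parameter, ev) {
    data.frame(lab = reports$lab[i], scheme = reports$scheme[i],
               year = reports$year[i], sample = reports$sample[i],
               parameter = parameter,
               method = if ("method" %in% names(reports)) reports$method[i] else NA_character_,
               status = ev$status, category = ev$category,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(reports))) {
    type <- reports$type[i]
    av <- index[[keys[i]]]
    if (is.null(av)) av <- assigned_value("NOT_EVALUABLE")

    if (type == "genotype") {
      excl <- reports$excluded_nulls[i]
      excl <- if (is.null(excl) || is.na(excl) || !nzchar(excl)) character() else
        strsplit(excl, ";", fixed = TRUE)[[1L]]
      ev <- evaluate_typing(reports$payload[i], av, excl, params)
      out[[i]] <- base_row(i, "genotype", ev)
    } else if (type == "risk") {
      geno_av <- index[[eqa_key(reports$scheme[i], reports$year[i],
                                reports$sample[i], "genotype")]]
      ev <- if (is.null(geno_av) || geno_av$mode == "NOT_EVALUABLE") {
        evaluation("NOT_EVALUABLE")
      } else {
        expected <- risk_lookup(map, geno_av$payload)
        if (is.na(expected)) {
          evaluation("NOT_EVALUABLE")
        } else if (identical(reports$payload[i], expected)) {
          evaluation("CORRECT")
        } else {
          evaluation("ERROR", "RISK_INTERPRETATION")
        }
      }
      out[[i]] <- base_row(i, "risk", ev)
    } else if (type == "quantitative") {
      ev <- evaluate_chimerism(as.numeric(reports$payload[i]), av, params)
      out[[i]] <- base_row(i, reports$parameter[i], ev)
    } else if (type == "specificities") {
      if (av$mode == "NOT_EVALUABLE") {
        out[[i]] <- base_row(i, "specificities", evaluation("NOT_EVALUABLE"))
      } else {
        reported <- strsplit(reports$payload[i], ";", fixed = TRUE)[[1L]]
        per_spec <- evaluate_antibody(reported, av$payload)
        block <- base_row(i, "x", evaluation("CORRECT"))[rep(1L, nrow(per_spec)), ]
        block$parameter <- paste0("specificity:", per_spec$specificity)
        block$status <- per_spec$status
        block$category <- per_spec$category
        out[[i]] <- block
      }
    } else {
      mismatch <- if (identical(type, "screening")) "SCREENING" else
        "QUALITATIVE_MISMATCH"
      ev <- evaluate_qualitative(reports$payload[i], av, mismatch)
      out[[i]] <- base_row(i, reports$parameter[i], ev)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-laboratory scheme-year outcomes
#'
#' Applies [scheme_pass()] to every laboratory with at least one valid result
#' in a scheme-year; laboratories with no valid result get no outcome.
#'
#' @param evals evaluations data.frame from [evaluate_reports()].
#' @param params an [consensus_params()] object.
#' @return data.frame with columns `lab`, `scheme`, `year`, `outcome`.
#' @export
lab_outcomes <- function(evals, params = consensus_params()) {
  groups <- split(evals, list(evals$lab, evals$scheme, evals$year),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (!any(g$status != "NOT_EVALUABLE")) return(NULL)
    data.frame(lab = g$lab[1L], scheme = g$scheme[1L], year = g$year[1L],
               outcome = scheme_pass(g, params), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out[order(out$lab, out$scheme, out$year), , drop = FALSE]
}

#' Run the full synthetic pipeline
#'
#' Generates truths and error-injected reports, assigns values (organizer
#' reference for typing, participant consensus otherwise), evaluates every
#' result, and aggregates.
#'
#' @param config an [simulation_config()].
#' @param seed master seed.
#' @param use_reference use the generated truths as the organizer reference
#'   for typing parameters (default); `FALSE` forces consensus typing.
#' @return list with `truth`, `reports`, `assigned`, `evaluations`, `stats`
#'   ([scheme_year_stats()]), `outcomes` ([lab_outcomes()]) and `pass_all`
#'   (percent of laboratories passing all schemes, by year).
#' @export
run_eqa_simulation <- function(config = simulation_config(), seed = 1L,
                               use_reference = TRUE) {
  truth <- generate_truth(config, seed)
  reports <- generate_reports(truth, config, seed)
  assigned <- assign_values(reports,
                            truth = if (use_reference) truth,
                            panel = config$antibody_panel,
                            params = config$params)
  evals <- evaluate_reports(reports, assigned, map = config$risk_map,
                            params = config$params)
  outcomes <- lab_outcomes(evals, config$params)
  pass_all <- do.call(rbind, lapply(split(outcomes, outcomes$year), function(g) {
    data.frame(year = g$year[1L], pass_all = labs_passing_all(g),
               stringsAsFactors = FALSE)
  }))
  rownames(pass_all) <- NULL
  list(truth = truth, reports = reports, assigned = assigned,
       evaluations = evals, stats = scheme_year_stats(evals),
       outcomes = outcomes, pass_all = pass_all)
}
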