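# Seeded synthetic laboratory-report generator with error injection. The
# generator emulates the statistical structure the analysis assumes: per
# scheme-year participation, per-result error probabilities and per-scheme
# error-category mixes, method-tag mixes, and payload formats identical to
# the ones the pipeline consumes.

scheme_kinds <- c(SER = "typing", LOW = "typing", HI = "typing",
                  KIR = "typing", HPA = "typing", CD = "typing_risk",
                  B27 = "qualitative", B57 = "qualitative",
                  XM = "qualitative", XMFC = "qualitative",
                  ALO = "antibody", AHPA = "antibody", CHM = "chimerism")

scheme_locus <- c(SER = "HLA-A", LOW = "HLA-A", HI = "HLA-A",
                  CD = "HLA-DQB1", KIR = "KIR2DL1", HPA = "HPA-1")

#' Default allele pool for the generator
#'
#' A small fictitious but nomenclature-valid allele set per locus, each with
#' sampling frequencies for truth genotypes and at least one null allele per
#' molecular locus. Null alleles carry zero truth frequency by default: they
#' exist in the pool so that null-allele errors can be injected, while truth
#' genotypes stay fully expressed.
#'
#' @return named list (by locus) of data.frames with columns `allele`, `freq`.
#' @export
default_allele_pool <- function() {
  list(
    "HLA-A" = data.frame(
      allele = c("A*01:01:01", "A*02:01:01", "A*03:01:01", "A*24:02:01",
                 "A*68:01:01", "A*01:04N"),
      freq = c(0.2, 0.2, 0.2, 0.2, 0.2, 0),
      stringsAsFactors = FALSE),
    "HLA-DQB1" = data.frame(
      allele = c("DQB1*02:01", "DQB1*03:01", "DQB1*03:02", "DQB1*05:01",
                 "DQB1*03:38N"),
      freq = c(0.25, 0.25, 0.25, 0.25, 0),
      stringsAsFactors = FALSE),
    "KIR2DL1" = data.frame(
      allele = c("KIR2DL1*001:01", "KIR2DL1*002:01", "KIR2DL1*003:01",
                 "KIR2DL1*004:01", "KIR2DL1*023N"),
      freq = c(0.25, 0.25, 0.25, 0.25, 0),
      stringsAsFactors = FALSE),
    "HPA-1" = data.frame(
      allele = c("HPA-1*001", "HPA-1*002", "HPA-1*003N"),
      freq = c(0.5, 0.5, 0),
      stringsAsFactors = FALSE)
  )
}

#' Default anti-HLA antibody panel
#'
#' @return character vector of serological specificities.
#' @export
default_antibody_panel <- function() {
  c("A1", "A2", "A3", "A24", "A68", "B7", "B8", "B27", "B44", "B57",
    "Cw4", "Cw6", "DR1", "DR4", "DR7", "DR11", "DR15", "DQ2", "DQ7", "DQ8")
}

default_category_mix <- function() {
  list(
    HI   = c(NULL_ALLELE = 0.601, ALLELE_MISMATCH = 0.2, HOMOZYGOSITY = 0.199),
    KIR  = c(ALLELE_MISMATCH = 0.401, HOMOZYGOSITY = 0.3, NULL_ALLELE = 0.299),
    LOW  = c(ALLELE_MISMATCH = 0.5, HOMOZYGOSITY = 0.3, NULL_ALLELE = 0.2),
    HPA  = c(ALLELE_MISMATCH = 0.5, HOMOZYGOSITY = 0.3, NULL_ALLELE = 0.2),
    SER  = c(ALLELE_MISMATCH = 0.7, HOMOZYGOSITY = 0.3),
    CD   = c(ALLELE_MISMATCH = 0.4, HOMOZYGOSITY = 0.2, NULL_ALLELE = 0.1,
             RISK_INTERPRETATION = 0.3),
    B27  = c(QUALITATIVE_MISMATCH = 1),
    B57  = c(QUALITATIVE_MISMATCH = 1),
    XM   = c(QUALITATIVE_MISMATCH = 1),
    XMFC = c(QUALITATIVE_MISMATCH = 1),
    CHM  = c(QUANTIFICATION = 0.622, QUALITATIVE_MISMATCH = 0.378),
    ALO  = c(FALSE_NEGATIVE_SPECIFICITY = 0.4485,
             FALSE_POSITIVE_SPECIFICITY = 0.4485,
             SCREENING = 0.019, QUALITATIVE_MISMATCH = 0.084),
    AHPA = c(FALSE_NEGATIVE_SPECIFICITY = 0.4485,
             FALSE_POSITIVE_SPECIFICITY = 0.4485,
             SCREENING = 0.019, QUALITATIVE_MISMATCH = 0.084)
  )
}

default_method_mix <- function() {
  list(
    HPA  = c(SSO = 0.5, SSP = 0.5),
    KIR  = c(SSO = 0.6, SSP = 0.4),
    LOW  = c(SSO = 0.7, SSP = 0.3),
    B57  = c(SSO = 0.55, rtPCR = 0.45),
    HI   = c(NGS = 0.8, SBT = 0.2),
    B27  = c("Mol.gen" = 0.75, FC = 0.25),
    CD   = c(SSO = 0.7, rtPCR = 0.3),
    ALO  = c("Luminex-SA" = 0.95, CDC = 0.05),
    AHPA = c(Luminex = 1),
    SER  = c(PBMC = 0.75, "T-cells" = 0.25),
    XM   = c(PBMC = 0.55, "T-cells" = 0.45),
    XMFC = c("Total-lymphocytes" = 0.6, "Separated-lymphocytes" = 0.4),
    CHM  = c(STR = 0.55, rtPCR = 0.45)
  )
}

#' Simulation configuration
#'
#' Default scale is a miniature programme (20 laboratories, 16 samples per
#' scheme-year, 3 years) so a full pipeline run takes seconds; per-scheme
#' error rates default to the published 12-year mean error rates
#' (`1 - mean rate / 100`, see [reference_scheme_means()]) and category mixes
#' default to the published per-scheme error-category proportions.
#'
#' @param schemes scheme short names (subset of [scheme_registry()]).
#' @param years simulated years.
#' @param labs laboratories per scheme-year (scalar, or named by scheme).
#' @param samples samples per scheme-year (scalar, or named by scheme).
#' @param error_rates per-result error probability, named by scheme; defaults
#'   derived from the published scheme means.
#' @param category_mix named list (by scheme) of named probability vectors
#'   over error categories, each summing to 1.
#' @param method_mix named list (by scheme) of named probability vectors over
#'   method tags.
#' @param allele_pool see [default_allele_pool()].
#' @param antibody_panel panel specificities, see [default_antibody_panel()].
#' @param n_positive_specificities true positives per antibody sample.
#' @param chimerism_range range of true percent-recipient values.
#' @param chimerism_noise_sd reporting noise of non-erroneous chimerism
#'   results (percentage points). Default 0: honest laboratories report the
#'   truth, so recovered success equals 100 * (1 - error rate) exactly in
#'   expectation.
#' @param resolution_mix named probability vector over the number of fields a
#'   laboratory reports for typing results.
#' @param lab_effect_sd sd (log scale) of a per-laboratory lognormal
#'   error-rate multiplier; 0 disables laboratory heterogeneity.
#' @param risk_map disease-risk map used for CD truth and scoring.
#' @param params an [consensus_params()] object.
#' @return a list of class `eqa_sim_config`.
#' @export
simulation_config <- function(schemes = c("HI", "LOW", "CD", "ALO", "XM", "CHM"),
                              years = 2020:2022,
                              labs = 20L,
                              samples = 16L,
                              error_rates = NULL,
                              category_mix = default_category_mix(),
                              method_mix = default_method_mix(),
                              allele_pool = default_allele_pool(),
                              antibody_panel = default_antibody_panel(),
                              n_positive_specificities = 6L,
                              chimerism_range = c(5, 60),
                              chimerism_noise_sd = 0,
                              resolution_mix = c("2" = 0.5, "3" = 0.35, "4" = 0.15),
                              lab_effect_sd = 0,
                              risk_map = cd_risk_map(),
                              params = consensus_params()) {
  registry <- scheme_registry()
  stopifnot(all(schemes %in% registry$scheme))
  if (is.null(error_rates)) {
    means <- reference_scheme_means()
    error_rates <- stats::setNames((100 - means$printed_mean) / 100,
                                   means$scheme)
  }
  stopifnot(all(schemes %in% names(error_rates)),
            all(error_rates >= 0 & error_rates <= 1),
            all(schemes %in% names(category_mix)),
            all(schemes %in% names(method_mix)),
            n_positive_specificities >= 1,
            n_positive_specificities < length(antibody_panel),
            length(chimerism_range) == 2, chimerism_range[1] >= 0,
            chimerism_range[2] <= 100, chimerism_noise_sd >= 0,
            lab_effect_sd >= 0)
  for (s in schemes) {
    mix <- category_mix[[s]]
    if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
      stop_eqa("invalid_config",
               sprintf("category mix for %s must be non-negative and sum to 1", s))
    }
    if (!all(names(mix) %in% ERROR_CATEGORIES)) {
      stop_eqa("invalid_config", sprintf("unknown category in mix for %s", s))
    }
  }
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      stats::setNames(rep(as.integer(x), length(schemes)), schemes)
    } else {
      stopifnot(all(schemes %in% names(x)))
      vapply(schemes, function(s) as.integer(x[[s]]), integer(1))
    }
  }
  structure(list(schemes = schemes, years = as.integer(years),
                 labs = expand(labs), samples = expand(samples),
                 error_rates = error_rates, category_mix = category_mix,
                 method_mix = method_mix, allele_pool = allele_pool,
                 antibody_panel = antibody_panel,
                 n_positive_specificities = as.integer(n_positive_specificities),
                 chimerism_range = chimerism_range,
                 chimerism_noise_sd = chimerism_noise_sd,
                 resolution_mix = resolution_mix,
                 lab_effect_sd = lab_effect_sd,
                 risk_map = risk_map, params = params),
            class = "eqa_sim_config")
}

#' Read a simulation configuration from JSON or YAML
#'
#' Scalar and vector fields of [simulation_config()] can be supplied from a
#' configuration file; structured defaults (allele pool, risk map, parameter
#' object) are kept unless overridden programmatically.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return an `eqa_sim_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("schemes", "years", "labs", "samples", "error_rates",
               "antibody_panel", "n_positive_specificities",
               "chimerism_range", "chimerism_noise_sd", "lab_effect_sd")
  cfg <- cfg[intersect(names(cfg), allowed)]
  if (!is.null(cfg$error_rates)) cfg$error_rates <- unlist(cfg$error_rates)
  do.call(simulation_config, cfg)
}

truncate_allele_string <- function(allele, n_fields) {
  a <- parse_allele(allele)
  if (!a$molecular || length(a$fields) <= n_fields) return(render_allele(a))
  a$fields <- a$fields[seq_len(n_fields)]
  a$suffix <- NA_character_
  render_allele(a)
}

pool_expressed <- function(pool) pool[!grepl("N$", pool$allele), , drop = FALSE]
pool_nulls <- function(pool) pool$allele[grepl("N$", pool$allele)]

#' Generate per-sample true values
#'
#' Deterministic under `seed`: each (scheme, year) draws from its own
#' substream, so adding a scheme or year never perturbs another's truths.
#' Typing truths are heterozygous pairs of distinct expressed alleles (EQA
#' panels favour informative samples); antibody truths are random positive
#' subsets of the panel; chimerism truths are uniform on `chimerism_range`,
#' reported to one decimal.
#'
#' @param config an [simulation_config()].
#' @param seed master seed.
#' @return data.frame with columns `scheme`, `year`, `sample`, `parameter`,
#'   `type`, `payload`.
#' @export
generate_truth <- function(config, seed) {
  stopifnot(inherits(config, "eqa_sim_config"))
  rows <- list()
  for (s in config$schemes) {
    kind <- scheme_kinds[[s]]
    for (y in config$years) {
      set.seed(stream_seed(seed, "truth", s, y))
      samples <- sprintf("S%02d", seq_len(config$samples[[s]]))
      for (sm in samples) {
        if (kind %in% c("typing", "typing_risk")) {
          pool <- pool_expressed(config$allele_pool[[scheme_locus[[s]]]])
          pair <- sample(pool$allele, 2L, prob = pool$freq)
          geno <- paste(pair, collapse = "+")
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = s, year = y, sample = sm, parameter = "genotype",
            type = "genotype", payload = geno, stringsAsFactors = FALSE)
          if (kind == "typing_risk") {
            rows[[length(rows) + 1L]] <- data.frame(
              scheme = s, year = y, sample = sm, parameter = "risk",
              type = "risk",
              payload = risk_lookup(config$risk_map, geno),
              stringsAsFactors = FALSE)
          }
        } else if (kind == "qualitative") {
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = s, year = y, sample = sm, parameter = "call",
            type = "qualitative",
            payload = sample(c("POSITIVE", "NEGATIVE"), 1L),
            stringsAsFactors = FALSE)
        } else if (kind == "antibody") {
          pos <- sort(sample(config$antibody_panel,
                             config$n_positive_specificities))
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = s, year = y, sample = sm,
            parameter = c("specificities", "screening", "interpretation"),
            type = c("specificities", "screening", "qualitative"),
            payload = c(paste(pos, collapse = ";"), "POSITIVE",
                        sample(c("POSITIVE", "NEGATIVE"), 1L)),
            stringsAsFactors = FALSE)
        } else if (kind == "chimerism") {
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = s, year = y, sample = sm,
            parameter = c("quantification", "detection"),
            type = c("quantitative", "qualitative"),
            payload = c(sprintf("%.1f", stats::runif(1, config$chimerism_range[1],
                                                     config$chimerism_range[2])),
                        sample(c("POSITIVE", "NEGATIVE"), 1L)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(scheme = character(), year = integer(),
                      sample = character(), parameter = character(),
                      type = character(), payload = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-result error probability for each result slot of a sample, scaled so
# that the average over the sample's results equals the configured scheme rate
# while the expected category shares equal the configured mix.
slot_rates <- function(scheme, rate, mix, panel_size) {
  kind <- scheme_kinds[[scheme]]
  mass <- function(categories) sum(mix[intersect(names(mix), categories)])
  if (kind == "typing") {
    c(genotype = rate)
  } else if (kind == "typing_risk") {
    n <- 2
    c(genotype = n * rate * mass(c("NULL_ALLELE", "HOMOZYGOSITY",
                                   "ALLELE_MISMATCH", "NOMENCLATURE")),
      risk = n * rate * mass("RISK_INTERPRETATION"))
  } else if (kind == "qualitative") {
    c(call = rate)
  } else if (kind == "chimerism") {
    n <- 2
    c(quantification = n * rate * mass("QUANTIFICATION"),
      detection = n * rate * mass("QUALITATIVE_MISMATCH"))
  } else { # antibody
    n <- panel_size + 2
    c(specificity = n * rate * mass(c("FALSE_POSITIVE_SPECIFICITY",
                                      "FALSE_NEGATIVE_SPECIFICITY")) / panel_size,
      screening = n * rate * mass("SCREENING"),
      interpretation = n * rate * mass("QUALITATIVE_MISMATCH"))
  }
}

toggle_status <- function(x) ifelse(x == "POSITIVE", "NEGATIVE", "POSITIVE")

# Corrupt a genotype according to a drawn category; returns the report string.
inject_typing_error <- function(category, truth_alleles, pool, res) {
  reported <- vapply(truth_alleles, truncate_allele_string, character(1),
                     n_fields = res)
  if (category == "HOMOZYGOSITY") {
    return(reported[[sample(2L, 1L)]])
  }
  if (category == "NULL_ALLELE") {
    nulls <- pool_nulls(pool)
    i <- sample(2L, 1L)
    reported[i] <- paste(c(reported[i], sample(nulls, 1L)), collapse = "/")
    return(paste(reported, collapse = "+"))
  }
  if (category == "ALLELE_MISMATCH") {
    candidates <- setdiff(pool_expressed(pool)$allele, truth_alleles)
    reported[sample(2L, 1L)] <-
      truncate_allele_string(sample(candidates, 1L), res)
    return(paste(reported, collapse = "+"))
  }
  stop_eqa("invalid_config",
           sprintf("category %s cannot be realized on a genotype", category))
}

#' Generate laboratory reports with injected errors
#'
#' Each result is erroneous with its scheme's per-result probability; the
#' error's category follows the configured per-scheme mix and is realized
#' concretely: an unexcluded null-allele alternative is added, a genotype copy
#' is dropped (homozygous report), a pool allele is substituted, a
#' quantification is shifted beyond the acceptance window, a specificity or
#' qualitative call is toggled, or a wrong risk label is reported.
#' Non-erroneous typing reports are truthful but may be reported at reduced
#' resolution (`resolution_mix`), which scoring does not penalize. Each
#' (scheme, year, laboratory) draws from its own substream of `seed`.
#'
#' @param truths output of [generate_truth()].
#' @param config the same [simulation_config()].
#' @param seed master seed.
#' @return data.frame with columns `lab`, `scheme`, `year`, `sample`,
#'   `parameter`, `type`, `method`, `payload`, `excluded_nulls`.
#' @export
generate_reports <- function(truths, config, seed) {
  stopifnot(inherits(config, "eqa_sim_config"))
  risk_labels <- unique(c(unname(config$risk_map$map),
                          config$risk_map$default))
  panel_size <- length(config$antibody_panel)
  blocks <- list()

  for (s in config$schemes) {
    kind <- scheme_kinds[[s]]
    mix <- config$category_mix[[s]]
    labs <- sprintf("L%02d", seq_len(config$labs[[s]]))
    geno_mix <- mix[intersect(names(mix), c("NULL_ALLELE", "HOMOZYGOSITY",
                                            "ALLELE_MISMATCH"))]
    for (y in config$years) {
      t_sy <- truths[truths$scheme == s & truths$year == y, , drop = FALSE]
      for (lab in labs) {
        set.seed(stream_seed(seed, "reports", s, y, lab))
        multiplier <- if (config$lab_effect_sd > 0) {
          stats::rlnorm(1, meanlog = -config$lab_effect_sd^2 / 2,
                        sdlog = config$lab_effect_sd)
        } else 1
        rates <- pmin(slot_rates(s, config$error_rates[[s]], mix,
                                 panel_size) * multiplier, 1)
        method <- sample(names(config$method_mix[[s]]), 1L,
                         prob = config$method_mix[[s]])
        rows <- t_sy
        rows$lab <- lab
        rows$method <- method
        rows$excluded_nulls <- ""

        for (i in seq_len(nrow(rows))) {
          type <- rows$type[i]
          truth_payload <- rows$payload[i]
          if (type == "genotype") {
            res <- as.integer(sample(names(config$resolution_mix), 1L,
                                     prob = config$resolution_mix))
            truth_alleles <- strsplit(truth_payload, "+", fixed = TRUE)[[1L]]
            pool <- config$allele_pool[[scheme_locus[[s]]]]
            if (stats::runif(1) < rates[["genotype"]]) {
              cat_i <- sample(names(geno_mix), 1L, prob = geno_mix)
              rows$payload[i] <- inject_typing_error(cat_i, truth_alleles,
                                                     pool, res)
            } else {
              rows$payload[i] <- paste(
                vapply(truth_alleles, truncate_allele_string, character(1),
                       n_fields = res), collapse = "+")
            }
          } else if (type == "risk") {
            if (stats::runif(1) < rates[["risk"]]) {
              rows$payload[i] <- sample(setdiff(risk_labels, truth_payload), 1L)
            }
          } else if (type == "quantitative") {
            value <- as.numeric(truth_payload)
            if (config$chimerism_noise_sd > 0) {
              value <- min(max(value + stats::rnorm(1, 0, config$chimerism_noise_sd), 0), 100)
            }
            if (stats::runif(1) < rates[["quantification"]]) {
              shift <- 15 + stats::runif(1, 0, 10)
              value <- if (value < 35) value + shift else value - shift
            }
            rows$payload[i] <- sprintf("%.1f", value)
          } else if (type == "specificities") {
            true_pos <- strsplit(truth_payload, ";", fixed = TRUE)[[1L]]
            true_neg <- setdiff(config$antibody_panel, true_pos)
            reported <- true_pos
            n_err <- stats::rbinom(1, panel_size, rates[["specificity"]])
            id_mix <- mix[c("FALSE_NEGATIVE_SPECIFICITY",
                            "FALSE_POSITIVE_SPECIFICITY")]
            for (k in seq_len(n_err)) {
              fn <- stats::runif(1) < id_mix[[1]] / sum(id_mix)
              if (fn && length(intersect(reported, true_pos)) > 0L) {
                drop <- sample(intersect(reported, true_pos), 1L)
                reported <- setdiff(reported, drop)
              } else if (length(setdiff(true_neg, reported)) > 0L) {
                reported <- c(reported, sample(setdiff(true_neg, reported), 1L))
              }
            }
            rows$payload[i] <- paste(sort(reported), collapse = ";")
          } else {
            slot <- switch(rows$parameter[i],
                           screening = "screening",
                           interpretation = "interpretation",
                           detection = "detection",
                           "call")
            r <- if (slot %in% names(rates)) rates[[slot]] else rates[[1L]]
            if (stats::runif(1) < r) {
              rows$payload[i] <- toggle_status(truth_payload)
            }
          }
        }
        blocks[[length(blocks) + 1L]] <- rows
      }
    }
  }
  if (length(blocks) == 0L) {
    return(data.frame(lab = character(), scheme = character(),
                      year = integer(), sample = character(),
                      parameter = character(), type = character(),
                      method = character(), payload = character(),
                      excluded_nulls = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, blocks)
  out <- out[, c("lab", "scheme", "year", "sample", "parameter", "type",
                 "method", "payload", "excluded_nulls"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- file round trip --------------------------------------------------------

report_columns <- c("lab", "scheme", "year", "sample", "parameter", "type",
                    "method", "payload", "excluded_nulls")
truth_columns <- c("scheme", "year", "sample", "parameter", "type", "payload")

#' Write/read laboratory report and truth tables
#'
#' Plain CSV with a stable schema and all payloads as strings, so
#' write-read-rewrite is byte-identical.
#'
#' @param x data.frame of reports (or truths).
#' @param path file path.
#' @return `read_*` return data.frames; `write_*` return `path` invisibly.
#' @export
write_reports <- function(x, path) {
  stopifnot(all(report_columns %in% names(x)))
  utils::write.csv(x[, report_columns, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  classes <- stats::setNames(rep("character", length(report_columns)),
                             report_columns)
  classes[["year"]] <- "integer"
  utils::read.csv(path, colClasses = classes, na.strings = character(),
                  stringsAsFactors = FALSE)
}

#' @rdname write_reports
#' @export
write_truth <- function(x, path) {
  stopifnot(all(truth_columns %in% names(x)))
  utils::write.csv(x[, truth_columns, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_truth <- function(path) {
  classes <- stats::setNames(rep("character", length(truth_columns)),
                             truth_columns)
  classes[["year"]] <- "integer"
  utils::read.csv(path, colClasses = classes, na.strings = character(),
                  stringsAsFactors = FALSE)
}

#' Write/read an antibody panel definition
#'
#' @param panel character vector of specificities.
#' @param path file path (JSON).
#' @return `read_panel` returns the character vector; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(list(specificities = panel), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE)$specificities)
}
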