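# Assigned-value determination: organizer reference or participant consensus
# for qualitative results, and the ISO 13528 Annex C robust location/scale
# estimator (Algorithm A) for quantitative chimerism.

#' Consensus and scoring parameters
#'
#' Bundle of the tunable thresholds used throughout assigned-value
#' determination and scoring.
#'
#' @param pos_threshold fraction of laboratories that must report a
#'   specificity (or a qualitative status, or a typing consensus class) for a
#'   positive consensus; default 0.75 ("at least 75%"), comparisons inclusive.
#' @param neg_threshold fraction of laboratories that must omit a specificity
#'   for a negative consensus; default 0.95. Omission fractions between
#'   `pos_threshold` and `neg_threshold` are non-assessable negatives and are
#'   not penalized.
#' @param typing_threshold consensus fraction for typing without an organizer
#'   reference; defaults to the same 75% rule.
#' @param winsor_factor winsorization half-width in robust-scale units (1.5).
#' @param mad_scale consistency constant for the initial median-absolute-
#'   deviation scale (1.483).
#' @param winsor_sd_scale consistency constant for the winsorized standard
#'   deviation (1.134).
#' @param tol,max_iter Algorithm A convergence tolerance (relative to the
#'   current scale, floored at `tol` itself) and iteration cap.
#' @param min_n minimum number of participant values for a quantitative or
#'   typing consensus; fewer values mark the parameter not evaluable.
#' @param z_limit acceptability limit for quantitative results in robust-scale
#'   units (|z| <= 2 is acceptable by default).
#' @param abs_tol absolute acceptability window (percentage points) used when
#'   the robust scale degenerates to zero.
#' @param max_error_samples maximum number of samples with at least one error
#'   a laboratory may have in a scheme-year and still pass (default 1).
#' @return a list of class `eqa_params`.
#' @export
consensus_params <- function(pos_threshold = 0.75,
                             neg_threshold = 0.95,
                             typing_threshold = 0.75,
                             winsor_factor = 1.5,
                             mad_scale = 1.483,
                             winsor_sd_scale = 1.134,
                             tol = 1e-6,
                             max_iter = 100L,
                             min_n = 3L,
                             z_limit = 2,
                             abs_tol = 5,
                             max_error_samples = 1L) {
  stopifnot(pos_threshold > 0.5, pos_threshold <= neg_threshold,
            neg_threshold <= 1,
            typing_threshold > 0.5, typing_threshold <= 1,
            winsor_factor > 0, mad_scale > 0, winsor_sd_scale > 0,
            tol > 0, max_iter >= 1, min_n >= 1, z_limit > 0, abs_tol >= 0,
            max_error_samples >= 0)
  structure(list(pos_threshold = pos_threshold, neg_threshold = neg_threshold,
                 typing_threshold = typing_threshold,
                 winsor_factor = winsor_factor, mad_scale = mad_scale,
                 winsor_sd_scale = winsor_sd_scale, tol = tol,
                 max_iter = as.integer(max_iter), min_n = as.integer(min_n),
                 z_limit = z_limit, abs_tol = abs_tol,
                 max_error_samples = as.integer(max_error_samples)),
            class = "eqa_params")
}

#' Robust location and scale (ISO 13528 Annex C, Algorithm A)
#'
#' Iterative winsorized estimator of location `x*` and scale `s*`:
#' initialization `x* = median(x)`, `s* = 1.483 * median(|x - x*|)`; each
#' iteration clips the data to `x* +/- 1.5 s*`, then sets `x*` to the mean and
#' `s*` to `1.134 *` the standard deviation of the clipped data, until both
#' updates move less than `tol * max(s*, tol)`. A zero scale (at
#' initialization or during iteration) stops immediately: the estimator is
#' undefined on a degenerate spread and downstream scoring falls back to an
#' absolute tolerance.
#'
#' @param values numeric vector (at least one finite value).
#' @param params an [consensus_params()] object.
#' @return an object of class `eqa_robust`: list with `x_star`, `s_star`, `n`,
#'   `iterations`, `converged`.
#' @examples
#' robust_location_scale(c(10, 10.2, 9.9, 10.1, 30))
#' @export
robust_location_scale <- function(values, params = consensus_params()) {
  x <- as.numeric(values)
  if (length(x) < 1L || anyNA(x) || any(!is.finite(x))) {
    stop_eqa("insufficient_data",
             "robust_location_scale needs at least one finite value")
  }
  x_star <- stats::median(x)
  s_star <- params$mad_scale * stats::median(abs(x - x_star))
  iterations <- 0L
  converged <- s_star <= 0
  if (converged) s_star <- 0

  while (!converged && iterations < params$max_iter) {
    iterations <- iterations + 1L
    delta <- params$winsor_factor * s_star
    w <- pmin(pmax(x, x_star - delta), x_star + delta)
    new_x <- mean(w)
    new_s <- params$winsor_sd_scale * stats::sd(w)
    eps <- params$tol * max(new_s, params$tol)
    if (abs(new_x - x_star) < eps && abs(new_s - s_star) < eps) {
      converged <- TRUE
    }
    x_star <- new_x
    s_star <- new_s
    if (s_star <= 0) {
      s_star <- 0
      converged <- TRUE
    }
  }

  structure(list(x_star = x_star, s_star = s_star, n = length(x),
                 iterations = iterations, converged = converged),
            class = "eqa_robust")
}

#' @export
print.eqa_robust <- function(x, ...) {
  cat(sprintf("<robust> x* = %.4g, s* = %.4g (n = %d, %d iterations%s)\n",
              x$x_star, x$s_star, x$n, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

# ---- assigned values -------------------------------------------------------

#' Assigned value container
#'
#' One assigned (true) value for a sample-by-parameter cell: an organizer
#' reference, a participant consensus with its supporting fraction, or a
#' not-evaluable marker (which carries no payload).
#'
#' @param mode one of `"REFERENCE"`, `"CONSENSUS"`, `"NOT_EVALUABLE"`.
#' @param payload the assigned genotype, qualitative status, per-specificity
#'   status map, or `eqa_robust` statistics; must be `NULL` for
#'   `NOT_EVALUABLE`.
#' @param support supporting fraction for a consensus value.
#' @param n number of contributing laboratories.
#' @return an object of class `eqa_assigned`.
#' @export
assigned_value <- function(mode, payload = NULL, support = NA_real_,
                           n = NA_integer_) {
  mode <- match.arg(mode, c("REFERENCE", "CONSENSUS", "NOT_EVALUABLE"))
  if (mode == "NOT_EVALUABLE" && !is.null(payload)) {
    stop_eqa("invalid_assigned", "NOT_EVALUABLE carries no payload")
  }
  structure(list(mode = mode, payload = payload, support = support,
                 n = as.integer(n)),
            class = "eqa_assigned")
}

#' @export
print.eqa_assigned <- function(x, ...) {
  cat("<assigned> ", x$mode,
      if (!is.na(x$support)) sprintf(" (support %.2f, n = %d)", x$support, x$n),
      "\n", sep = "")
  invisible(x)
}

#' Antibody specificity consensus (75%/95% rules)
#'
#' For each specificity, let `p` be the fraction of laboratories reporting it
#' positive and `q = 1 - p` the omission fraction. The consensus status is
#' POSITIVE when `p >= pos_threshold` (default 0.75), NEGATIVE when
#' `q >= neg_threshold` (default 0.95), NON_ASSESSABLE when
#' `pos_threshold <= q < neg_threshold` (negative by omission of 75-95% of
#' laboratories: not penalized in scoring), and NO_CONSENSUS otherwise. The
#' four statuses partition the positive-fraction interval. Laboratories that
#' reported a specificity as inconclusive should be removed from that
#' specificity's denominator before calling this.
#'
#' @param n_positive integer vector (optionally named by specificity) of
#'   laboratories reporting each specificity positive.
#' @param n_total matching vector of laboratories that returned the panel for
#'   each specificity.
#' @param params an [consensus_params()] object.
#' @return character vector of statuses, named like `n_positive`.
#' @examples
#' antibody_consensus(c(A2 = 8, B7 = 1), c(A2 = 10, B7 = 10))
#' @export
antibody_consensus <- function(n_positive, n_total,
                               params = consensus_params()) {
  if (length(n_total) == 1L) n_total <- rep(n_total, length(n_positive))
  stopifnot(length(n_positive) == length(n_total))
  if (length(n_positive) == 0L || any(n_total < 1)) {
    stop_eqa("empty_panel", "each specificity needs at least one reporting lab")
  }
  if (any(n_positive < 0 | n_positive > n_total)) {
    stop_eqa("empty_panel", "n_positive must lie in [0, n_total]")
  }
  p <- n_positive / n_total
  q <- (n_total - n_positive) / n_total
  status <- ifelse(p >= params$pos_threshold, "POSITIVE",
            ifelse(q >= params$neg_threshold, "NEGATIVE",
            ifelse(q >= params$pos_threshold, "NON_ASSESSABLE",
                   "NO_CONSENSUS")))
  names(status) <- names(n_positive)
  status
}

#' Assigned value for a typed parameter
#'
#' When the organizer reference is available it is the assigned value
#' regardless of participant reports (for DNA-based typing the organizer's
#' results are considered correct). Without a reference, participant reports
#' are grouped into concordance-equivalence classes (mutually concordant at
#' their shared resolution, see [genotypes_equivalent()]); if the modal class
#' reaches `typing_threshold` its highest-resolution member is the consensus,
#' otherwise the parameter is not evaluable.
#'
#' @param reports list of `eqa_genotype` reports.
#' @param reference optional organizer `eqa_genotype`.
#' @param params an [consensus_params()] object.
#' @return an [assigned_value()].
#' @export
typing_assigned_value <- function(reports, reference = NULL,
                                  params = consensus_params()) {
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "eqa_genotype"))
    return(assigned_value("REFERENCE", reference,
                          n = length(reports)))
  }
  if (length(reports) == 0L) {
    stop_eqa("no_data", "no reports and no reference")
  }
  n <- length(reports)
  class_of <- integer(n)
  representatives <- list()
  for (i in seq_len(n)) {
    g <- reports[[i]]
    assigned <- 0L
    for (k in seq_along(representatives)) {
      if (genotypes_equivalent(g, representatives[[k]])) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      representatives[[length(representatives) + 1L]] <- g
      assigned <- length(representatives)
    }
    class_of[i] <- assigned
  }
  counts <- tabulate(class_of, nbins = length(representatives))
  modal <- which.max(counts)
  support <- counts[modal] / n
  if (support < params$typing_threshold) {
    return(assigned_value("NOT_EVALUABLE", n = n))
  }
  members <- reports[class_of == modal]
  res <- vapply(members, genotype_resolution, integer(1))
  assigned_value("CONSENSUS", members[[which.max(res)]],
                 support = support, n = n)
}

#' Qualitative consensus (crossmatch, B27/B57 status, screening)
#'
#' Majority status among the reporting laboratories, accepted as consensus
#' when its fraction reaches `pos_threshold`; otherwise not evaluable.
#'
#' @param calls character vector of `"POSITIVE"`/`"NEGATIVE"` calls.
#' @param params an [consensus_params()] object.
#' @return an [assigned_value()] whose payload is the consensus status.
#' @export
qualitative_consensus <- function(calls, params = consensus_params()) {
  if (length(calls) == 0L) stop_eqa("no_data", "no qualitative calls")
  stopifnot(all(calls %in% c("POSITIVE", "NEGATIVE")))
  tab <- table(calls)
  top <- names(tab)[which.max(tab)]
  support <- max(tab) / length(calls)
  if (support >= params$pos_threshold) {
    assigned_value("CONSENSUS", top, support = support, n = length(calls))
  } else {
    assigned_value("NOT_EVALUABLE", n = length(calls))
  }
}

#' Assigned value for quantitative chimerism
#'
#' Wraps [robust_location_scale()] over the participant percentages; with
#' fewer than `min_n` values the parameter is not evaluable.
#'
#' @param values numeric vector of percent-recipient values in \[0, 100\].
#' @param params an [consensus_params()] object.
#' @return an [assigned_value()] whose payload is an `eqa_robust`.
#' @export
chimerism_assigned <- function(values, params = consensus_params()) {
  v <- as.numeric(values)
  if (anyNA(v) || any(v < 0 | v > 100)) {
    stop_eqa("out_of_range", "chimerism values must lie in [0, 100]")
  }
  if (length(v) < params$min_n) {
    return(assigned_value("NOT_EVALUABLE", n = length(v)))
  }
  rs <- robust_location_scale(v, params)
  assigned_value("CONSENSUS", rs, n = length(v))
}
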