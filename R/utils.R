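# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., immunoEQA_malformed_allele = ...).
stop_eqa <- function(class, msg) {
  stop(errorCondition(msg,
                      class = c(paste0("immunoEQA_", class), "immunoEQA_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Presentation rounding used for all reported percentages: exact halves round
#' away from zero (99.25 -> 99.3), unlike [base::round()]'s round-half-even.
#' Internal arithmetic is never rounded; this is applied at the reporting edge
#' only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic substream seed from a master seed and a character key, so each
# (scheme, year, lab) draws from its own stream and adding a scheme never
# perturbs another scheme's draws. Plain polynomial rolling hash mod a prime
# below 2^31.
stream_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "\r")
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}
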