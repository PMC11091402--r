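# Parsing, normalization and comparison of immunogenetics typing strings:
# WHO-style colon-delimited allele names (HLA, KIR, HPA), a GL-string subset
# for genotypes ("+" separates the two gene copies, "/" separates ambiguity
# alternatives), and the concordance rules used for scoring.

EXPRESSION_SUFFIXES <- c("N", "L", "S", "C", "A", "Q")

normalize_locus <- function(locus) {
  locus <- toupper(locus)
  if (grepl("^(KIR|HPA)", locus)) locus else paste0("HLA-", sub("^HLA-", "", locus))
}

#' Parse an allele string
#'
#' Accepts molecular designations (`"A*24:02"`, `"HLA-DQB1*03:38N"`,
#' `"KIR2DL1*001"`) with 1-4 colon-separated numeric fields and an optional
#' expression suffix (N, L, S, C, A, Q), and serological antigen designations
#' without a `*` separator (`"A2"`, `"HLA-B27"`). Loci without a known prefix
#' are normalized to `HLA-`.
#'
#' @param text a single allele string.
#' @return an object of class `eqa_allele` with elements `locus`, `fields`
#'   (character vector, leading zeros preserved), `suffix` (`NA` or one of
#'   N/L/S/C/A/Q), `molecular` (logical) and `raw`.
#' @seealso [render_allele()], [concordant_allele()]
#' @examples
#' parse_allele("A*01:04N")
#' parse_allele("B27")
#' @export
parse_allele <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop_eqa("malformed_allele", "allele string is empty")
  }
  raw <- text
  s <- toupper(trimws(text))

  if (grepl("*", s, fixed = TRUE)) {
    parts <- strsplit(s, "*", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L])) {
      stop_eqa("malformed_allele",
               sprintf("malformed locus separator in '%s'", raw))
    }
    locus <- normalize_locus(parts[1L])
    body <- parts[2L]
    suffix <- NA_character_
    last <- substr(body, nchar(body), nchar(body))
    if (grepl("[A-Z]", last)) {
      if (!last %in% EXPRESSION_SUFFIXES) {
        stop_eqa("malformed_allele",
                 sprintf("unknown expression suffix '%s' in '%s'", last, raw))
      }
      suffix <- last
      body <- substr(body, 1L, nchar(body) - 1L)
    }
    fields <- strsplit(body, ":", fixed = TRUE)[[1L]]
    if (length(fields) < 1L || length(fields) > 4L ||
        !all(grepl("^[0-9]+$", fields))) {
      stop_eqa("malformed_allele",
               sprintf("empty or non-numeric field token in '%s'", raw))
    }
    molecular <- TRUE
  } else {
    # Serological antigen: letters then digits, one field, no suffix.
    s2 <- sub("^HLA-", "", s)
    if (!grepl("^[A-Z]+[0-9]+$", s2)) {
      stop_eqa("malformed_allele",
               sprintf("missing locus separator in '%s'", raw))
    }
    locus <- paste0("HLA-", sub("^([A-Z]+).*$", "\\1", s2))
    fields <- sub("^[A-Z]+", "", s2)
    suffix <- NA_character_
    molecular <- FALSE
  }

  structure(list(locus = locus, fields = fields, suffix = suffix,
                 molecular = molecular, raw = raw),
            class = "eqa_allele")
}

#' Render an allele in canonical form
#'
#' Canonical form is uppercase with numeric fields zero-padded to at least two
#' digits for molecular designations; serological antigens keep their reported
#' field width. `render_allele(parse_allele(x))` is a fixed point.
#'
#' @param allele an `eqa_allele`.
#' @return a single string.
#' @export
render_allele <- function(allele) {
  stopifnot(inherits(allele, "eqa_allele"))
  if (!allele$molecular) {
    return(paste0(allele$locus, allele$fields[1L]))
  }
  f <- allele$fields
  pad <- ifelse(nchar(f) < 2L, paste0(strrep("0", pmax(2L - nchar(f), 0L)), f), f)
  paste0(allele$locus, "*", paste(pad, collapse = ":"),
         ifelse(is.na(allele$suffix), "", allele$suffix))
}

#' Is an allele a null (non-expressed) allele?
#'
#' @param allele an `eqa_allele`.
#' @return `TRUE`/`FALSE`.
#' @export
is_null_allele <- function(allele) {
  stopifnot(inherits(allele, "eqa_allele"))
  identical(allele$suffix, "N")
}

#' @export
print.eqa_allele <- function(x, ...) {
  cat("<allele> ", render_allele(x), "\n", sep = "")
  invisible(x)
}

# Do two expression suffixes conflict? A null allele never matches an
# expressed one even when the numeric fields agree; two different declared
# suffixes conflict; an undeclared suffix is compatible with any expressed
# annotation.
suffixes_conflict <- function(a, b) {
  if (xor(identical(a, "N"), identical(b, "N"))) return(TRUE)
  if (!is.na(a) && !is.na(b) && a != b) return(TRUE)
  FALSE
}

#' Allele concordance at the reported resolution
#'
#' A reported allele is concordant with the assigned (true) allele when its
#' fields are a numeric prefix of the truth's fields -- i.e. the comparison is
#' made at the resolution the laboratory reported, and reaching allelic
#' resolution is not required -- and the expression suffixes do not conflict
#' (expressed vs null is always a conflict).
#'
#' @param reported,truth `eqa_allele` objects on the same locus.
#' @return `TRUE`/`FALSE`.
#' @export
concordant_allele <- function(reported, truth) {
  stopifnot(inherits(reported, "eqa_allele"), inherits(truth, "eqa_allele"))
  if (reported$locus != truth$locus) {
    stop_eqa("locus_mismatch",
             sprintf("locus mismatch: %s vs %s", reported$locus, truth$locus))
  }
  if (reported$molecular != truth$molecular) return(FALSE)
  nr <- length(reported$fields)
  if (nr > length(truth$fields)) return(FALSE)
  if (!all(as.integer(reported$fields) == as.integer(truth$fields[seq_len(nr)]))) {
    return(FALSE)
  }
  !suffixes_conflict(reported$suffix, truth$suffix)
}

# ---- genotypes -------------------------------------------------------------

new_ambiguous_call <- function(alternatives, excluded_nulls = character()) {
  structure(list(alternatives = alternatives, excluded_nulls = excluded_nulls),
            class = "eqa_call")
}

allele_sort_key <- function(alleles) {
  vapply(alleles, function(a) {
    f <- formatC(as.integer(a$fields), width = 6L, flag = "0")
    paste0(paste(f, collapse = ":"), "|", ifelse(is.na(a$suffix), "", a$suffix))
  }, character(1))
}

render_call <- function(call) {
  r <- vapply(call$alternatives, render_allele, character(1))
  paste(r[order(allele_sort_key(call$alternatives))], collapse = "/")
}

#' Parse a genotype string (GL-string subset)
#'
#' `"+"` separates the two gene copies and `"/"` separates ambiguity
#' alternatives within a copy, e.g. `"A*02:01/A*02:09+A*03:01"`. A single
#' call marks reported homozygosity; writing the same allele twice sets the
#' `reported_doubled` flag. Full GL-string operators (`|`, `^`) are rejected.
#' Null alleles explicitly excluded by the reporting laboratory are supplied
#' through `excluded_nulls` (generic "every null excluded" annotations are not
#' representable by design: each excluded allele must be listed).
#'
#' @param text genotype string.
#' @param excluded_nulls character vector of allele strings the laboratory
#'   explicitly excluded; each must parse to a null allele.
#' @return an object of class `eqa_genotype` with elements `locus`, `calls`
#'   (list of 1-2 ambiguous calls), `reported_doubled` and `raw`.
#' @examples
#' parse_genotype("A*02:01/A*02:09+A*03:01")
#' parse_genotype("DQB1*03:01/DQB1*03:38N+DQB1*02:01",
#'                excluded_nulls = "DQB1*03:38N")
#' @export
parse_genotype <- function(text, excluded_nulls = character()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop_eqa("malformed_genotype", "genotype string is empty")
  }
  if (grepl("[|^]", text)) {
    stop_eqa("malformed_genotype",
             "full GL-string operators '|' and '^' are not supported")
  }
  parts <- strsplit(trimws(text), "+", fixed = TRUE)[[1L]]
  if (length(parts) < 1L || length(parts) > 2L || !all(nzchar(trimws(parts)))) {
    stop_eqa("malformed_genotype",
             sprintf("expected 1 or 2 '+'-separated copies in '%s'", text))
  }

  excl <- lapply(excluded_nulls, parse_allele)
  bad <- !vapply(excl, is_null_allele, logical(1))
  if (any(bad)) {
    stop_eqa("malformed_genotype",
             "excluded_nulls may only contain null (suffix N) alleles")
  }
  excl_rendered <- vapply(excl, render_allele, character(1))

  calls <- lapply(parts, function(p) {
    alts <- lapply(strsplit(trimws(p), "/", fixed = TRUE)[[1L]],
                   function(a) parse_allele(trimws(a)))
    new_ambiguous_call(alts, excl_rendered)
  })

  loci <- unique(unlist(lapply(calls, function(cl) {
    vapply(cl$alternatives, function(a) a$locus, character(1))
  })))
  if (length(loci) != 1L) {
    stop_eqa("malformed_genotype",
             sprintf("mixed loci in genotype '%s': %s",
                     text, paste(loci, collapse = ", ")))
  }

  reported_doubled <- length(calls) == 2L &&
    identical(render_call(calls[[1L]]), render_call(calls[[2L]]))

  structure(list(locus = loci, calls = calls,
                 reported_doubled = reported_doubled, raw = text),
            class = "eqa_genotype")
}

#' Render a genotype in canonical form
#'
#' Alternatives within a call and the two calls themselves are sorted
#' canonically, so rendering is independent of reporting order and
#' `render_genotype(parse_genotype(x))` is a fixed point.
#'
#' @param genotype an `eqa_genotype`.
#' @return a single string.
#' @export
render_genotype <- function(genotype) {
  stopifnot(inherits(genotype, "eqa_genotype"))
  r <- vapply(genotype$calls, render_call, character(1))
  paste(sort(r), collapse = "+")
}

#' @export
print.eqa_genotype <- function(x, ...) {
  cat("<genotype> ", render_genotype(x), "\n", sep = "")
  invisible(x)
}

#' Does an ambiguous call contain an unresolved null allele?
#'
#' TRUE when some alternative is a null allele that the laboratory did not
#' explicitly list as excluded. Ambiguities encompassing a null allele must be
#' resolved or the null explicitly excluded; leaving one unexcluded is the
#' dominant error source in high-resolution typing.
#'
#' @param call one element of `genotype$calls`.
#' @return `TRUE`/`FALSE`.
#' @export
unexcluded_null <- function(call) {
  stopifnot(inherits(call, "eqa_call"))
  any(vapply(call$alternatives, function(a) {
    is_null_allele(a) && !(render_allele(a) %in% call$excluded_nulls)
  }, logical(1)))
}

# Does some alternative of the reported call match some alternative of the
# truth call at the reported resolution?
call_matches <- function(reported_call, truth_call) {
  for (ra in reported_call$alternatives) {
    for (ta in truth_call$alternatives) {
      if (concordant_allele(ra, ta)) return(TRUE)
    }
  }
  FALSE
}

genotype_copies <- function(genotype) {
  if (length(genotype$calls) == 1L) genotype$calls[c(1L, 1L)] else genotype$calls
}

#' Genotype concordance
#'
#' A reported genotype is concordant with the assigned genotype when there is
#' a perfect matching between the two assigned copies and the reported calls
#' such that each assigned copy is concordant (at the reported resolution)
#' with at least one alternative of its matched call. A single reported call
#' is a homozygosity claim: it is replicated over both assigned copies, so it
#' only matches a truth that is homozygous at the reported resolution.
#'
#' @param reported,truth `eqa_genotype` objects on the same locus.
#' @return `TRUE`/`FALSE`.
#' @export
genotype_concordant <- function(reported, truth) {
  stopifnot(inherits(reported, "eqa_genotype"), inherits(truth, "eqa_genotype"))
  if (reported$locus != truth$locus) {
    stop_eqa("locus_mismatch",
             sprintf("locus mismatch: %s vs %s", reported$locus, truth$locus))
  }
  r <- genotype_copies(reported)
  t <- genotype_copies(truth)
  (call_matches(r[[1L]], t[[1L]]) && call_matches(r[[2L]], t[[2L]])) ||
    (call_matches(r[[1L]], t[[2L]]) && call_matches(r[[2L]], t[[1L]]))
}

#' Are two genotypes concordant at their shared resolution?
#'
#' Symmetric relation used to group participant reports into
#' concordance-equivalence classes: true when either genotype is concordant
#' with the other, i.e. one is a refinement of the other at the resolution
#' both share.
#'
#' @param g1,g2 `eqa_genotype` objects.
#' @return `TRUE`/`FALSE`.
#' @export
genotypes_equivalent <- function(g1, g2) {
  if (g1$locus != g2$locus) return(FALSE)
  genotype_concordant(g1, g2) || genotype_concordant(g2, g1)
}

# Total reported field count, used to pick the highest-resolution
# representative of a consensus class.
genotype_resolution <- function(genotype) {
  sum(vapply(genotype$calls, function(cl) {
    max(vapply(cl$alternatives, function(a) length(a$fields), integer(1)))
  }, integer(1)))
}
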