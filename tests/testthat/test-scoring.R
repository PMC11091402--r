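ref_av <- function(s) typing_assigned_value(list(), parse_genotype(s))

test_that("typing evaluation follows the documented decision order", {
  # unexcluded null alternative against an expressed assigned genotype
  ev <- evaluate_typing("DQB1*03:01/DQB1*03:38N+DQB1*02:01",
                        ref_av("DQB1*03:01+DQB1*02:01"))
  expect_identical(ev$status, "ERROR")
  expect_identical(ev$category, "NULL_ALLELE")

  # explicit exclusion resolves the ambiguity
  ev2 <- evaluate_typing("DQB1*03:01/DQB1*03:38N+DQB1*02:01",
                         ref_av("DQB1*03:01+DQB1*02:01"),
                         excluded_nulls = "DQB1*03:38N")
  expect_identical(ev2$status, "CORRECT")

  # concordance at reported resolution is not penalized
  expect_identical(
    evaluate_typing("A*24:02+A*03:01",
                    ref_av("A*24:02:01:01+A*03:01:01"))$status,
    "CORRECT")

  # doubled allele against a heterozygous truth
  ev3 <- evaluate_typing("A*02:01+A*02:01", ref_av("A*02:01+A*68:01"))
  expect_identical(ev3$category, "HOMOZYGOSITY")
  # single-call report behaves the same
  ev4 <- evaluate_typing("A*02:01", ref_av("A*02:01+A*68:01"))
  expect_identical(ev4$category, "HOMOZYGOSITY")

  expect_identical(
    evaluate_typing("A*24:02+A*01:01", ref_av("A*02:01+A*68:01"))$category,
    "ALLELE_MISMATCH")

  # unparseable payloads and wrong loci are nomenclature errors
  expect_identical(
    evaluate_typing("A*xx:01+A*02:01", ref_av("A*02:01+A*68:01"))$category,
    "NOMENCLATURE")
  expect_identical(
    evaluate_typing("B*57:01+B*08:01", ref_av("A*02:01+A*68:01"))$category,
    "NOMENCLATURE")

  expect_identical(
    evaluate_typing("A*02:01+A*68:01", assigned_value("NOT_EVALUABLE"))$status,
    "NOT_EVALUABLE")
})

test_that("reporting a null allele is correct when the truth is null", {
  av <- ref_av("A*01:04N+A*02:01")
  ev <- evaluate_typing("A*01:04N/A*01:01+A*02:01", av)
  expect_identical(ev$status, "CORRECT")
})

test_that("typing evaluation is invariant to alternative ordering", {
  av <- ref_av("DQB1*03:01+DQB1*02:01")
  e1 <- evaluate_typing("DQB1*03:01/DQB1*03:38N+DQB1*02:01", av)
  e2 <- evaluate_typing("DQB1*03:38N/DQB1*03:01+DQB1*02:01", av)
  expect_identical(e1$category, e2$category)
  e3 <- evaluate_typing("DQB1*02:01+DQB1*03:01/DQB1*03:38N", av)
  expect_identical(e1$category, e3$category)
})

test_that("self-evaluation of a generated corpus is always CORRECT", {
  pool <- default_allele_pool()
  set.seed(31)
  for (i in 1:50) {
    locus <- sample(names(pool), 1)
    alleles <- pool[[locus]]$allele[!grepl("N$", pool[[locus]]$allele)]
    g <- paste(sample(alleles, 2), collapse = "+")
    expect_identical(evaluate_typing(g, ref_av(g))$status, "CORRECT", info = g)
  }
})

test_that("antibody specificity scoring follows consensus statuses", {
  assigned <- c(A2 = "POSITIVE", B7 = "NEGATIVE", DR4 = "NON_ASSESSABLE",
                DQ2 = "NO_CONSENSUS")
  ev <- evaluate_antibody(c("B7"), assigned)
  expect_identical(ev$status[ev$specificity == "A2"], "ERROR")
  expect_identical(ev$category[ev$specificity == "A2"],
                   "FALSE_NEGATIVE_SPECIFICITY")
  expect_identical(ev$category[ev$specificity == "B7"],
                   "FALSE_POSITIVE_SPECIFICITY")
  expect_identical(ev$status[ev$specificity == "DR4"], "NOT_EVALUABLE")
  expect_identical(ev$status[ev$specificity == "DQ2"], "NOT_EVALUABLE")

  ev2 <- evaluate_antibody(c("A2"), assigned)
  expect_identical(ev2$status[ev2$specificity == "A2"], "CORRECT")
  expect_identical(ev2$status[ev2$specificity == "B7"], "CORRECT")

  expect_error(evaluate_antibody("Cw6", assigned),
               class = "immunoEQA_unknown_specificity")
})

test_that("chimerism scoring uses |z| <= 2 and the absolute fallback", {
  rs <- structure(list(x_star = 12.1, s_star = 0.3, n = 10, iterations = 2,
                       converged = TRUE), class = "eqa_robust")
  expect_identical(evaluate_chimerism(12.3, rs)$status, "CORRECT")
  expect_identical(evaluate_chimerism(12.1, rs)$status, "CORRECT")
  ev <- evaluate_chimerism(30.0, rs)
  expect_identical(ev$category, "QUANTIFICATION")
  # exact boundary is acceptable
  expect_identical(evaluate_chimerism(12.1 + 2 * 0.3, rs)$status, "CORRECT")

  rs0 <- structure(list(x_star = 10, s_star = 0, n = 5, iterations = 0,
                        converged = TRUE), class = "eqa_robust")
  expect_identical(evaluate_chimerism(14.9, rs0)$status, "CORRECT")
  expect_identical(evaluate_chimerism(15.1, rs0)$category, "QUANTIFICATION")

  expect_error(evaluate_chimerism(120, rs), class = "immunoEQA_out_of_range")
})

test_that("chimerism scoring is monotone in the deviation", {
  rs <- robust_location_scale(c(11, 12, 12.5, 12, 13, 11.5))
  devs <- seq(0, 40, by = 0.25)
  status <- vapply(devs, function(d) {
    evaluate_chimerism(min(rs$x_star + d, 100), rs)$status
  }, character(1))
  # once an ERROR appears it never reverts to CORRECT
  first_err <- match("ERROR", status)
  expect_false(is.na(first_err))
  expect_true(all(status[first_err:length(status)] == "ERROR"))
})

test_that("qualitative scoring matches against the matching consensus only", {
  pos <- qualitative_consensus(rep("POSITIVE", 10))
  neg <- qualitative_consensus(rep("NEGATIVE", 10))
  expect_identical(evaluate_qualitative("POSITIVE", pos)$status, "CORRECT")
  # whole-blood crossmatch reported positive because a lymphocyte fraction
  # was positive, while the whole-blood consensus is negative
  ev <- evaluate_qualitative("POSITIVE", neg)
  expect_identical(ev$category, "QUALITATIVE_MISMATCH")
  expect_identical(
    evaluate_qualitative("NEGATIVE", assigned_value("NOT_EVALUABLE"))$status,
    "NOT_EVALUABLE")
  expect_identical(
    evaluate_qualitative("POSITIVE", neg, "SCREENING")$category, "SCREENING")
})

test_that("risk interpretation is scored on top of the genotype", {
  map <- cd_risk_map()
  av <- ref_av("DQB1*02:01+DQB1*03:02")
  both <- evaluate_risk("DQB1*02:01+DQB1*03:02", "HIGH", av, map)
  expect_identical(both$typing$status, "CORRECT")
  expect_identical(both$risk$status, "CORRECT")

  wrong_risk <- evaluate_risk("DQB1*02:01+DQB1*03:02", "LOW", av, map)
  expect_identical(wrong_risk$typing$status, "CORRECT")
  expect_identical(wrong_risk$risk$category, "RISK_INTERPRETATION")

  # unmapped genotype without a default: risk component is not evaluable
  strict <- risk_map(c("DQB1*02:01+DQB1*02:01" = "HIGH"))
  ev <- evaluate_risk("DQB1*03:01+DQB1*05:01", "HIGH",
                      ref_av("DQB1*03:01+DQB1*05:01"), strict)
  expect_identical(ev$risk$status, "NOT_EVALUABLE")
})

test_that("scheme pass rule counts errored samples", {
  evals <- data.frame(sample = rep(sprintf("S%02d", 1:16), each = 2),
                      status = "CORRECT", stringsAsFactors = FALSE)
  expect_identical(scheme_pass(evals), "PASS")

  evals$status[c(1, 5)] <- "ERROR"   # two distinct errored samples
  expect_identical(scheme_pass(evals), "FAIL")

  evals$status[5] <- "CORRECT"       # one errored sample
  expect_identical(scheme_pass(evals), "PASS")

  ne <- data.frame(sample = "S01", status = "NOT_EVALUABLE")
  expect_error(scheme_pass(ne), class = "immunoEQA_no_valid_results")
})
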