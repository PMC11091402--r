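test_that("generation is deterministic under the master seed", {
  cfg <- simulation_config(schemes = c("HI", "CHM", "ALO"), years = 2022L,
                           labs = 5L, samples = 4L)
  t1 <- generate_truth(cfg, 42L)
  t2 <- generate_truth(cfg, 42L)
  expect_identical(t1, t2)
  r1 <- generate_reports(t1, cfg, 42L)
  r2 <- generate_reports(t2, cfg, 42L)
  expect_identical(r1, r2)
  # a different seed changes the reports
  expect_false(identical(r1, generate_reports(t1, cfg, 43L)))
})

test_that("per-scheme substreams isolate schemes from each other", {
  small <- simulation_config(schemes = "CHM", years = 2022L, labs = 5L,
                             samples = 4L)
  wide <- simulation_config(schemes = c("CHM", "HI"), years = 2022L,
                            labs = 5L, samples = 4L)
  t_small <- generate_truth(small, 7L)
  t_wide <- generate_truth(wide, 7L)
  chm_wide <- t_wide[t_wide$scheme == "CHM", ]
  rownames(chm_wide) <- NULL
  expect_identical(t_small, chm_wide)
})

test_that("truths respect the configured pools and ranges", {
  cfg <- simulation_config(schemes = c("HI", "CD", "CHM"), years = 2022L,
                           labs = 3L, samples = 20L)
  truth <- generate_truth(cfg, 5L)
  genos <- truth$payload[truth$type == "genotype"]
  # default pools give null alleles zero truth frequency
  expect_false(any(grepl("N(\\+|$|/)", genos)))
  # truths are heterozygous pairs of distinct alleles
  for (g in genos) {
    copies <- strsplit(g, "+", fixed = TRUE)[[1]]
    expect_length(copies, 2)
    expect_false(copies[1] == copies[2])
  }
  # every truth parses and satisfies the nomenclature invariants
  for (g in genos) {
    parsed <- parse_genotype(g)
    expect_identical(render_genotype(parse_genotype(render_genotype(parsed))),
                     render_genotype(parsed))
  }

  # point-mass chimerism truth
  pm <- simulation_config(schemes = "CHM", years = 2022L, labs = 3L,
                          samples = 6L, chimerism_range = c(10, 10))
  tpm <- generate_truth(pm, 5L)
  expect_true(all(tpm$payload[tpm$type == "quantitative"] == "10.0"))
})

test_that("zero error rate yields a perfect pipeline run", {
  cfg <- simulation_config(schemes = c("HI", "CHM", "ALO", "XM", "CD"),
                           years = 2022L, labs = 8L, samples = 6L,
                           error_rates = c(HI = 0, CHM = 0, ALO = 0,
                                           XM = 0, CD = 0))
  res <- run_eqa_simulation(cfg, seed = 9L)
  expect_equal(success_rate(res$evaluations), 100.0)
  expect_true(all(res$stats$n_errors == 0))
  expect_true(all(res$outcomes$outcome == "PASS"))
  expect_equal(res$pass_all$pass_all, 100.0)
})

test_that("forced quantification injection fails every chimerism result", {
  cfg <- simulation_config(schemes = "CHM", years = 2022L, labs = 6L,
                           samples = 5L, error_rates = c(CHM = 1),
                           category_mix = c(default_category_mix()[
                             setdiff(names(default_category_mix()), "CHM")],
                             list(CHM = c(QUANTIFICATION = 1))))
  truth <- generate_truth(cfg, 3L)
  reports <- generate_reports(truth, cfg, 3L)
  quant <- reports[reports$type == "quantitative", ]
  truth_quant <- truth[truth$type == "quantitative", ]
  # scored against the true value (organizer sense), every result errs
  for (i in seq_len(nrow(quant))) {
    tv <- as.numeric(
      truth_quant$payload[truth_quant$sample == quant$sample[i]])
    rs <- robust_location_scale(rep(tv, 3))
    ev <- evaluate_chimerism(as.numeric(quant$payload[i]), rs)
    expect_identical(ev$category, "QUANTIFICATION")
  }
})

test_that("injected null-allele records are exactly the unexcluded-null flags", {
  cfg <- simulation_config(schemes = "HI", years = 2022L, labs = 10L,
                           samples = 10L, error_rates = c(HI = 1),
                           category_mix = c(default_category_mix()[
                             setdiff(names(default_category_mix()), "HI")],
                             list(HI = c(NULL_ALLELE = 1))))
  truth <- generate_truth(cfg, 4L)
  reports <- generate_reports(truth, cfg, 4L)
  flagged <- vapply(seq_len(nrow(reports)), function(i) {
    g <- parse_genotype(reports$payload[i])
    any(vapply(g$calls, unexcluded_null, logical(1)))
  }, logical(1))
  expect_true(all(flagged))

  # and with injection off, no report carries an unexcluded null
  cfg0 <- simulation_config(schemes = "HI", years = 2022L, labs = 10L,
                            samples = 10L, error_rates = c(HI = 0))
  r0 <- generate_reports(generate_truth(cfg0, 4L), cfg0, 4L)
  flagged0 <- vapply(seq_len(nrow(r0)), function(i) {
    g <- parse_genotype(r0$payload[i])
    any(vapply(g$calls, unexcluded_null, logical(1)))
  }, logical(1))
  expect_false(any(flagged0))
})

test_that("report files round-trip byte-identically", {
  cfg <- simulation_config(schemes = c("HI", "ALO", "CHM"), years = 2022L,
                           labs = 4L, samples = 3L)
  truth <- generate_truth(cfg, 11L)
  reports <- generate_reports(truth, cfg, 11L)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_reports(reports, p1)
  back <- read_reports(p1)
  write_reports(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(back$payload, reports$payload)

  t1 <- withr::local_tempfile(fileext = ".csv")
  write_truth(truth, t1)
  expect_identical(read_truth(t1)$payload, truth$payload)

  pj <- withr::local_tempfile(fileext = ".json")
  write_panel(default_antibody_panel(), pj)
  expect_identical(read_panel(pj), default_antibody_panel())

  # error-free files parse with zero nomenclature errors end to end
  cfg0 <- simulation_config(schemes = "HI", years = 2022L, labs = 4L,
                            samples = 3L, error_rates = c(HI = 0))
  res0 <- run_eqa_simulation(cfg0, seed = 11L)
  expect_false(any(res0$evaluations$category %in% "NOMENCLATURE"))
})

test_that("an empty scheme list produces empty but schema-valid outputs", {
  cfg <- simulation_config(schemes = character(), years = 2022L,
                           labs = 4L, samples = 3L)
  truth <- generate_truth(cfg, 1L)
  reports <- generate_reports(truth, cfg, 1L)
  expect_equal(nrow(truth), 0)
  expect_equal(nrow(reports), 0)
  p <- withr::local_tempfile(fileext = ".csv")
  write_reports(reports, p)
  expect_equal(nrow(read_reports(p)), 0)
})

test_that("configuration validation rejects bad mixes", {
  expect_error(
    simulation_config(schemes = "CHM",
                      category_mix = c(default_category_mix()[
                        setdiff(names(default_category_mix()), "CHM")],
                        list(CHM = c(QUANTIFICATION = 0.5)))),
    class = "immunoEQA_invalid_config")
  expect_error(simulation_config(schemes = "NOPE"))
})

test_that("configurations load from JSON and YAML", {
  pj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schemes": ["CHM"], "years": [2022], "labs": 5, "samples": 4,
               "error_rates": {"CHM": 0.1}}', pj)
  cfg <- read_simulation_config(pj)
  expect_identical(cfg$schemes, "CHM")
  expect_equal(cfg$error_rates[["CHM"]], 0.1)

  py <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schemes: [HI, CHM]", "years: [2021, 2022]", "labs: 6",
               "samples: 4"), py)
  cfgy <- read_simulation_config(py)
  expect_identical(cfgy$schemes, c("HI", "CHM"))
  expect_equal(cfgy$labs[["HI"]], 6L)
})
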