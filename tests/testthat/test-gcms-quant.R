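test_that("linear retention indices interpolate the alkane ladder", {
  ladder <- synthetic_alkane_ladder()
  t27 <- ladder$rt[ladder$n == 27]
  t28 <- ladder$rt[ladder$n == 28]
  expect_equal(retention_index(t27, ladder), 2700)
  expect_equal(retention_index((t27 + t28) / 2, ladder), 2750)
  expect_equal(retention_index(c(t27, t28), ladder), c(2700, 2800))
  expect_error(retention_index(min(ladder$rt) - 1, ladder), "outside")
  expect_error(retention_index(max(ladder$rt) + 1, ladder), "outside")
  # inverse interpolation round-trips
  expect_equal(ri_to_rt(retention_index(10.5, ladder), ladder), 10.5)
})

test_that("peaks match standards by retention index and spectral score", {
  ladder <- synthetic_alkane_ladder()
  standards <- synthetic_standards()
  # a peak at a standard's exact position with its exact spectrum
  i <- which(standards$name == "fucosterol")
  pt <- peak_table(data.frame(
    rt_min = ri_to_rt(standards$ri[i], ladder),
    area = 100, spectrum = standards$spectrum[i]), sample = "s1")
  ids <- identify_peaks(pt, standards, ladder)
  expect_identical(ids$compound, "fucosterol")
  expect_equal(ids$score, 1)

  # two standards inside the RI window with distinct spectra: the higher
  # cosine similarity wins (expected scores precomputed independently)
  specA <- c("100" = 1)
  specB <- c("100" = 1, "200" = 1)
  peak_spec <- c("100" = 1, "200" = 0.5)
  two <- data.frame(name = c("stdA", "stdB"), ri = c(3000, 3004),
                    spectrum = c("100:1", "100:1;200:1"),
                    alias_note = "", role = "sterol",
                    stringsAsFactors = FALSE)
  sA <- oracle_cosine(peak_spec, specA)
  sB <- oracle_cosine(peak_spec, specB)
  expect_gt(sB, sA)
  pt2 <- peak_table(data.frame(rt_min = ri_to_rt(3002, ladder), area = 5,
                               spectrum = "100:1;200:0.5"), sample = "s2")
  ids2 <- identify_peaks(pt2, two, ladder, ri_tol = 10, s_min = 0.5)
  expect_identical(ids2$compound, "stdB")
  expect_equal(ids2$score, sB, tolerance = 1e-12)

  # equal spectral score: the smaller RI deviation breaks the tie
  tie <- data.frame(name = c("near", "far"), ri = c(3003, 3006),
                    spectrum = "100:1", alias_note = "", role = "sterol",
                    stringsAsFactors = FALSE)
  ids3 <- identify_peaks(pt2, tie, ladder, ri_tol = 10, s_min = 0.5)
  expect_identical(ids3$compound, "near")

  # no qualifying standard
  pt4 <- peak_table(data.frame(rt_min = ri_to_rt(2950, ladder), area = 5,
                               spectrum = "97:1"), sample = "s3")
  ids4 <- identify_peaks(pt4, standards, ladder)
  expect_identical(ids4$compound, "unidentified")
})

test_that("peak tables are validated on construction", {
  expect_error(peak_table(data.frame(rt_min = c(5, 4), area = 1,
                                     spectrum = "100:1"), "s"),
               "increasing")
  expect_error(peak_table(data.frame(rt_min = 5, area = -1,
                                     spectrum = "100:1"), "s"),
               "negative")
  expect_error(peak_table(data.frame(rt_min = 5, area = 1,
                                     spectrum = "30:1"), "s"),
               "50-500")
})

test_that("response-factor calibration averages across mixes and levels", {
  gen <- gen_peak_tables(c(cholesterol = 10, fucosterol = 50),
                         rrf_truth = c(cholesterol = 1.3, fucosterol = 0.7),
                         seed = 5)
  rrf <- calibrate(gen$calibration)
  expect_equal(rrf$rrf[rrf$sterol == "cholesterol"], 1.3, tolerance = 1e-12)
  expect_equal(rrf$rrf[rrf$sterol == "fucosterol"], 0.7, tolerance = 1e-12)
  expect_true(all(rrf$rel_spread < 1e-12))

  # a compound responding exactly like the internal standard has RRF 1
  cs <- data.frame(sterol = "x", mix = c(1, 1, 2, 2),
                   level_conc = c(10, 20, 10, 20),
                   area = c(0.2, 0.4, 0.2, 0.4) * 1e6,
                   is_area = 1e6, is_conc = 50)
  expect_equal(calibrate(cs)$rrf, 1)
  cs_zero <- transform(cs, area = 0)
  expect_error(calibrate(cs_zero), "zero")
  cs_is <- transform(cs, is_area = 0)
  expect_error(calibrate(cs_is), "positive")
  expect_warning(calibrate(cs[cs$mix == 1, ]), "single")
})

test_that("quantification inverts the generator exactly without noise", {
  mass <- c(cholesterol = 20, fucosterol = 120, desmosterol = 4,
            zymosterol = 0.004, squalene = 10)
  rrf_true <- c(cholesterol = 1.3, fucosterol = 0.9, desmosterol = 1.1,
                zymosterol = 1.2, squalene = 0.8)
  gen <- gen_peak_tables(mass, rrf_truth = rrf_true, seed = 42)
  rrf <- calibrate(gen$calibration)
  ids <- identify_peaks(gen$peaks, gen$standards, gen$ladder)
  prof <- quantify(gen$peaks, ids, rrf)
  got <- prof$mass_ug[match(names(mass), prof$compound)]
  expect_lt(max(abs(got - mass) / mass), 1e-9)
  expect_equal(sum(prof$pct), 100, tolerance = 1e-6)
  # concentration per dry weight uses the 60 mg default
  expect_equal(prof$conc_ug_mg[prof$compound == "fucosterol"], 120 / 60)
  # the 0.0026 % component is flagged nd, everything else detected
  expect_identical(prof$status[prof$compound == "zymosterol"], "nd")
  expect_true(all(prof$status[prof$compound != "zymosterol"] == "detected"))
})

test_that("quantification is invariant to a global area rescaling", {
  mass <- c(cholesterol = 15, fucosterol = 90)
  gen <- gen_peak_tables(mass, seed = 8)
  rrf <- calibrate(gen$calibration)
  ids <- identify_peaks(gen$peaks, gen$standards, gen$ladder)
  p1 <- quantify(gen$peaks, ids, rrf)
  ids2 <- ids; ids2$area <- ids2$area * 7.3
  pt2 <- gen$peaks; pt2$area <- pt2$area * 7.3
  p2 <- quantify(pt2, ids2, rrf)
  expect_equal(p1$mass_ug, p2$mass_ug, tolerance = 1e-12)
  expect_equal(p1$pct, p2$pct, tolerance = 1e-12)
})

test_that("a single detected sterol normalises to 100 percent", {
  gen <- gen_peak_tables(c(cholesterol = 30), seed = 2)
  prof <- quantify(gen$peaks,
                   identify_peaks(gen$peaks, gen$standards, gen$ladder),
                   calibrate(gen$calibration))
  expect_equal(prof$pct, 100)
})

test_that("a missing internal standard is an error", {
  gen <- gen_peak_tables(c(cholesterol = 30), seed = 2)
  ids <- identify_peaks(gen$peaks, gen$standards, gen$ladder)
  ids$compound[ids$compound == "5a-cholestane"] <- "unidentified"
  expect_error(quantify(gen$peaks, ids, calibrate(gen$calibration)),
               "internal standard")
})

test_that("support states follow the cholesterol/desmosterol rule", {
  st <- function(...) support_state(c(...), species = "sp")$state
  expect_identical(st(cholesterol = "detected", desmosterol = "detected"),
                   "strong")
  expect_identical(st(cholesterol = "detected", desmosterol = "nd"), "weak")
  expect_identical(st(cholesterol = "nd", desmosterol = "nd"), "none")
  # desmosterol alone is not evidence for the late-reduction pathway end
  expect_identical(st(cholesterol = "nd", desmosterol = "detected"), "none")
  # missing compounds count as not detected
  expect_identical(st(fucosterol = "detected"), "none")
})

test_that("quantification error scales with multiplicative noise", {
  mass <- c(cholesterol = 20, fucosterol = 120, desmosterol = 4)
  mare <- vapply(c(0.02, 0.10), function(sig) {
    errs <- vapply(1:40, function(i) {
      gen <- gen_peak_tables(mass, noise_sd = sig, seed = 1000 + i)
      prof <- quantify(gen$peaks,
                       identify_peaks(gen$peaks, gen$standards, gen$ladder),
                       calibrate(gen$calibration))
      got <- prof$mass_ug[match(names(mass), prof$compound)]
      mean(abs(got - mass) / mass)
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(mare[1], mare[2])
  expect_lt(mare[1], 0.05)
})
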