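test_that("class profiles are deterministic, distinct, and ghost mirrors RBC membrane", {
  p_plasma <- class_profile("plasma")
  expect_gt(p_plasma$band_weights[["amide_I"]], 0)
  expect_gt(p_plasma$band_weights[["amide_II"]], 0)

  rbc <- class_profile("RBC")
  ghost <- class_profile("RBC-ghost")
  expect_identical(ghost$band_weights[["ch2_sym"]],
                   rbc$band_weights[["ch2_sym"]])
  expect_identical(ghost$band_weights[["ch2_asym"]],
                   rbc$band_weights[["ch2_asym"]])
  expect_lt(ghost$band_weights[["amide_I"]], rbc$band_weights[["amide_I"]])
  expect_lt(ghost$band_weights[["amide_II"]], rbc$band_weights[["amide_II"]])

  cls <- component_classes()
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (i < j) {
        wi <- class_profile(cls[i])$band_weights
        wj <- class_profile(cls[j])$band_weights
        expect_true(any(wi != wj), info = paste(cls[i], "vs", cls[j]))
      }
    }
  }

  expect_error(class_profile("platelet"), "unknown")
})

test_that("generate_cohort honours shape, grid, and the seeding contract", {
  cfg <- synth_config(n_patients_per_class = 2, seed = 1)
  set1 <- generate_cohort(cfg)
  expect_s3_class(set1, "spectrum_set")
  expect_equal(ncol(set1$absorbance), 10)       # 2 patients x 5 classes
  expect_equal(nrow(set1$absorbance), 1501)     # (4000 - 1000)/2 + 1
  expect_equal(set1$wavenumber[1], 4000)
  expect_equal(set1$wavenumber[1501], 1000)
  expect_equal(nrow(set1$metadata), 10)
  expect_setequal(unique(set1$metadata$class), component_classes())

  set1b <- generate_cohort(cfg)
  expect_identical(set1$absorbance, set1b$absorbance)
  set2 <- generate_cohort(synth_config(n_patients_per_class = 2, seed = 2))
  expect_false(identical(set1$absorbance, set2$absorbance))
})

test_that("degenerate noise settings give identical spectra within class", {
  profs <- default_class_profiles(baseline_slope_range = c(0, 0),
                                  baseline_offset_range = c(0, 0),
                                  noise_sd = 0)
  cfg <- synth_config(n_patients_per_class = 3, patient_sd = 0, seed = 4,
                      group_counts = c(cirrhosis = 3))
  set <- generate_cohort(cfg, profs, effect = NULL)
  for (cls in component_classes()) {
    x <- set$absorbance[, set$metadata$class == cls, drop = FALSE]
    expect_equal(max(abs(sweep(x, 1, x[, 1]))), 0, info = cls)
  }
})

test_that("inject_disease_effect adds the tapered bump and nothing else", {
  wn <- seq(4000, 1000, by = -2)
  a <- rep(0.5, length(wn))

  zero_eff <- disease_effect(effect_sizes = c(amide_II = 0, ch2 = 0,
                                              nucleic = 0))
  expect_identical(inject_disease_effect(a, wn, zero_eff), a)

  one <- disease_effect(windows = list(w = c(2000, 2100)),
                        effect_sizes = c(w = 0.1), taper = 25)
  out <- inject_disease_effect(a, wn, one)
  inside <- wn >= 2000 & wn <= 2100
  expect_identical(out[!inside], a[!inside])
  # direct-subtraction oracle: bump equals effect size times the taper shape
  shape <- irlatent:::.window_taper(wn, 2000, 2100, taper = 25)
  expect_equal(out - a, 0.1 * shape)
  expect_equal(mean(out[inside] - a[inside]), 0.1 * mean(shape[inside]))

  # two disjoint windows: additive and non-overlapping
  two <- disease_effect(windows = list(w1 = c(2000, 2100),
                                       w2 = c(3000, 3100)),
                        effect_sizes = c(w1 = 0.1, w2 = 0.2), taper = 25)
  out2 <- inject_disease_effect(a, wn, two)
  d <- out2 - a
  s1 <- 0.1 * irlatent:::.window_taper(wn, 2000, 2100, taper = 25)
  s2 <- 0.2 * irlatent:::.window_taper(wn, 3000, 3100, taper = 25)
  expect_equal(d, s1 + s2)
  expect_equal(sum(s1 * s2), 0)

  bad <- disease_effect(windows = list(w = c(500, 900)),
                        effect_sizes = c(w = 0.1))
  expect_error(inject_disease_effect(a, wn, bad), "window_outside_grid")
})

test_that("disease effect shifts only EV spectra of the target group", {
  profs <- default_class_profiles(baseline_slope_range = c(0, 0),
                                  baseline_offset_range = c(0, 0),
                                  noise_sd = 0)
  cfg <- synth_config(n_patients_per_class = 6, patient_sd = 0, seed = 9)
  eff <- disease_effect()
  set <- generate_cohort(cfg, profs, eff)
  g <- set$metadata$group
  for (cls in component_classes()) {
    sel <- set$metadata$class == cls
    hcc <- rowMeans(set$absorbance[, sel & g == "HCC", drop = FALSE])
    cir <- rowMeans(set$absorbance[, sel & g == "cirrhosis", drop = FALSE])
    d <- hcc - cir
    if (cls %in% eff$classes) {
      in_any <- Reduce(`|`, lapply(eff$windows, function(w)
        set$wavenumber >= w[1] & set$wavenumber <= w[2]))
      expect_true(all(d[!in_any] == 0), info = cls)
      expect_gt(max(d[in_any]), 0)
    } else {
      expect_true(all(d == 0), info = cls)
    }
  }
})

test_that("cohorts round-trip through the wide-CSV writer", {
  set <- small_cohort(n = 2, seed = 77)
  spectra <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_set(set, spectra, meta)
  back <- read_spectrum_set(spectra, meta)
  expect_equal(back$wavenumber, set$wavenumber)
  expect_equal(unname(back$absorbance), unname(set$absorbance),
               tolerance = 1e-12)
  expect_equal(back$metadata$class, set$metadata$class)
})

test_that("generated classes are recoverable by k-means on preprocessed spectra", {
  skip_if_not_installed("mclust")
  coh <- generate_cohort(synth_config(n_patients_per_class = 20, seed = 11))
  pp <- preprocess_set(coh)
  km <- stats::kmeans(pp$x, centers = 5, nstart = 25)
  ari <- mclust::adjustedRandIndex(km$cluster, pp$metadata$class)
  expect_gte(ari, 0.8)
})
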