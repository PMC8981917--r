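test_that("drag subtraction: constant offset and interpolation against a dense oracle", {
  # constant 2 mN baseline shifts loads down by 2 mN
  tr <- tensile_trace(c(0, 0.05, 0.1), c(0, 0.5, 1.0), c(0.003, 0.007, 0.012))
  bl <- tensile_trace(c(0, 0.05, 0.1), c(0, 0.5, 1.0), rep(0.002, 3),
                      is_baseline = TRUE)
  out <- subtract_drag(tr, bl)
  expect_equal(out$load, c(0.001, 0.005, 0.010))
  expect_equal(out$extension, tr$extension)

  # coarse baseline grid: corrected load matches independent linear interpolation
  set.seed(7)
  ext_fine <- seq(0, 2, by = 0.01)
  tr2 <- tensile_trace(seq_along(ext_fine) * 0.05, ext_fine,
                       0.05 * ext_fine + 0.01)
  ext_coarse <- seq(0, 2, by = 0.25)
  bl_load <- 0.002 * sqrt(ext_coarse)
  bl2 <- tensile_trace(seq_along(ext_coarse) * 0.05, ext_coarse, bl_load,
                       is_baseline = TRUE)
  out2 <- subtract_drag(tr2, bl2)
  oracle <- tr2$load - approx(ext_coarse, bl_load, xout = ext_fine)$y
  expect_equal(out2$load, oracle)

  # baseline covering too little of the trace range errors
  bl3 <- tensile_trace(c(0, 0.05), c(0, 0.5), c(0, 0.001), is_baseline = TRUE)
  expect_error(subtract_drag(tr2, bl3), "covers only")
  expect_error(subtract_drag(tr, tr2), "is_baseline")
})

test_that("tension onset follows the 5 mN raw-load rule", {
  tr <- tensile_trace(time = (0:4) * 0.05, extension = c(0, 0.005, 0.01, 0.015, 0.02),
                      load = c(1, 3, 4, 6, 9) / 1000)
  p <- test_protocol()
  onset <- detect_tension_onset(tr, p)
  expect_equal(onset$onset_index, 4L)        # first load above 5 mN (1-based)
  expect_equal(onset$gauge_length, 5.015)    # 5 mm + extension at onset
  low <- tensile_trace((0:2) * 0.05, c(0, 1, 2), c(0.001, 0.002, 0.005))
  expect_error(detect_tension_onset(low, p), "never in tension")
  expect_error(detect_tension_onset(tr, p, threshold = -1), "positive")
})

test_that("elliptical area closed forms", {
  expect_equal(elliptical_area(1, 1), pi / 4)
  expect_equal(elliptical_area(0.8, 0.6), 0.12 * pi)
  expect_error(elliptical_area(0, 1), "positive")
})

test_that("stress-strain conversion implements the defining identities", {
  tr <- tensile_trace(time = (0:3) * 0.05,
                      extension = c(0, 1, 5 * (exp(1) - 1), 10),
                      load = c(0, 0.2, 0.3, 0.4))
  cv <- to_stress_strain(tr, 1, 5, 0.25)
  expect_equal(cv$eng_stress[2], 0.4)              # 0.2 N / (2 * 0.25 mm^2)
  expect_equal(cv$true_strain[1], 0)
  expect_equal(cv$true_strain[3], 1)               # eng strain e - 1
  expect_equal(cv$true_strain, log(1 + cv$eng_strain))
  expect_equal(cv$true_stress, cv$eng_stress * (1 + cv$eng_strain))
  # eng stress 2 at eng strain 0.5 -> true stress 3
  cv2 <- curve_from_arrays(c(0, 0.5), c(0, 2))
  expect_equal(cv2$true_stress[2], 3.0)
  expect_error(to_stress_strain(tr, 1, -5, 0.25), "gauge_length")
  expect_error(to_stress_strain(tr, 9, 5, 0.25), "onset_index")
})

test_that("equation identities hold to 1e-12 relative tolerance on generated curves", {
  for (seed in 1:5) {
    sp <- make_specimen(E = 10 + 5 * seed, uts = 1 + 0.4 * seed,
                        noise_sd = 5, seed = seed)
    onset <- detect_tension_onset(sp$trace, sp$protocol)
    cv <- to_stress_strain(sp$trace, onset$onset_index, onset$gauge_length,
                           sp$geom$a0_min)
    expect_equal(cv$true_strain, log(1 + cv$eng_strain), tolerance = 1e-12)
    expect_equal(cv$true_stress, cv$eng_stress * (1 + cv$eng_strain),
                 tolerance = 1e-12)
    expect_equal(cv$eng_strain[1], 0)
    expect_true(all(diff(cv$eng_strain) >= 0))
  }
})

test_that("tangent modulus: exact line, quadratic closed form, contracts", {
  strain <- seq(0, 0.3, length.out = 500)
  lin <- curve_from_arrays(strain, 20 * strain)
  prof <- tangent_modulus_profile(lin, 0.08)
  expect_equal(prof$slope, rep(20, nrow(prof)), tolerance = 1e-9)

  # sigma = 100 eps^2: continuous LS slope over the last window [0.22, 0.30]
  # is 100 * (0.22 + 0.30) = 52
  quad <- curve_from_arrays(seq(0, 0.30, length.out = 1000),
                            100 * seq(0, 0.30, length.out = 1000)^2)
  pq <- tangent_modulus_profile(quad, 0.08)
  expect_rel_equal(max(pq$slope), 52, 0.01)

  # full-span window equals the global OLS slope
  pall <- tangent_modulus_profile(quad, 0.30)
  ref <- unname(coef(lm(quad$eng_stress ~ quad$eng_strain))[2])
  expect_equal(pq_all <- pall$slope[1], ref, tolerance = 1e-9)

  short <- curve_from_arrays(c(0, 0.01, 0.02), c(0, 1, 2))
  expect_error(tangent_modulus_profile(short, 0.08), "curve too short")
})

test_that("failure rule reproduces worked examples and boundary behaviour", {
  f1 <- detect_failure(c(10, 50, 100, 58))
  expect_true(f1$failure_detected)
  expect_equal(f1$failure_index, 4L)          # 58 < 0.6 * 100
  f2 <- detect_failure(c(100, 70))            # 30% drop: below threshold
  expect_false(f2$failure_detected)
  expect_equal(f2$failure_index, 2L)
  f3 <- detect_failure(1:50)                  # monotone: no failure
  expect_false(f3$failure_detected)
  expect_equal(f3$failure_index, 50L)
  expect_error(detect_failure(1), "2 samples")
})

test_that("summary: endpoints from a linear-then-rupture curve, ties and contracts", {
  strain <- seq(0, 0.3, by = 5e-4)
  stress <- 10 * strain
  strain <- c(strain, max(strain) + 5e-4)
  stress <- c(stress, 0.3 * max(stress))       # 70% drop
  cv <- curve_from_arrays(strain, stress)
  prof <- tangent_modulus_profile(cv, 0.08)
  fl <- detect_failure(cv)
  sm <- summarize_mechanics(cv, prof, fl)
  expect_equal(sm$uts, 3.0, tolerance = 1e-9)
  expect_equal(sm$mtm, 10, tolerance = 1e-9)
  expect_equal(sm$failure_strain, max(strain))
  expect_true(sm$failure_detected)
  # exact ties in the max slope resolve to the earliest window
  prof2 <- data.frame(window_start_strain = c(0, 0.1, 0.2),
                      window_end_strain = c(0.08, 0.18, 0.28),
                      start_index = c(1L, 50L, 100L),
                      end_index = c(40L, 90L, 140L),
                      slope = c(5, 5, 4))
  sm_tie <- summarize_mechanics(cv, prof2,
                                list(failure_index = length(cv$eng_strain),
                                     failure_detected = TRUE))
  expect_equal(sm_tie$mtm, 5)
  expect_equal(sm_tie$mtm_window_start_strain, 0)
  # identical curves give identical summaries
  sm2 <- summarize_mechanics(cv, prof, fl)
  expect_identical(sm, sm2)
  expect_error(summarize_mechanics(cv, prof[0, ], fl), "empty")
  expect_error(summarize_mechanics(cv, prof, list(failure_index = 2,
                                                  failure_detected = TRUE)),
               "before the first full tangent window")
})

test_that("MTM from true stress-strain exceeds the engineering MTM on rising curves", {
  for (seed in 1:5) {
    sp <- make_specimen(E = 8 + 6 * seed, uts = 1 + 0.5 * seed, seed = seed)
    onset <- detect_tension_onset(sp$trace, sp$protocol)
    cv <- to_stress_strain(sp$trace, onset$onset_index, onset$gauge_length,
                           sp$geom$a0_min)
    fl <- detect_failure(cv)
    pe <- tangent_modulus_profile(cv, 0.08, "engineering", last_index = fl$failure_index)
    pt <- tangent_modulus_profile(cv, 0.08, "true", last_index = fl$failure_index)
    expect_gt(max(pt$slope), max(pe$slope))
  }
})

test_that("MTM lands in the linear region, past the toe, on J-shaped curves", {
  for (seed in 1:5) {
    toe <- 0.03 + 0.005 * seed
    sp <- make_specimen(E = 20, uts = 3, toe = toe, seed = seed)
    row <- analyze_trace(sp$trace, NULL, sp$geom, sp$protocol)
    smfull <- local({
      onset <- detect_tension_onset(sp$trace, sp$protocol)
      cv <- to_stress_strain(sp$trace, onset$onset_index, onset$gauge_length,
                             sp$geom$a0_min)
      prof <- tangent_modulus_profile(cv, 0.08)
      summarize_mechanics(cv, prof, detect_failure(cv))
    })
    # strain is referenced to the 5 mN onset, which sits slightly inside
    # the toe; allow that shift when checking the window starts past it
    onset_shift <- sqrt(2 * toe * 0.005 / (2 * sp$geom$a0_mean) / 20)
    expect_gte(smfull$mtm_window_start_strain + onset_shift + 0.002, toe)
  }
})

test_that("parameter recovery holds at 1% load noise across a seeded sweep", {
  set.seed(99)
  p <- default_protocol()
  bl <- gen_drag_baseline(p, 2)
  for (i in 1:8) {
    E <- runif(1, 5, 40)
    uts <- pmin(5, pmax(0.5, E * runif(1, 0.12, 0.2)))
    toe <- runif(1, 0.02, 0.05)
    geom <- geom_with_area(0.3)
    noise_mN <- 0.01 * 2 * geom$a0_mean * uts * 1000
    sp <- make_specimen(E = E, uts = uts, toe = toe, noise_sd = noise_mN,
                        drag = 2, seed = 1000 + i)
    row <- analyze_trace(sp$trace, bl, sp$geom, sp$protocol, peak_smooth_s = 2.5)
    expect_rel_equal(row$mtm_mpa, E, 0.05)
    expect_rel_equal(row$uts_mpa, uts, 0.02)
  }
})
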