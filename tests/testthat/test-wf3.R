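test_that("upper limit is pooled mean plus two population SDs", {
  # pixels {90, 110} repeated: mean 100, population SD 10 -> UL = 120
  s <- manual_limits_subject(c(90, 110), fat_values = c(30, 30, 31))
  lim <- compute_reference_limits(structure(list(s), class = "stirq_cohort"))
  expect_equal(unname(lim$UL), rep(120, 6))
  expect_named(lim$UL, calf_muscles())
})

test_that("lower limit is the histogram mode, robust to vessel admixture", {
  # mode by count: 500 pixels at 30 vs 20 at 60
  fat <- c(rep(30, 500), rep(60, 20))
  s <- manual_limits_subject(c(90, 110), fat)
  lim <- compute_reference_limits(structure(list(s), class = "stirq_cohort"))
  expect_equal(lim$LL, 30)
  # adding 5% bright vessel pixels leaves the mode unchanged
  with_vessels <- c(fat, rep(200, round(0.05 * length(fat))))
  s2 <- manual_limits_subject(c(90, 110), with_vessels)
  lim2 <- compute_reference_limits(structure(list(s2), class = "stirq_cohort"))
  expect_equal(lim2$LL, 30)
  # while the pooled mean does move upward (the rationale for using the mode)
  expect_gt(mean(with_vessels), mean(fat))
})

test_that("missing subcutaneous fat or empty pools are reported", {
  fshd <- tiny_fshd(n = 2, seed = 61)
  expect_error(compute_reference_limits(fshd), class = "stirq_wf3_error")
})

test_that("FFG and MEG are strict-threshold pixel fractions", {
  lim <- structure(list(UL = setNames(rep(120, 6), calf_muscles()),
                        LL = 30, bin_width = 1), class = "stirq_limits")
  v <- compute_ffg_meg(manual_grade_subject(c(10, 20, 40, 50)), "S", lim,
                       slice_index = 1)
  expect_equal(v$FFG, 0.5)    # 10 and 20 below LL = 30
  expect_equal(v$MEG, 0)
  v2 <- compute_ffg_meg(manual_grade_subject(c(100, 130, 90, 125)), "S", lim,
                        slice_index = 1)
  expect_equal(v2$MEG, 0.5)   # 130 and 125 above UL = 120
  expect_equal(v2$FFG, 0)
  # boundary values count for neither grade (strict inequalities) and sides
  # with different compositions are averaged
  v3 <- compute_ffg_meg(manual_grade_subject(c(30, 60, 120, 60)), "S", lim,
                        slice_index = 1)
  expect_equal(v3$FFG, 0)
  expect_equal(v3$MEG, 0)
  v4 <- compute_ffg_meg(
    manual_grade_subject(c(10, 10, 10, 10), c(60, 60, 60, 60)), "S", lim,
    slice_index = 1)
  expect_equal(v4$FFG, 0.5)   # mean of 1 (left) and 0 (right)
})

test_that("WF3 tables pair each muscle's grade with its biomarker", {
  hc <- tiny_hc(n = 2, seed = 7)
  fshd <- tiny_fshd(n = 4, seed = 71)
  lim <- compute_reference_limits(hc)
  tabs <- build_wf3_tables(fshd, lim)
  expect_named(tabs, calf_muscles())
  for (m in calf_muscles()) {
    expect_equal(nrow(tabs[[m]]$FF), 4)
    expect_named(tabs[[m]]$FF, c("subject_id", "FFG", "FF_pp"))
    expect_named(tabs[[m]]$wT2, c("subject_id", "MEG", "wT2_ms"))
    expect_true(all(tabs[[m]]$FF$FFG >= 0 & tabs[[m]]$FF$FFG <= 1))
  }
  # deterministic given cohort and limits
  expect_identical(tabs, build_wf3_tables(fshd, lim))
})

test_that("fat-free phantoms give near-zero fat infiltration grades", {
  zero <- tidyr::expand_grid(muscle = calf_muscles(), side = c("left", "right"))
  zero$f <- 0; zero$e <- 0
  fshd <- generate_fshd_cohort(phantom_params(n_subjects = 3, seed = 73),
                               latent_override = zero)
  lim <- compute_reference_limits(tiny_hc(n = 2, seed = 7))
  tabs <- build_wf3_tables(fshd, lim)
  ffg <- unlist(lapply(tabs, function(t) t$FF$FFG))
  # the muscle law leaves essentially no mass below LL (7 SDs away)
  expect_true(all(ffg <= 0.02))
})

test_that("grades track the latent fractions monotonically across ROIs", {
  fshd <- generate_fshd_cohort(phantom_params(n_subjects = 5, seed = 79))
  lim <- compute_reference_limits(tiny_hc(n = 2, seed = 7))
  d <- purrr::map_dfr(fshd, function(s) {
    grades <- purrr::map_dfr(calf_muscles(), function(m)
      compute_ffg_meg(s, m, lim))
    lat <- dplyr::summarise(dplyr::group_by(s$latent, muscle),
                            f = mean(f), e = mean(e), .groups = "drop")
    dplyr::left_join(grades, lat, by = "muscle")
  })
  expect_gte(nrow(d), 30)   # 5 subjects x 6 muscles, sides averaged
  expect_gt(cor(d$f, d$FFG, method = "spearman"), 0.9)
  expect_gt(cor(d$e, d$MEG, method = "spearman"), 0.9)
})

test_that("grades are invariant under a joint monotone intensity map", {
  hc <- tiny_hc(n = 2, seed = 7)
  fshd <- tiny_fshd(n = 2, seed = 83)
  remap <- function(cohort, f) {
    out <- purrr::map(cohort, function(s) {
      s$slices <- purrr::map(s$slices, function(sl) {
        slice_image(f(sl$pixels), sl$pixel_spacing, sl$slice_thickness)
      })
      s
    })
    structure(out, class = "stirq_cohort")
  }
  up <- function(x) 2 * x + 10          # strictly increasing affine map
  lim0 <- compute_reference_limits(hc, bin_width = 1)
  lim1 <- compute_reference_limits(remap(hc, up), bin_width = 2)
  g0 <- purrr::map_dfr(calf_muscles(), function(m)
    compute_ffg_meg(fshd[[1]], m, lim0))
  g1 <- purrr::map_dfr(calf_muscles(), function(m)
    compute_ffg_meg(remap(fshd, up)[[1]], m, lim1))
  expect_equal(g1$MEG, g0$MEG)
  expect_equal(g1$FFG, g0$FFG, tolerance = 0.01)
})

test_that("reference limits serialize to JSON and back", {
  lim <- compute_reference_limits(tiny_hc(n = 2, seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_limits(lim, path)
  back <- read_reference_limits(path)
  expect_equal(back$UL, lim$UL)
  expect_equal(back$LL, lim$LL)
  expect_equal(tidy(back), tidy(lim))
})
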