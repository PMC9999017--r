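test_that("parameter validation rejects bad fields by name", {
  expect_error(phantom_params(muscle_intensity_sd = 0), "muscle_intensity_sd",
               class = "stirq_config_error")
  expect_error(phantom_params(n_subjects = 1), "n_subjects",
               class = "stirq_config_error")
  expect_error(phantom_params(image_size = c(32, 128)), "image_size",
               class = "stirq_config_error")
  expect_error(phantom_params(fat_intensity_mode = 150), "fat_intensity_mode",
               class = "stirq_config_error")
})

test_that("healthy-control cohort has the stated structure", {
  hc <- generate_hc_cohort(phantom_params(n_subjects = 6, seed = 7))
  expect_length(hc, 6)
  for (s in hc) {
    expect_length(s$slices, 6)
    labs <- sort(unique(as.vector(s$masks[[1]])))
    expect_setequal(setdiff(labs, 0), 1:13)  # 12 muscle regions + SUBCUT_FAT
    expect_true(all(s$slices[[1]]$pixels >= 0))
  }
  # every muscle region is large enough for robust statistics
  n_px <- vapply(1:12, function(lab) sum(hc[[1]]$masks[[1]] == lab), numeric(1))
  expect_true(all(n_px >= 64))
})

test_that("generation is deterministic given the seed", {
  a <- generate_fshd_cohort(phantom_params(n_subjects = 3, seed = 99))
  b <- generate_fshd_cohort(phantom_params(n_subjects = 3, seed = 99))
  expect_identical(a, b)
  c2 <- generate_fshd_cohort(phantom_params(n_subjects = 3, seed = 100))
  expect_false(identical(a[[1]]$slices[[1]]$pixels, c2[[1]]$slices[[1]]$pixels))
})

test_that("FSHD cohort carries complete ground truth linked to the latents", {
  co <- generate_fshd_cohort(phantom_params(n_subjects = 25, seed = 1234))
  expect_length(co, 25)
  gt <- ground_truth_table(co)
  expect_equal(nrow(gt), 25 * 6)
  expect_true(all(is.finite(gt$FF_pp)), all(gt$FF_pp >= 0 & gt$FF_pp <= 100))
  expect_true(all(gt$wT2_ms > 0))
  for (s in co) {
    expect_equal(sort(s$ground_truth$muscle), sort(calf_muscles()))
    expect_true(all(s$latent$f + s$latent$e <= 1))
  }
})

test_that("degenerate latent override gives noise-only ground truth", {
  zero <- tidyr::expand_grid(muscle = calf_muscles(),
                             side = c("left", "right"))
  zero$f <- 0; zero$e <- 0
  p <- phantom_params(n_subjects = 10, seed = 21)
  co <- generate_fshd_cohort(p, latent_override = zero)
  gt <- ground_truth_table(co)
  expect_true(all(gt$FF_pp <= 3 * p$ff_noise_sd))       # clipped at 0 below
  expect_true(all(abs(gt$wT2_ms - p$wt2_baseline) <= 3 * p$wt2_noise_sd))
})

test_that("empirical ROI fat fraction matches the requested latent fraction", {
  # large ROIs (>= 2000 px) so the pixel count resolves the fraction finely
  p <- phantom_params(n_subjects = 2, seed = 31, image_size = c(224, 224),
                      roi_size = 48)
  lat <- tidyr::expand_grid(muscle = calf_muscles(), side = c("left", "right"))
  lat$f <- rep(c(0.15, 0.45), 6); lat$e <- 0.1
  co <- generate_fshd_cohort(p, latent_override = lat)
  s <- co[[1]]
  for (m in c("S", "TA")) {
    for (sd_ in c("left", "right")) {
      px <- roi_pixels(s, 1, m, sd_)
      expect_gte(length(px), 2000)
      f_req <- lat$f[lat$muscle == m & lat$side == sd_]
      # fat pixels are dark: count below the midpoint between fat and muscle
      f_emp <- mean(px < 65)
      expect_lt(abs(f_emp - f_req), 0.02)
    }
  }
})

test_that("ground-truth regression recovers the generator slope", {
  co <- generate_fshd_cohort(phantom_params(n_subjects = 25, seed = 1234))
  d <- purrr::map_dfr(co, function(s) {
    lat <- dplyr::summarise(dplyr::group_by(s$latent, muscle),
                            f_bar = mean(f), .groups = "drop")
    dplyr::left_join(s$ground_truth, lat, by = "muscle")
  })
  expect_gte(nrow(d), 50)
  slope <- coef(lm(FF_pp ~ f_bar, data = d))[["f_bar"]]
  expect_lt(abs(slope - 100) / 100, 0.05)
})

test_that("pooled subcutaneous-fat histogram mode equals the fat mode parameter", {
  hc <- generate_hc_cohort(phantom_params(n_subjects = 6, seed = 7))
  fat <- unlist(lapply(hc, function(s) {
    lapply(seq_along(s$slices), function(k) roi_pixels(s, k, "SUBCUT_FAT"))
  }))
  expect_gte(length(fat), 1e4)
  counts <- table(round(fat))
  mode_val <- as.numeric(names(counts)[which.max(counts)])
  expect_lte(abs(mode_val - 30), 1)
})

test_that("cohort serialization round-trips every field and is byte-stable", {
  co <- generate_fshd_cohort(phantom_params(n_subjects = 2, seed = 5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  manifest <- write_cohort(co, d1)
  write_cohort(co, d2)
  rt <- read_cohort(d1)
  for (i in seq_along(co)) {
    expect_identical(rt[[i]]$subject_id, co[[i]]$subject_id)
    for (k in seq_along(co[[i]]$slices)) {
      expect_equal(rt[[i]]$slices[[k]]$pixels, co[[i]]$slices[[k]]$pixels)
      expect_identical(rt[[i]]$masks[[k]], co[[i]]$masks[[k]])
    }
    expect_equal(as.data.frame(rt[[i]]$ground_truth),
                 as.data.frame(co[[i]]$ground_truth))
  }
  # manifest lists one entry per subject with one file per slice
  man <- jsonlite::read_json(manifest)
  expect_length(man, 2)
  expect_length(man[[1]]$slices, length(co[[1]]$slices))
  # identical cohorts serialize to identical bytes
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("reading a non-cohort directory fails with an informative error", {
  d <- withr::local_tempdir()
  expect_error(read_cohort(d), "manifest", class = "stirq_io_error")
})
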