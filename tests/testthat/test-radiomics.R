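test_that("quantization follows the equal-width binning conventions", {
  # 64 distinct equally spaced values with G = 64 map bijectively to 1..64
  q <- quantize_roi(matrix(0:63, 8, 8), G = 64)
  expect_setequal(q$levels, 1:64)
  expect_equal(sort(unique(q$levels)), 1:64)
  # constant ROI collapses to level 1
  qc <- quantize_roi(matrix(7, 4, 4), G = 16)
  expect_true(all(qc$levels == 1))
  # boundary value 10 stays in the first (closed) bin
  qb <- quantize_roi(matrix(c(0, 10, 20), 1, 3), G = 2)
  expect_equal(qb$levels, c(1, 1, 2))
  expect_error(quantize_roi(matrix(1, 2, 2), mask = matrix(0, 2, 2)),
               class = "stirq_radiomics_error")
})

test_that("first-order features match hand computations", {
  q <- quantize_roi(matrix(c(1, 2, 3, 4), 2, 2), G = 4)
  f <- first_order_features(q)
  expect_equal(f[["CONVENTIONAL_mean"]], 2.5)
  expect_equal(f[["CONVENTIONAL_std"]], sqrt(1.25))   # population sd
  expect_equal(f[["CONVENTIONAL_Q1"]], 1.75)          # type-7 quantiles
  expect_equal(f[["CONVENTIONAL_median"]], 2.5)
  expect_equal(f[["CONVENTIONAL_Q3"]], 3.25)
  expect_equal(f[["CONVENTIONAL_sum"]], 10)
  expect_equal(f[["CONVENTIONAL_RMS"]], sqrt(mean(c(1, 4, 9, 16))))

  # constant ROI: degenerate distribution
  fc <- first_order_features(quantize_roi(matrix(5, 3, 3), G = 8))
  expect_equal(fc[["CONVENTIONAL_mean"]], 5)
  expect_equal(fc[["CONVENTIONAL_std"]], 0)
  expect_equal(fc[["CONVENTIONAL_uniformity"]], 1)
  expect_equal(fc[["CONVENTIONAL_entropy_log2"]], 0)
  expect_equal(fc[["CONVENTIONAL_hist_mode"]], 5)

  # two equal-mass levels
  f2 <- first_order_features(quantize_roi(matrix(c(0, 0, 1, 1), 2, 2), G = 2))
  expect_equal(f2[["CONVENTIONAL_uniformity"]], 0.5)
  expect_equal(f2[["CONVENTIONAL_entropy_log2"]], 1)

  expect_error(first_order_features(quantize_roi(matrix(1, 1, 1), G = 2)),
               class = "stirq_radiomics_error")
})

test_that("GLCM features agree with the pair-enumeration oracle", {
  # degenerate single-cell GLCM
  fc <- glcm_features(quantize_roi(matrix(4, 3, 3), G = 4))
  expect_equal(fc[["GLCM_Energy"]], 1)
  expect_equal(fc[["GLCM_Contrast"]], 0)
  expect_equal(fc[["GLCM_Dissimilarity"]], 0)
  expect_equal(fc[["GLCM_Entropy_log2"]], 0)

  # the spec's 2x2 example
  g <- matrix(c(1, 1, 1, 2), 2, 2)
  f <- glcm_features(quantized_from_grid(g, G = 2))
  expect_equal(f, oracle_glcm_features(g, G = 2), tolerance = 1e-12)

  # random larger grids with background holes
  set.seed(101)
  for (i in 1:25) {
    gr <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
    gr[sample(36, 6)] <- NA
    expect_equal(glcm_features(quantized_from_grid(gr, G = 3)),
                 oracle_glcm_features(gr, G = 3), tolerance = 1e-12)
  }
})

test_that("vertical GLCM correlation of a striped image is -1", {
  stripes <- matrix(rep(c(1, 2), 3), 6, 6)       # rows alternate 1, 2
  f <- glcm_features(quantized_from_grid(stripes, G = 2), directions = "90")
  expect_equal(f[["GLCM_Correlation"]], -1)
})

test_that("direction-averaged GLCM features are invariant under 90-degree rotation", {
  set.seed(7)
  g <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)
  rot <- t(g)[, nrow(g):1]                        # 90-degree rotation
  f1 <- glcm_features(quantized_from_grid(g, G = 4))
  f2 <- glcm_features(quantized_from_grid(rot, G = 4))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("GLZLM features agree with the flood-fill oracle", {
  # constant ROI: a single zone of size n
  n <- 9
  fz <- glzlm_features(quantize_roi(matrix(2, 3, 3), G = 4))
  expect_equal(fz[["GLZLM_LZE"]], n^2)
  expect_equal(fz[["GLZLM_ZP"]], 1 / n)
  expect_equal(fz[["GLZLM_GLNU"]], 1)

  # two hand-drawn zones on a 4x4 grid
  g <- matrix(1, 4, 4); g[1:2, 1:2] <- 2
  expect_equal(glzlm_features(quantized_from_grid(g, G = 2)),
               oracle_glzlm_features(g), tolerance = 1e-12)

  # under 8-connectivity a checkerboard is two diagonal zones of size 8
  cb <- outer(1:4, 1:4, function(r, c) 1 + (r + c) %% 2)
  fcb <- glzlm_features(quantized_from_grid(cb, G = 2))
  expect_equal(fcb[["GLZLM_LZE"]], 64)        # (8^2 + 8^2) / 2 zones
  expect_equal(fcb[["GLZLM_ZP"]], 2 / 16)
  # all-singleton zones need no same-level 8-neighbours: a 4-level tiling
  tile <- matrix(c(1, 3, 1, 3, 2, 4, 2, 4, 1, 3, 1, 3, 2, 4, 2, 4), 4, 4)
  ft <- glzlm_features(quantized_from_grid(tile, G = 4))
  expect_equal(ft[["GLZLM_SZE"]], 1)
  expect_equal(ft[["GLZLM_LZE"]], 1)
  expect_equal(ft[["GLZLM_ZP"]], 1)

  set.seed(13)
  for (i in 1:25) {
    gr <- matrix(sample(1:3, 49, replace = TRUE), 7, 7)
    gr[sample(49, 8)] <- NA
    expect_equal(glzlm_features(quantized_from_grid(gr, G = 3)),
                 oracle_glzlm_features(gr), tolerance = 1e-12)
  }
})

test_that("GLZLM mass balance holds on extracted phantom ROIs", {
  s <- tiny_fshd(n = 2, seed = 41)[[1]]
  q <- quantize_roi(s$slices[[1]]$pixels, s$masks[[1]] == 1, G = 16)
  M <- stirq:::glzlm_matrix(q)
  sizes <- matrix(seq_len(ncol(M)), nrow(M), ncol(M), byrow = TRUE)
  expect_equal(sum(M * sizes), sum(s$masks[[1]] == 1))  # pixels conserved
  f <- glzlm_features(q)
  expect_true(all(is.finite(f)))
})

test_that("GLRLM features behave on known patterns", {
  # single-level 4x4 ROI: horizontal/vertical runs of 4, diagonal 1..4..1
  g <- matrix(1, 4, 4)
  f <- glrlm_features(quantized_from_grid(g, G = 1))
  # runs per direction: rows 4x4 -> 4 runs; cols 4; diagonals 7 (both): mean 5.5
  expect_equal(f[["GLRLM_RP"]], 5.5 / 16)
  expect_equal(f[["GLRLM_LGRE"]], 1)
  expect_equal(f[["GLRLM_HGRE"]], 1)
  # a 4-level tiling with no same-level neighbours: every run has length 1
  tile <- matrix(c(1, 3, 1, 3, 2, 4, 2, 4, 1, 3, 1, 3, 2, 4, 2, 4), 4, 4)
  ft <- glrlm_features(quantized_from_grid(tile, G = 4))
  expect_equal(ft[["GLRLM_SRE"]], 1)
  expect_equal(ft[["GLRLM_LRE"]], 1)
  expect_equal(ft[["GLRLM_RP"]], 1)
})

test_that("shape features follow the slab geometry", {
  sq <- shape_features(matrix(1, 10, 10), pixel_spacing = 1, slice_thickness = 5)
  expect_equal(sq[["SHAPE_Volume_vx"]], 100)
  expect_equal(sq[["SHAPE_Volume_mL"]], 0.5)
  expect_equal(sq[["SHAPE_Surface_mm2"]], 40 * 5)
  one <- shape_features(matrix(1, 1, 1), 1, 5)
  expect_equal(one[["SHAPE_Volume_vx"]], 1)
  # 2x1 rectangle: 6 boundary edges -> 6 mm perimeter, 30 mm2 lateral surface
  rect <- matrix(0, 4, 4); rect[2:3, 2] <- 1
  r <- shape_features(rect, 1, 5)
  expect_equal(r[["SHAPE_Surface_mm2"]], 30)
  expect_error(shape_features(matrix(0, 3, 3), 1, 5),
               class = "stirq_radiomics_error")
})

test_that("extraction returns the complete 56-feature catalog per muscle", {
  cat56 <- feature_catalog()
  expect_length(cat56, 56)
  grp <- feature_catalog(grouped = TRUE)
  expect_equal(lengths(grp), c(first_order = 25, glcm = 7, glzlm = 11,
                               glrlm = 8, shape = 5))
  s <- tiny_fshd(n = 2, seed = 43)[[1]]
  f <- extract_features(s)
  expect_equal(nrow(f), 6)
  expect_equal(setdiff(names(f), "muscle"), cat56)
  expect_false(anyNA(f))
})

test_that("side averaging equals either side when the sides are identical", {
  s <- tiny_fshd(n = 2, seed = 47)[[1]]
  # copy the left ROI onto the right for muscle S (labels 1 and 2)
  for (k in seq_along(s$slices)) {
    mask <- s$masks[[k]]
    left <- which(mask == 1); right <- which(mask == 2)
    s$slices[[k]]$pixels[right] <- s$slices[[k]]$pixels[left]
  }
  f_avg <- extract_features(s)
  left_only <- roi_feature_vector_for_test(s, label = 1)
  row_s <- unlist(f_avg[f_avg$muscle == "S", feature_catalog()])
  expect_equal(unname(row_s), unname(left_only), tolerance = 1e-12)
})

test_that("feature tables have one row per subject and CSV round-trip exactly", {
  co <- tiny_fshd(n = 3, seed = 53)
  tabs <- build_feature_tables(co)
  expect_named(tabs, calf_muscles())
  for (tab in tabs) {
    expect_equal(nrow(tab), 3)
    expect_equal(ncol(tab), 1 + 56 + 2)    # id + features + FF + wT2
  }
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tabs$S, path, row.names = FALSE)
  back <- tibble::as_tibble(utils::read.csv(path))
  expect_equal(as.data.frame(back), as.data.frame(tabs$S), tolerance = 1e-12)
  expect_error(build_feature_tables(structure(list(), class = "stirq_cohort")),
               class = "stirq_radiomics_error")
})
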