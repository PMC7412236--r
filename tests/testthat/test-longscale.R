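test_that("halving gives equal pieces, sharing the middle point when odd", {
  h <- split_halves(rnorm(800))
  expect_equal(length(h$first), 400L)
  expect_equal(length(h$second), 400L)
  expect_equal(h$overlap, 0L)

  v <- rnorm(801)
  h <- split_halves(v)
  expect_equal(length(h$first), 401L)
  expect_equal(h$overlap, 1L)
  expect_equal(as.numeric(h$first)[401], as.numeric(h$second)[1])
  expect_equal(c(as.numeric(h$first),
                 as.numeric(h$second)[-seq_len(h$overlap)]), v)
})

test_that("asymmetric images carry the two halves' strict triangles", {
  set.seed(21)
  for (signed in c(FALSE, TRUE)) {
    v <- rnorm(800)
    cfg <- embed_config(2, 1)
    a <- asymmetric_rp(v, cfg, signed = signed)
    expect_true(is_asymmetric(a))
    h <- split_halves(znorm(v))
    cfg_raw <- embed_config(2, 1, normalize = FALSE)
    r1 <- rp_pixels(rp_encode(h$first, cfg_raw, signed = signed))
    r2 <- rp_pixels(rp_encode(h$second, cfg_raw, signed = signed))
    px <- rp_pixels(a)
    expect_identical(px[upper.tri(px)], r1[upper.tri(r1)])
    expect_identical(px[lower.tri(px)], r2[lower.tri(r2)])
    expect_true(all(diag(px) == 0))
  }
})

test_that("a series with identical halves collapses to the plain image", {
  set.seed(22)
  half <- rnorm(360)
  v <- c(half, half)
  cfg <- embed_config(2, 1, normalize = FALSE)
  a <- asymmetric_rp(v, cfg, signed = TRUE)
  plain <- rp_encode(half, cfg, signed = TRUE)
  expect_equal(rp_pixels(a), rp_pixels(plain))
})

test_that("the long-series threshold is strict: 701 goes asymmetric, 700 does not", {
  cfg <- embed_config(2, 1)
  expect_true(is_asymmetric(msrp_encode(rnorm(701), cfg, size = 32)))
  expect_false(is_asymmetric(msrp_encode(rnorm(700), cfg, size = 32)))
})

test_that("resizing is the identity at native size and preserves structure", {
  set.seed(23)
  img <- rp_encode(rnorm(65), embed_config(2, 1), signed = TRUE)
  expect_equal(rp_pixels(resize_image(img, 64)), rp_pixels(img))

  const <- matrix(3.5, 40, 40)
  expect_true(all(abs(resize_image(const, 16) - 3.5) < 1e-12))

  small <- rp_pixels(resize_image(img, 32))
  expect_lte(max(abs(small + t(small))), 1e-6 * max(abs(small)))

  u <- rp_encode(rnorm(65), embed_config(2, 1))
  ru <- rp_pixels(resize_image(u, 32))
  expect_equal(ru, t(ru), tolerance = 1e-12)
  expect_equal(rp_pixels(resize_image(resize_image(u, 32), 32)), ru)

  expect_error(resize_image(img, 1), "size")
  meta <- rp_meta(resize_image(img, 32))
  expect_equal(meta$resized_from, 64L)
  expect_true(is_signed(resize_image(img, 32)))
})

test_that("scale grids enumerate (m, tau, size) deterministically", {
  grid <- scale_grid(sizes = c(16L, 32L))
  v <- rnorm(100)
  imgs <- generate_scales(v, grid)
  expect_length(imgs, 4L)
  expect_equal(names(imgs), c("m2_tau1_s16", "m2_tau1_s32",
                              "m3_tau4_s16", "m3_tau4_s32"))
  expect_false(any(vapply(imgs, is_asymmetric, TRUE)))
  expect_length(attr(imgs, "failed"), 0L)

  long <- generate_scales(rnorm(720), grid)
  expect_true(all(vapply(long, is_asymmetric, TRUE)))

  single <- scale_grid(mt_pairs = list(c(2L, 1L)), sizes = 24L)
  one <- generate_scales(v, single)
  expect_length(one, 1L)
  direct <- resize_image(msrp_encode(v, embed_config(2, 1), signed = TRUE), 24)
  expect_equal(rp_pixels(one[[1]]), rp_pixels(direct))
})

test_that("infeasible grid entries are reported per entry, not fatal", {
  grid <- scale_grid(mt_pairs = list(c(2L, 1L), c(8L, 9L)), sizes = 16L)
  imgs <- generate_scales(rnorm(30), grid)
  expect_length(imgs, 1L)
  expect_match(attr(imgs, "failed"), "m=8")
})

test_that("a single-candidate grid returns without extra training", {
  ds <- generate_synthetic("trend_pair", n_per_class = 8, length = 30,
                           noise_sd = 0.1, seed = 31)
  grid <- scale_grid(mt_pairs = list(c(2L, 1L)), sizes = 16L)
  choice <- select_scale(ds, grid,
                         trainer_config("cnn", fast_cfg(epochs = 5),
                                        pilot_size = 16L))
  expect_s3_class(choice, "scale_choice")
  expect_equal(choice$n_evaluated, 1L)
  expect_equal(c(choice$m, choice$tau, choice$size), c(2L, 1L, 16L))
})

test_that("degenerate stratified splits are rejected", {
  ds <- ts_dataset(matrix(rnorm(3 * 20), 3), c("a", "a", "b"))
  grid <- scale_grid(mt_pairs = list(c(2L, 1L)), sizes = 16L)
  expect_error(select_scale(ds, grid, trainer_config("cnn", fast_cfg(5))),
               "stratification")
})
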