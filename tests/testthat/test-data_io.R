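test_that("UCR-style rows parse identically under comma and tab dialects", {
  fc <- tempfile(); ft <- tempfile()
  writeLines(c("1,0.5,0.3,0.1", "2,-0.2,0.0,0.4"), fc)
  writeLines(c("1\t0.5\t0.3\t0.1", "2\t-0.2\t0.0\t0.4"), ft)
  dc <- read_ucr(fc); dt <- read_ucr(ft)
  expect_equal(ts_length(dc), 3L)
  expect_equal(n_series(dc), 2L)
  expect_equal(dc$labels, c("1", "2"))
  expect_equal(dc$values, dt$values)
  expect_equal(dc$class_id, dt$class_id)
})

test_that("write/read round-trips values to high precision", {
  set.seed(41)
  ds <- ts_dataset(matrix(rnorm(6 * 25), 6), rep(c("1", "2", "3"), 2),
                   name = "rt")
  for (sep in c("\t", ",")) {
    f <- tempfile()
    write_ucr(ds, f, sep = sep)
    back <- read_ucr(f)
    expect_lt(max(abs(back$values - ds$values)), 1e-12)
    expect_equal(back$labels, ds$labels)
  }
})

test_that("ragged and non-numeric rows fail with located errors", {
  f <- tempfile()
  writeLines(c("1,0.5,0.3", "2,0.1"), f)
  err <- tryCatch(read_ucr(f), error = identity)
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "inconsistent length")

  writeLines(c("1,0.5,0.3", "2,oops,0.1"), f)
  err <- tryCatch(read_ucr(f), error = identity)
  expect_match(conditionMessage(err), "non-numeric")
  expect_match(conditionMessage(err), "row 2")
})

test_that("the packaged benchmark table is intact and parsed with metadata", {
  tbl <- load_table2()
  expect_equal(dim(tbl$errors), c(45L, 9L))
  expect_true(all(tbl$errors >= 0 & tbl$errors <= 1))
  expect_equal(unname(tbl$errors["Adiac(64,2,1)", "FCN"]), 0.1430)
  expect_equal(tbl$method_names[c(1, 9)], c("RP-CNN", "MS-RP-FCN"))
  scales <- attr(tbl, "scales")
  expect_equal(scales[scales$dataset == "Adiac", c("size", "m", "tau")],
               data.frame(size = 64L, m = 2L, tau = 1L), ignore_attr = TRUE)
  expect_equal(scales[scales$dataset == "CinTorso", c("size", "m", "tau")],
               data.frame(size = 128L, m = 3L, tau = 4L), ignore_attr = TRUE)
  expect_true(all(tbl$n_classes >= 2))
  expect_equal(tbl$n_classes[match("FiftyWords(48,3,4)", tbl$dataset_names)],
               50L)
})

test_that("synthetic generators are seed-reproducible", {
  for (kind in c("trend_pair", "triangle_wave", "multiclass")) {
    a <- generate_synthetic(kind, n_per_class = 5, length = 40, seed = 7)
    b <- generate_synthetic(kind, n_per_class = 5, length = 40, seed = 7)
    c <- generate_synthetic(kind, n_per_class = 5, length = 40, seed = 8)
    expect_identical(a$values, b$values)
    expect_false(identical(a$values, c$values))
  }
})

test_that("noise-free trend pairs are strictly monotone and confusable unsigned", {
  ds <- generate_synthetic("trend_pair", n_per_class = 3, length = 30,
                           noise_sd = 0, seed = 1)
  up <- ds$values[ds$labels == "up", , drop = FALSE]
  down <- ds$values[ds$labels == "down", , drop = FALSE]
  expect_true(all(apply(up, 1, function(v) all(diff(v) > 0))))
  expect_true(all(apply(down, 1, function(v) all(diff(v) < 0))))

  cfg <- embed_config(2, 1)
  u_up <- rp_pixels(rp_encode(up[1, ], cfg))
  u_down <- rp_pixels(rp_encode(down[1, ], cfg))
  expect_equal(u_up, u_down)
  s_up <- rp_pixels(rp_encode(up[1, ], cfg, signed = TRUE))
  s_down <- rp_pixels(rp_encode(down[1, ], cfg, signed = TRUE))
  expect_false(identical(sign(s_up), sign(s_down)))
  expect_equal(s_up, -s_down)
})

test_that("the multiclass and long generators cover their regimes", {
  mc <- generate_synthetic("multiclass", n_per_class = 4, length = 50, seed = 2)
  expect_equal(mc$n_classes, 4L)
  expect_equal(n_series(mc), 16L)

  lg <- generate_synthetic("long", n_per_class = 2, seed = 3)
  expect_gt(ts_length(lg), 700L)
  expect_error(generate_synthetic("long", length = 500), "> 700")

  tw <- generate_synthetic("triangle_wave", n_per_class = 2, length = 80,
                           noise_sd = 0, seed = 4)
  v <- tw$values[1, ]
  # 4 periods: the wave repeats every length/4 samples
  expect_equal(v[1:20], v[21:40], tolerance = 1e-9)
})

test_that("image stacks round-trip through their container", {
  ds <- generate_synthetic("trend_pair", n_per_class = 3, length = 24, seed = 5)
  stack <- encode_dataset(ds, embed_config(2, 1), signed = TRUE, size = 16)
  f <- tempfile(fileext = ".rds")
  save_image_stack(stack, f)
  back <- load_image_stack(f)
  expect_identical(back$images, stack$images)
  expect_identical(back$meta, stack$meta)
  expect_error(load_image_stack(tempfile()), "not found")
})
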