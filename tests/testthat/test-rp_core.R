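raw_cfg <- function(m = 2, tau = 1, ...) embed_config(m, tau, normalize = FALSE, ...)

test_that("delay embedding produces the delayed subsequences", {
  st <- embed_series(c(1, 2, 3), raw_cfg())
  expect_equal(unclass(st), matrix(c(1, 2, 2, 3), 2, 2), ignore_attr = TRUE)

  v <- rnorm(11)
  st1 <- embed_series(v, raw_cfg(m = 1, tau = 1))
  expect_equal(as.numeric(st1), v)
  expect_equal(nrow(st1), length(v))

  v9 <- rnorm(9)
  st9 <- embed_series(v9, raw_cfg(m = 3, tau = 4))
  expect_equal(nrow(st9), 1L)
  expect_equal(unclass(st9)[1, ], v9[c(1, 5, 9)])
})

test_that("state count is L - (m-1) tau and short series are rejected by name", {
  for (case in list(c(20, 2, 1), c(20, 3, 4), c(9, 3, 4), c(50, 4, 7))) {
    v <- rnorm(case[1])
    st <- embed_series(v, raw_cfg(m = case[2], tau = case[3]))
    expect_equal(nrow(st), case[1] - (case[2] - 1) * case[3])
  }
  err <- tryCatch(embed_series(rnorm(8), raw_cfg(m = 3, tau = 4)),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "infeasible")
  expect_match(conditionMessage(err), "8")
  expect_match(conditionMessage(err), "m = 3")
})

test_that("opposite monotone trends share one unsigned image but signed images differ", {
  for (normalize in c(FALSE, TRUE)) {
    cfg <- embed_config(2, 1, normalize = normalize)
    up <- rp_encode(c(1, 2, 3), cfg)
    down <- rp_encode(c(3, 2, 1), cfg)
    expect_equal(rp_pixels(up), matrix(c(0, 2, 2, 0), 2, 2))
    expect_equal(rp_pixels(up), rp_pixels(down))
    sup <- rp_encode(c(1, 2, 3), cfg, signed = TRUE)
    sdown <- rp_encode(c(3, 2, 1), cfg, signed = TRUE)
    expect_equal(rp_pixels(sup), matrix(c(0, 2, -2, 0), 2, 2))
    expect_equal(rp_pixels(sdown), -rp_pixels(sup))
  }
})

test_that("sign mask follows the sign of the state-difference sum, +1 at zero", {
  st <- embed_series(c(1, 2, 3), raw_cfg())
  expect_equal(unclass(sign_mask(st)), matrix(c(1, 1, -1, 1), 2, 2),
               ignore_attr = TRUE)

  stc <- embed_series(rep(2, 10), raw_cfg())
  expect_true(all(unclass(sign_mask(stc)) == 1))
  expect_true(all(rp_pixels(recurrence_matrix(stc)) == 0))
  expect_true(all(rp_pixels(rp_encode(rep(2, 10), raw_cfg(), signed = TRUE)) == 0))

  set.seed(4)
  st <- embed_series(rnorm(30), raw_cfg(m = 3, tau = 2))
  mask <- unclass(sign_mask(st))
  s <- rowSums(unclass(st))
  nz <- outer(s, s, "-") != 0
  expect_true(all((mask + t(mask))[nz] == 0))
  expect_true(all(mask %in% c(-1, 1)))
})

test_that("recurrence matrices match a brute-force double loop for all norms", {
  set.seed(11)
  for (rep in 1:3) {
    v <- rnorm(sample(30:60, 1))
    for (mt in list(c(2, 1), c(3, 4))) {
      for (nm in c("l1", "l2", "l2sq", "linf")) {
        cfg <- raw_cfg(m = mt[1], tau = mt[2], norm = nm)
        st <- embed_series(v, cfg)
        expect_equal(rp_pixels(recurrence_matrix(st)), brute_force_rp(st, nm),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("unsigned images are symmetric PSD-signed textures; signed images antisymmetric", {
  set.seed(5)
  for (rep in 1:4) {
    v <- rnorm(40)
    cfg <- embed_config(2, 1)
    u <- rp_pixels(rp_encode(v, cfg))
    s <- rp_pixels(rp_encode(v, cfg, signed = TRUE))
    expect_equal(u, t(u))
    expect_true(all(diag(u) == 0) && all(diag(s) == 0))
    expect_true(all(u >= 0))
    expect_equal(abs(s), u)
    mask <- unclass(sign_mask(embed_series(v, cfg)))
    nz <- (mask + t(mask)) == 0
    expect_true(all((s + t(s))[nz] == 0))
  }
})

test_that("binarized plots are the Heaviside of the distance image", {
  set.seed(6)
  v <- rnorm(40)
  cfg_raw <- raw_cfg()
  st <- embed_series(v, cfg_raw)
  d <- rp_pixels(recurrence_matrix(st))
  eps <- stats::median(d)
  cfg_bin <- raw_cfg(epsilon = eps, binarize = TRUE)
  b <- rp_pixels(recurrence_matrix(embed_series(v, cfg_bin), cfg_bin))
  expect_true(all(b %in% c(0, 1)))
  expect_equal(b, (eps - d >= 0) + 0)
})

test_that("binarization needs epsilon and refuses to be signed", {
  expect_error(embed_config(2, 1, binarize = TRUE), "epsilon")
  cfg <- raw_cfg(epsilon = 0.5, binarize = TRUE)
  st <- embed_series(rnorm(20), cfg)
  expect_error(signed_recurrence_matrix(st, cfg), "undefined for binarized")
})

test_that("the one-call encoder equals its composed parts and records provenance", {
  set.seed(8)
  v <- rnorm(50)
  cfg <- embed_config(3, 4, norm = "l2")
  st <- embed_series(v, cfg)
  expect_equal(rp_pixels(rp_encode(v, cfg, signed = TRUE)),
               unclass(sign_mask(st)) * rp_pixels(recurrence_matrix(st)),
               ignore_attr = TRUE)
  meta <- rp_meta(rp_encode(v, cfg))
  expect_equal(meta[c("m", "tau", "norm", "source_length")],
               list(m = 3L, tau = 4L, norm = "l2", source_length = 50L))
})

test_that("z-normalization is the default and behaves at constants", {
  v <- c(3, 7, 1, 9, 4)
  z <- znorm(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(znorm(rep(5, 8)), rep(0, 8))
  st <- embed_series(v, embed_config(2, 1))
  expect_equal(unclass(st)[, 1], z[1:4], ignore_attr = TRUE)
})
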