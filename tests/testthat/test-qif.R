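test_that("texture backend honours the width contract and determinism", {
  b8 <- texture_backend(8, seed = 5)
  patch <- test_image(0.5, seed = 2)$pixels[201:264, 201:264, ,
                                            drop = FALSE]
  expect_length(b8$fn(patch), 8L)
  # two instantiations with the same seed agree
  expect_identical(texture_backend(16, seed = 9)$fn(patch),
                   texture_backend(16, seed = 9)$fn(patch))
  expect_false(identical(texture_backend(16, seed = 9)$fn(patch),
                         texture_backend(16, seed = 10)$fn(patch)))
})

test_that("contrast-type base features vanish exactly on a constant patch", {
  flat <- array(0.42, dim = c(64, 64, 3))
  f <- texture_base_features(flat)
  ct <- attr(f, "contrast_type")
  expect_true(any(ct))
  expect_true(all(f[ct] == 0))
  expect_false(all(f[!ct] == 0))
})

test_that("band-pass energy matches a direct-convolution oracle", {
  set.seed(31)
  patch <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  f <- texture_base_features(patch, resize = 32L)
  luma <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  for (s in c(2L, 4L, 8L)) {
    a <- boxmean_naive(luma, s)
    b <- boxmean_naive(luma, 2L * s)
    ro <- (nrow(a) - nrow(b)) %/% 2L; co <- (ncol(a) - ncol(b)) %/% 2L
    bp <- a[ro + seq_len(nrow(b)), co + seq_len(ncol(b))] - b
    expect_equal(unname(f[paste0("bandpass_e_s", s)]), mean(bp^2),
                 tolerance = 1e-10)
  }
})

test_that("high-severity patches carry more band-pass energy than low", {
  hi <- test_image(0.9, seed = 7, px = 512)
  lo <- test_image(0.1, seed = 7, px = 512)
  e <- function(img) {
    ps <- sample_patches(img, n = 20, seed = 3)
    mean(vapply(ps$patches, function(p) {
      f <- texture_base_features(p$pixels)
      sum(f[grep("bandpass_e", names(f))])
    }, numeric(1)))
  }
  expect_gt(e(hi), e(lo))
})

test_that("extraction yields one row per patch, in order, finite", {
  img <- test_image(0.5, seed = 13, px = 512)
  ps <- sample_patches(img, n = 25, seed = 2, biopsy_id = "bq")
  bk <- texture_backend(32, seed = 1)
  q <- extract_features(ps, bk)
  expect_identical(dim(q$values), c(25L, 32L))
  expect_true(all(is.finite(q$values)))
  expect_identical(q$patch_ids, 1:25)
  expect_identical(q$biopsy_id, "bq")

  # patch-order permutation permutes rows identically (no hidden state)
  perm <- c(5:1, 6:25)
  ps2 <- ps
  ps2$patches <- ps$patches[perm]
  class(ps2) <- "patch_set"
  q2 <- extract_features(ps2, bk)
  expect_equal(unname(q2$values), unname(q$values[perm, ]))

  # identical patch duplicated -> identical rows
  ps3 <- ps
  ps3$patches <- ps$patches[c(1, 1)]
  class(ps3) <- "patch_set"
  q3 <- extract_features(ps3, bk)
  expect_identical(q3$values[1, ], q3$values[2, ])
})

test_that("texture features separate severity with a logistic readout", {
  imgs <- c(lapply(1:2, function(i)
    test_image(0.15 + 0.05 * i, seed = 40 + i, px = 512)),
    lapply(1:2, function(i)
      test_image(0.75 + 0.05 * i, seed = 50 + i, px = 512)))
  labs <- c(0, 0, 1, 1)
  n_base <- length(texture_base_features(array(0.5, dim = c(32, 32, 3))))
  feats <- list(); y <- c()
  for (i in seq_along(imgs)) {
    ps <- sample_patches(imgs[[i]], n = 50, seed = i)
    feats[[i]] <- t(vapply(ps$patches, function(p)
      as.numeric(texture_base_features(p$pixels)), numeric(n_base)))
    y <- c(y, rep(labs[i], 50))
  }
  X <- do.call(rbind, feats)
  keep <- apply(X, 2, sd) > 0
  # logistic readout on the leading principal components (the base bank
  # has collinear columns, so a full-rank design is used for the readout)
  pcs <- prcomp(scale(X[, keep]), rank. = 5)$x
  set.seed(77)
  fold <- sample(rep_len(1:5, nrow(pcs)))
  acc <- mean(unlist(lapply(1:5, function(f) {
    d <- data.frame(y = y[fold != f], pcs[fold != f, ])
    fit <- suppressWarnings(glm(y ~ ., data = d, family = binomial()))
    pred <- predict(fit, newdata = data.frame(pcs[fold == f, ]))
    (pred > 0) == (y[fold == f] == 1)
  })))
  expect_gte(acc, 0.9)
})

test_that("the ONNX backend is offline-safe and runner-pluggable", {
  expect_error(onnx_cnn_backend("/no/such/model.onnx", layer = "fc7"),
               "not found")
  path <- withr::local_tempfile(fileext = ".onnx")
  writeLines("synthetic placeholder, not a real model", path)
  bk <- onnx_cnn_backend(path, layer = "fc7")
  expect_identical(bk$n_features, 4096L)
  expect_error(bk$fn(array(0, dim = c(8, 8, 3))), "runner")

  mock_runner <- function(pixels, model_path, layer)
    rep(mean(pixels), 4096)
  bk2 <- onnx_cnn_backend(path, layer = "fc7", runner = mock_runner)
  patch <- array(0.25, dim = c(8, 8, 3))
  expect_identical(bk2$fn(patch), bk2$fn(patch))
  expect_length(bk2$fn(patch), 4096L)
})
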