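test_that("the augmentation catalogue lists exactly the 30 stated variants", {
  cat30 <- augmentation_catalogue()
  expect_equal(nrow(cat30), 30)
  expect_equal(sum(duplicated(cat30)), 0)
  tab <- table(cat30$name)
  expect_equal(unname(tab[c("sharpen", "emboss", "gaussian_blur", "rotate",
                            "edge", "skew", "flip")]), rep(4L, 7),
               ignore_attr = TRUE)
  expect_equal(unname(tab["shear"]), 2L, ignore_attr = TRUE)
  expect_setequal(cat30$parameter[cat30$name == "rotate"],
                  c("45", "90", "135", "180"))
  expect_setequal(cat30$parameter[cat30$name == "sharpen"],
                  c("0.5", "1", "1.5", "2"))
  expect_setequal(cat30$parameter[cat30$name == "skew"],
                  c("left", "right", "forward", "backward"))
})

test_that("flips and 180-degree rotation are involutions; 90 has period 4", {
  set.seed(1)
  img <- image_record(matrix(runif(48 * 40), 48, 40), id = "t")
  for (p in c("left", "top")) {
    twice <- apply_augmentation(apply_augmentation(img, "flip", p), "flip", p)
    expect_identical(twice$pixels, img$pixels)
  }
  r2 <- apply_augmentation(apply_augmentation(img, "rotate", "180"),
                           "rotate", "180")
  expect_identical(r2$pixels, img$pixels)

  sq <- image_record(matrix(runif(32 * 32), 32, 32))
  r <- sq
  for (i in 1:4) r <- apply_augmentation(r, "rotate", "90")
  expect_identical(r$pixels, sq$pixels)
})

test_that("every augmentation preserves shape and the [0,1] range", {
  set.seed(2)
  img <- image_record(matrix(runif(40 * 40), 40, 40), id = "s")
  rgb <- image_record(array(runif(32 * 32 * 3), c(32, 32, 3)), id = "rgb")
  cat30 <- augmentation_catalogue()
  for (i in seq_len(nrow(cat30))) {
    out <- apply_augmentation(img, cat30$name[i], cat30$parameter[i])
    expect_identical(dim(out$pixels), dim(img$pixels))
    expect_true(all(out$pixels >= 0 & out$pixels <= 1))
    expect_equal(length(out$provenance), 1)
  }
  out3 <- apply_augmentation(rgb, "rotate", "45")
  expect_identical(dim(out3$pixels), dim(rgb$pixels))
  expect_error(apply_augmentation(img, "solarize", "1"), "unknown")
})

test_that("gaussian blur never increases total variation", {
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(runif(30 * 30), 30, 30)
    bl <- apply_augmentation(image_record(m), "gaussian_blur", "1")
    expect_lte(total_variation(bl$pixels), total_variation(m))
  }
})

test_that("bilinear downsizing averages aligned 2x2 blocks", {
  # hand-computed oracle: with pixel-center alignment, each output pixel of a
  # 2x downsample sits at the corner of a 2x2 source block
  set.seed(4)
  m <- matrix(runif(64), 8, 8)
  dn <- bilinear_resize(m, c(4, 4))
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(dn, oracle, tolerance = 1e-12)
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_true(all(bilinear_resize(cb, c(4, 4)) == 0.5))
})

test_that("preprocessing resizes, filters and stays constant on constants", {
  const <- image_record(matrix(0.42, 64, 64), id = "c")
  out <- preprocess_image(const, out_size = c(32, 32),
                          clahe = list(clip = 2, tiles = c(4, 4)))
  expect_equal(dim(out$pixels), c(32, 32))
  expect_equal(sd(out$pixels), 0)
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))

  # identity configuration
  set.seed(5)
  img <- image_record(matrix(runif(48 * 48), 48, 48))
  id <- preprocess_image(img, out_size = c(48, 48), median_k = 1, clahe = NULL)
  expect_equal(id$pixels, img$pixels, tolerance = 1e-12)

  rgb <- image_record(array(runif(64 * 64 * 3), c(64, 64, 3)))
  outr <- preprocess_image(rgb, out_size = c(32, 32))
  expect_equal(dim(outr$pixels), c(32, 32, 3))
  expect_error(preprocess_image(img, c(32, 32), median_k = 2), "odd")
})

test_that("sevenfold augmentation multiplies every class by exactly seven", {
  set.seed(6)
  recs <- c(
    lapply(1:4, function(i)
      image_record(matrix(runif(64), 8, 8), label = "DR", id = paste0("dr", i))),
    lapply(1:3, function(i)
      image_record(matrix(runif(64), 8, 8), label = "DME", id = paste0("dme", i))))
  aug <- sevenfold_augment(recs, seed = 11)
  expect_length(aug, 7 * 7)
  labs <- vapply(aug, function(r) r$label, character(1))
  expect_equal(unname(table(labs)[c("DR", "DME")]), c(28L, 21L),
               ignore_attr = TRUE)
  # determinism: same seed gives byte-identical outputs
  aug2 <- sevenfold_augment(recs, seed = 11)
  expect_identical(aug, aug2)
  # each source contributes itself once, ops distinct per source
  plan <- sevenfold_plan(data.frame(id = c("a", "b"), label = "x"), seed = 1)
  expect_equal(nrow(plan), 14)
  expect_equal(sum(plan$op == "original"), 2)
  for (src in c("a", "b")) {
    ops <- plan[plan$id == src & plan$op != "original", c("op", "parameter")]
    expect_equal(nrow(unique(ops)), 6)
  }
  expect_error(sevenfold_augment(list()), "empty dataset")
})

test_that("split accounting conserves counts and honours overrides", {
  expect_equal(split_counts(c(a = 10))$train, 7)
  expect_equal(split_counts(c(a = 10))$test, 3)
  sp <- split_counts(c(DR = 11599, DME = 1267, Glaucoma = 1519),
                     test_overrides = c(DR = 3479, DME = 380, Glaucoma = 456))
  expect_equal(sp$train, c(8120, 887, 1063))
  expect_equal(sum(sp$train), 10070)
  expect_equal(sp$train + sp$test, c(11599, 1267, 1519))
  set.seed(7)
  cnt <- c(x = sample(50:500, 1), y = sample(50:500, 1))
  sp2 <- split_counts(cnt, train_frac = 0.6)
  expect_equal(sp2$train + sp2$test, unname(cnt))
  expect_error(split_counts(c(a = 5), test_overrides = c(a = 6)), "exceeds")
})

test_that("images and masks round-trip through PNG", {
  set.seed(8)
  img <- matrix(runif(32 * 32), 32, 32)
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_lt(max(abs(back - img)), 1 / 255)  # 8-bit quantization only
  mask <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  write_mask_png(mask, f)
  expect_equal(read_mask_png(f), mask, ignore_attr = TRUE)
  unlink(f)
})
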