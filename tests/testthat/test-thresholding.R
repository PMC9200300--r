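test_that("binarization is strict at the threshold", {
  x <- matrix(c(100L, 200L), 1, 2)
  expect_equal(as.vector(binarize(x, 150)), c(0L, 1L))
  expect_equal(as.vector(binarize(matrix(150L, 1, 1), 150)), 0L)
  expect_true(all(binarize(matrix(sample(0:255, 100, TRUE), 10, 10), 255) == 0L))
  expect_error(binarize(x, 300), "\\[0, 255\\]")
})

test_that("binarization is monotone in the threshold", {
  set.seed(21)
  x <- matrix(sample(0:255, 400, TRUE), 20, 20)
  for (pair in list(c(10, 80), c(100, 101), c(0, 254))) {
    lo <- binarize(x, pair[1]); hi <- binarize(x, pair[2])
    expect_true(all(hi <= lo)) # foreground(T2) subset of foreground(T1)
    expect_equal(sum(lo), sum(x > pair[1]))
  }
})

test_that("Renyi entropy matches closed forms and the Shannon limit", {
  u <- rep(1 / 256, 256)
  expect_equal(renyi_entropy(u, 0.5), log(256))
  expect_equal(renyi_entropy(u, 2), log(256))
  expect_equal(shannon_entropy(u), log(256))

  point <- c(1, rep(0, 255))
  expect_equal(renyi_entropy(point, 2), 0)
  expect_equal(shannon_entropy(point), 0)
  expect_equal(renyi_entropy(c(0.5, 0.5), 2), log(2))

  set.seed(4)
  for (i in 1:10) {
    q <- rexp(256); q <- q / sum(q)
    expect_equal(renyi_entropy(q, 1 + 1e-6), shannon_entropy(q),
                 tolerance = 1e-4)
    expect_equal(renyi_entropy(q, 1 - 1e-6), shannon_entropy(q),
                 tolerance = 1e-4)
  }
  expect_error(renyi_entropy(u, 1), "shannon")
  expect_error(renyi_entropy(u, -2), "positive")
})

test_that("max-entropy threshold equals exhaustive search on random histograms", {
  set.seed(7)
  for (i in 1:100) {
    counts <- random_histogram()
    q <- counts / sum(counts)
    expect_identical(max_entropy_threshold(counts), brute_force_kapur(q))
  }
})

test_that("max-entropy threshold separates well-separated blocks", {
  counts <- integer(256)
  counts[1:50] <- 40L    # bins 0..49
  counts[201:250] <- 40L # bins 200..249
  T <- max_entropy_threshold(counts)
  expect_gte(T, 49); expect_lte(T, 199)
  expect_error(max_entropy_threshold(c(10L, integer(255))), "degenerate")
})

test_that("Renyi threshold weights collapse correctly and stay bracketed", {
  # two tight blocks: all three alpha candidates coincide in the gap
  counts <- integer(256); counts[11:20] <- 100L; counts[231:240] <- 100L
  cands <- c(mpquant:::entropy_argmax(counts, 0.5),
             mpquant:::entropy_argmax(counts, 1),
             mpquant:::entropy_argmax(counts, 2))
  T <- renyi_threshold(counts)
  if (length(unique(cands)) == 1L) expect_equal(T, cands[1])
  expect_gte(T, min(cands)); expect_lte(T, max(cands))

  set.seed(12)
  for (i in 1:20) {
    counts <- random_histogram(min_bins = 5L)
    cands <- c(mpquant:::entropy_argmax(counts, 0.5),
               mpquant:::entropy_argmax(counts, 1),
               mpquant:::entropy_argmax(counts, 2))
    T <- renyi_threshold(counts)
    expect_gte(T, min(cands)); expect_lte(T, max(cands))
  }
})

test_that("alpha = 1 Renyi candidate is the Kapur threshold", {
  set.seed(9)
  for (i in 1:20) {
    counts <- random_histogram()
    expect_identical(mpquant:::entropy_argmax(counts, 1),
                     max_entropy_threshold(counts))
  }
})

test_that("despeckle equals the brute-force 3x3 median", {
  const <- matrix(55L, 6, 6)
  expect_identical(despeckle(const), const)
  speck <- matrix(0L, 7, 7); speck[4, 4] <- 255L
  expect_true(all(despeckle(speck) == 0L))
  set.seed(14)
  x <- matrix(sample(0:255, 15 * 11, TRUE), 15, 11)
  expect_identical(despeckle(x), brute_force_median3(x))
})

test_that("outlier removal drops components below the area cutoff", {
  m <- matrix(0L, 12, 12)
  m[2, 2] <- 1L               # 1 px speck
  m[5:8, 5:8] <- 1L           # 16 px blob
  m[11, 10:12] <- 1L          # 3 px strip
  out <- remove_outliers(mp_mask(m), min_size = 4)
  expect_equal(flood_fill_count(out), 1L)
  expect_equal(sum(out), 16L)
  blob <- mp_mask(matrix(1L, 10, 10))
  expect_identical(unclass(remove_outliers(blob, 4)), unclass(blob))
  expect_equal(sum(remove_outliers(mp_mask(matrix(c(1L, rep(0L, 24)), 5, 5)),
                                   min_size = 4)), 0L)
})

test_that("preset threshold models follow their published recipes", {
  spec <- threshold_model("mp_vat")
  expect_equal(spec$channel, "gray"); expect_equal(spec$rule, "max_entropy")
  spec2 <- threshold_model("mp_vat2")
  expect_equal(spec2$channel, "red"); expect_equal(spec2$rule, "renyi")
  spec3 <- threshold_model("c_vat")
  expect_equal(spec3$fixed, 222)
  expect_true(spec3$despeckle && spec3$outliers)
  expect_error(threshold_model("custom"), "fixed_value")
})

test_that("fixed-threshold pipeline is strict above 222 and empty when dark", {
  # uniform image exactly at the fixed threshold -> empty mask
  img <- mp_image(array(222L, c(8, 8, 3)))
  expect_equal(sum(run_tr_model(img, "c_vat")), 0L)
  dark <- mp_image(array(5L, c(8, 8, 3)))
  expect_equal(sum(run_tr_model(dark, threshold_model("custom",
                                                      fixed_value = 100))), 0L)
  # a sufficiently large bright block survives despeckle + outlier removal
  px <- array(0L, c(16, 16, 3)); px[4:9, 4:9, ] <- 255L
  expect_gt(sum(run_tr_model(mp_image(px), "c_vat")), 0L)
})

test_that("channel choice matters: red-only MP is invisible to no model", {
  px <- array(10L, c(16, 16, 3))
  px[5:10, 5:10, 1] <- 250L # MP signal only in red
  img <- mp_image(px)
  expect_gt(sum(run_tr_model(img, "mp_vat2")), 0L)
  expect_gt(sum(run_tr_model(img, "mp_vat")), 0L) # gray sees 0.299 * 250
})

test_that("mp_vat recovers the exact object count on quiet scenes", {
  for (s in 1:5) {
    sc <- disk_scene(n = 5, seed = s, canvas = c(128, 128),
                     background_level = 20, background_noise_sd = 0.5)
    mask <- run_tr_model(sc$image, "mp_vat")
    expect_equal(quantify_mask(mask)$mp_count, 5L)
  }
})
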