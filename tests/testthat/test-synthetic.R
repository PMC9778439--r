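test_that("scene generation honours its spec and ground truth", {
  # empty scene: background + strip only
  sc0 <- generate_scene(scene_spec(n_seeds = 0, rng_seed = 1))
  expect_equal(nrow(sc0$truth$circles), 0)
  gray0 <- rgb_to_gray(sc0$image)
  below <- gray0[(sc0$truth$strip_height_px + 1):nrow(gray0), ]
  expect_lt(mean(below), 40)            # nothing but dark surface below strip

  sc <- generate_scene(scene_spec(n_seeds = 10, radius_range_px = c(40, 60),
                                  rng_seed = 7))
  expect_equal(nrow(sc$truth$circles), 10)
  expect_true(all(sc$truth$circles$radius_px >= 40 &
                    sc$truth$circles$radius_px <= 60))
  expect_length(sc$truth$patch_labels, 10)
  expect_equal(sc$truth$px_per_mm, 20)
})

test_that("rendered grid pitch matches px_per_mm (autocorrelation peak)", {
  sc <- generate_scene(scene_spec(n_seeds = 0, px_per_mm = 20, rng_seed = 3))
  gray <- rgb_to_gray(sc$image)
  row <- gray[sc$truth$strip_height_px %/% 2 + 2, ] - mean(gray[2, ])
  row <- row - mean(row)
  ac <- vapply(2:40, function(lag)
    sum(row[1:(length(row) - lag)] * row[(lag + 1):length(row)]), 0)
  expect_equal(which.max(ac) + 1, 20)
})

test_that("scene generation is bit-identical under a fixed seed and fails at impossible density", {
  s <- scene_spec(n_seeds = 5, rng_seed = 42)
  expect_identical(generate_scene(s), generate_scene(s))
  dense <- scene_spec(image_size = c(200, 200), n_seeds = 10,
                      radius_range_px = c(50, 60), rng_seed = 1)
  expect_error(generate_scene(dense), "placement failure")
})

test_that("scene_spec enforces its invariants", {
  expect_error(scene_spec(radius_range_px = c(3, 10)))
  expect_error(scene_spec(px_per_mm = 1.5))
  expect_error(scene_spec(background_level = 90))
})

test_that("patch generator satisfies the class definitions", {
  # absent: no significant region under region analysis
  pa <- generate_patch("absent", 96, rng_seed = 4)
  expect_equal(region_analysis(pa)$n_significant, 0)

  # complex: pattern coverage forced above one half by construction,
  # dotted: well below -- the separation invariant, across seeds
  for (s in 1:5) {
    pc <- generate_patch("complex", 96, rng_seed = s)
    pd <- generate_patch("dotted", 96, rng_seed = s)
    cov <- function(p) {
      fg <- attr(p, "true_fg")
      sum(fg & p$mask) / sum(p$mask)
    }
    expect_gt(cov(pc), 0.5)
    expect_lt(cov(pd), 0.5)
  }

  expect_identical(texture_group("marbled"), "dense")
  expect_error(generate_patch("striped", 96), "'arg' should be one of")
  expect_error(generate_patch("absent", 16))
  expect_identical(generate_patch("spotted", 64, rng_seed = 2),
                   generate_patch("spotted", 64, rng_seed = 2))
})

test_that("every rendered seed is bright enough for the radiometric check", {
  for (seed in 1:3) {
    spec <- scene_spec(n_seeds = 6, rng_seed = seed)
    sc <- generate_scene(spec)
    gray <- rgb_to_gray(sc$image)
    xs <- matrix(rep(0:(ncol(gray) - 1), each = nrow(gray)), nrow(gray))
    ys <- matrix(rep(0:(nrow(gray) - 1), times = ncol(gray)), nrow(gray))
    for (i in seq_len(nrow(sc$truth$circles))) {
      cr <- sc$truth$circles[i, ]
      inside <- (xs - cr$x)^2 + (ys - cr$y)^2 <= cr$radius_px^2
      expect_gte(mean(gray[inside]), spec$background_level + 60)
    }
  }
})

test_that("pattern class vocabulary and group mapping are fixed", {
  expect_setequal(pattern_classes(),
                  c("absent", "dotted", "spotted", "marbled", "complex"))
  expect_identical(texture_group(c("absent", "spotted")), c("rare", "rare"))
  expect_identical(texture_group(c("dotted", "complex")), c("sparse", "sparse"))
  expect_error(texture_group("plaid"), "unknown pattern class")
})
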