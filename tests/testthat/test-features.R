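flat_patch <- function(level = 120, size = 64) {
  img <- array(level, c(size, size, 3))
  ctr <- (size - 1) / 2
  d <- sqrt(outer((0:(size - 1) - ctr)^2, (0:(size - 1) - ctr)^2,
                  function(a, b) a + b))
  seed_patch(img, t(d) <= size / 2 - 2)
}

test_that("LBP signature: length, normalization, flat-region code", {
  p <- flat_patch()
  d <- lbp_descriptor(p)
  expect_length(d, 18)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(d[[17]], 1)   # all-neighbours-equal maps to the 16-ones bin

  q <- generate_patch("marbled", 96, rng_seed = 3)
  dq <- lbp_descriptor(q)
  expect_length(dq, 18)
  expect_equal(sum(dq), 1, tolerance = 1e-9)
  expect_true(all(dq >= 0) && all(is.finite(dq)))

  tiny <- seed_patch(array(100, c(8, 8, 3)),
                     matrix(TRUE, 8, 8))
  expect_error(lbp_descriptor(tiny), "insufficient region")
})

test_that("LBP is rotation-invariant within tolerance", {
  p <- generate_patch("spotted", 96, rng_seed = 5)
  rot90 <- function(a) {
    out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(a[, , k])[, dim(a)[1]:1]
    out
  }
  pr <- seed_patch(rot90(p$pixels), t(p$mask)[, nrow(p$mask):1])
  expect_lt(sum(abs(lbp_descriptor(p) - lbp_descriptor(pr))), 0.05)
})

test_that("colour histogram: block structure and normalization", {
  img <- array(0, c(64, 64, 3)); img[, , 1] <- 255
  p <- seed_patch(img, matrix(TRUE, 64, 64))
  h <- color_histogram(p)
  expect_length(h, 180)
  expect_equal(h[[60]], 1)                 # R mass in the last bin
  expect_equal(h[[61]], 1)                 # G mass in the first bin
  expect_equal(h[[121]], 1)                # B mass in the first bin
  expect_equal(unname(vapply(0:2, function(k) sum(h[k * 60 + 1:60]), 0)),
               c(1, 1, 1))
})

test_that("uniform-random channels give flat histograms (chi-square)", {
  img <- withr::with_seed(10, array(runif(3 * 100 * 100, 0, 255.999),
                                    c(100, 100, 3)))
  p <- seed_patch(img, matrix(TRUE, 100, 100))
  h <- color_histogram(p)
  # joint test across the three 60-bin blocks (each block sums to one, so
  # the pooled expectation is uniform over all 180 bins)
  counts <- h * 1e4
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("the combined descriptor has 198 items and is deterministic", {
  p <- generate_patch("dotted", 96, rng_seed = 2)
  v <- feature_vector(p)
  expect_length(v, 198)
  expect_identical(names(v)[c(1, 198)], c("f000", "f197"))
  expect_identical(v, feature_vector(generate_patch("dotted", 96, rng_seed = 2)))
})

test_that("feature extraction never reads outside the mask", {
  p <- generate_patch("spotted", 64, rng_seed = 6)
  v1 <- feature_vector(p)
  tampered <- p
  for (k in 1:3) {
    ch <- tampered$pixels[, , k]
    ch[!p$mask] <- 0
    tampered$pixels[, , k] <- ch
  }
  expect_identical(v1, feature_vector(tampered))
})

test_that("classes separate in feature space (inter > intra distance)", {
  n <- 30
  fa <- feature_matrix(lapply(1:n, function(i)
    generate_patch("absent", 80, rng_seed = i)))
  fm <- feature_matrix(lapply(1:n, function(i)
    generate_patch("marbled", 80, rng_seed = i)))
  l2 <- function(a, b) sqrt(rowSums((a - b)^2))
  intra <- mean(c(l2(fa[1:(n / 2), ], fa[(n / 2 + 1):n, ]),
                  l2(fm[1:(n / 2), ], fm[(n / 2 + 1):n, ])))
  inter <- mean(l2(fa, fm))
  expect_gt(inter, intra)
})
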