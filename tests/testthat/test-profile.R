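test_that("smoothing preserves constants and is the identity for tiny bandwidths", {
  p <- tiling_profile(tibble::tibble(chrom = "c", pos = seq(0, 5000, 50),
                                     value = 2.7))
  s <- smooth_profile(p, 500)
  expect_equal(s$value, rep(2.7, nrow(p)), tolerance = 1e-12)
  expect_true(profile_meta(s)$smoothed)
  expect_equal(profile_meta(s)$bandwidth, 500)

  set.seed(1)
  q <- tiling_profile(tibble::tibble(chrom = "c", pos = seq(0, 5000, 50),
                                     value = runif(101, 0.5, 3)))
  tiny <- smooth_profile(q, 1)  # bandwidth far below probe spacing
  expect_equal(tiny$value, q$value, tolerance = 1e-9)
})

test_that("smoothed values match a direct Gaussian convolution oracle", {
  sd <- 0.25 * 500 / qnorm(0.75)
  oracle <- function(pos, y) {
    vapply(seq_along(pos), function(i) {
      w <- dnorm(pos, pos[i], sd)
      w[w < dnorm(0, 0, sd) * exp(-0.5 * 8^2)] <- 0  # same 8-sd support
      sum(w * y) / sum(w)
    }, numeric(1))
  }
  set.seed(2)
  # regular grid with one elevated probe among flat background
  pos_r <- seq(0, 6000, 50)
  y_r <- rep(1, length(pos_r)); y_r[61] <- 5
  p_r <- tiling_profile(tibble::tibble(chrom = "c", pos = pos_r, value = y_r))
  expect_equal(smooth_profile(p_r, 500)$value, oracle(pos_r, y_r),
               tolerance = 1e-9)

  # irregular grid
  pos_i <- sort(sample(0:8000, 120))
  y_i <- runif(120, 0.5, 4)
  p_i <- tiling_profile(tibble::tibble(chrom = "c", pos = pos_i, value = y_i))
  expect_equal(smooth_profile(p_i, 500)$value, oracle(pos_i, y_i),
               tolerance = 1e-9)
})

test_that("smoothing is linear and stays within the input range", {
  set.seed(3)
  pos <- seq(0, 10000, 50)
  f <- runif(length(pos), 0.5, 2)
  g <- runif(length(pos), 1, 3)
  mk <- function(v) tiling_profile(tibble::tibble(chrom = "c", pos = pos,
                                                  value = v))
  a <- 0.7; b <- 1.9
  lhs <- smooth_profile(mk(a * f + b * g), 500)$value
  rhs <- a * smooth_profile(mk(f), 500)$value +
    b * smooth_profile(mk(g), 500)$value
  expect_equal(lhs, rhs, tolerance = 1e-9)

  s <- smooth_profile(mk(f), 500)$value
  expect_true(all(s >= min(f) - 1e-12 & s <= max(f) + 1e-12))
})

test_that("the bandwidth convention matches stats::ksmooth", {
  set.seed(4)
  pos <- seq(0, 20000, 50)
  y <- exp(rnorm(length(pos), 0, 0.3))
  p <- tiling_profile(tibble::tibble(chrom = "c", pos = pos, value = y))
  ours <- smooth_profile(p, 500)$value
  ks <- stats::ksmooth(pos, y, kernel = "normal", bandwidth = 500,
                       x.points = pos)$y
  # ksmooth truncates its kernel earlier, hence the loose tolerance
  expect_equal(ours, ks, tolerance = 2e-3)
})

test_that("smoothing respects chromosome boundaries and re-smoothing is guarded", {
  p <- tiling_profile(tibble::tibble(
    chrom = rep(c("a", "b"), each = 21),
    pos = rep(seq(0, 1000, 50), 2),
    value = c(rep(1, 21), rep(3, 21))))
  s <- smooth_profile(p, 500)
  expect_equal(s$value, c(rep(1, 21), rep(3, 21)), tolerance = 1e-12)
  expect_error(smooth_profile(s, 500), "already smoothed")
  expect_silent(smooth_profile(s, 250, allow_resmooth = TRUE))
})

test_that("decile normalization rescales by the interpolated first decile", {
  mk <- function(v) tiling_profile(tibble::tibble(
    chrom = "c", pos = seq(0, by = 50, length.out = length(v)), value = v))

  np <- decile_normalize(mk(rep(4, 20)))
  expect_equal(np$value, rep(1, 20))
  expect_equal(profile_meta(np)$norm_factor, 0.25)

  # linear-interpolation quantile: h = 0.1*(n-1)+1 = 10.9 for 1..100
  n100 <- decile_normalize(mk(1:100))
  expect_equal(profile_meta(n100)$norm_factor, 1 / 10.9)
  expect_equal(quantile(n100$value, 0.1, names = FALSE), 1, tolerance = 1e-9)

  # idempotence: a second pass finds factor 1
  again <- decile_normalize(n100)
  expect_equal(profile_meta(again)$norm_factor, 1, tolerance = 1e-9)

  expect_error(decile_normalize(mk(1:5)), "at least 10")
})

test_that("ratio profiles divide elementwise with a denominator floor", {
  pos <- seq(0, 450, 50)
  a <- flagged_profile("c", pos, c(1, 2, 3, 1, 1, 1, 4, 2, 1, 1), "8A")
  expect_equal(ratio_profile(a, a)$value, rep(1, 10))

  num <- flagged_profile("c", pos, rep(1, 10), "num")
  den <- flagged_profile("c", pos, c(0.1, rep(1, 9)), "den")
  r <- ratio_profile(num, den, floor = 0.25)
  expect_equal(r$value[1], 4)        # denominator floored at 0.25
  expect_equal(attr(r, "label"), "num/den")

  set.seed(5)
  x <- flagged_profile("c", pos, runif(10, 0.1, 3), "x")
  y <- flagged_profile("c", pos, runif(10, 0.1, 3), "y")
  manual <- vapply(1:10, function(i) x$value[i] / max(y$value[i], 0.25),
                   numeric(1))
  expect_equal(ratio_profile(x, y)$value, manual)

  z <- flagged_profile("c", pos + 25, runif(10, 0.5, 2), "z")
  expect_error(ratio_profile(x, z), "identical probe grids")
  raw <- tiling_profile(tibble::tibble(chrom = "c", pos = pos, value = 1:10))
  expect_error(ratio_profile(raw, y), "smoothed")
})

test_that("profile inversion is the reciprocal with the same floor", {
  pos <- seq(0, 200, 50)
  ones <- flagged_profile("c", pos, rep(1, 5))
  expect_equal(invert_profile(ones)$value, rep(1, 5))
  four <- flagged_profile("c", pos, rep(4, 5))
  expect_equal(invert_profile(four)$value, rep(0.25, 5))

  set.seed(6)
  v <- runif(5, 0.3, 3)  # in the floor-free range both ways
  p <- flagged_profile("c", pos, v)
  expect_equal(invert_profile(invert_profile(p))$value, v, tolerance = 1e-12)
})

test_that("bedGraph files round-trip with their metadata sidecar", {
  g <- one_chrom_genome(2000)
  b <- blocks_tbl("chr1", 500L, 700L, heat = 3)
  p <- simulate_profile(g, b, allele = "WT", config = allele_config(seed = 2))
  p <- decile_normalize(p)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(p, path)
  back <- read_bedgraph(path, g)
  expect_equal(back$value, p$value)
  expect_equal(back$pos, p$pos)
  expect_equal(profile_meta(back)$norm_factor, profile_meta(p)$norm_factor)
  expect_true(profile_meta(back)$normalized)
  expect_equal(attr(back, "label"), "WT")
})

test_that("malformed bedGraph input is rejected with its line number", {
  g <- one_chrom_genome(1000)
  w <- function(lines) {
    f <- tempfile(fileext = ".bedGraph"); writeLines(lines, f); f
  }
  one <- read_bedgraph(w("chr1\t0\t50\t1.5"), g)
  expect_equal(one$pos, 0)
  expect_equal(one$value, 1.5)

  expect_error(read_bedgraph(w(c("chr1\t0\t50\t1", "chr1\t40\t90\t1")), g),
               "line 2")
  expect_error(read_bedgraph(w(c("chr1\t100\t150\t1", "chr1\t0\t50\t1")), g),
               "line 2")
  expect_error(read_bedgraph(w("chr1\t980\t1030\t1"), g), "past chromosome end")
  expect_error(read_bedgraph(w("chrX\t0\t50\t1"), g), "chrX")
})
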