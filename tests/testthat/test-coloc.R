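test_that("nearest-edge distances follow the inside-still-counts rule", {
  b <- blocks_tbl("c", 1000L, 1180L)
  at <- function(pos, ...) {
    distance_to_nearest_block(tibble::tibble(chrom = "c", pos = pos), b,
                              ...)$distance
  }
  expect_equal(at(1000), 0)          # at the start edge
  expect_equal(at(1179), 0)          # at the end edge (end - 1)
  expect_equal(at(1090), 89)         # block center: nearer edge, not zero
  expect_equal(at(1500), 321)        # outside: distance to end - 1
  expect_equal(at(1090, inside_is_zero = TRUE), 0)

  # no blocks on the chromosome
  far <- distance_to_nearest_block(tibble::tibble(chrom = "d", pos = 5), b)
  expect_equal(far$distance, Inf)
})

test_that("distances agree with the brute-force pairwise oracle", {
  set.seed(8)
  b <- blocks_tbl(rep(c("a", "b"), c(3, 2)),
                  start = c(100L, 2000L, 7000L, 500L, 4000L),
                  end = c(400L, 2300L, 7100L, 900L, 4800L))
  peaks <- tibble::tibble(chrom = sample(c("a", "b"), 10, TRUE),
                          pos = sample(0:8000, 10))
  for (iz in c(FALSE, TRUE)) {
    got <- distance_to_nearest_block(peaks, b, inside_is_zero = iz)$distance
    expect_equal(got, oracle_edge_distance(peaks$chrom, peaks$pos, b, iz))
  }
})

test_that("cumulative curves count distances correctly and monotonically", {
  b <- blocks_tbl("c", c(1000L, 5000L), c(1200L, 5400L))
  edges <- tibble::tibble(chrom = "c", pos = c(1000, 5399))
  expect_equal(cumulative_distance_curve(edges, b, grid = 0)$fraction, 1)

  two <- tibble::tibble(chrom = "c", pos = c(1299, 1899))
  # distances 100 and 700 by construction (nearest end-edge at 1199)
  cv <- cumulative_distance_curve(two, b, grid = c(0, 600, 1000))
  expect_equal(cv$fraction, c(0, 0.5, 1))

  set.seed(9)
  pk <- tibble::tibble(chrom = "c", pos = sample(0:6000, 40))
  grid <- seq(0, 3000, 250)
  cv2 <- cumulative_distance_curve(pk, b, grid = grid)
  d <- oracle_edge_distance(pk$chrom, pk$pos, b)
  expect_equal(cv2$fraction, vapply(grid, function(g) mean(d <= g), numeric(1)))
  expect_true(all(diff(cv2$fraction) >= 0))
  expect_true(all(cv2$fraction >= 0 & cv2$fraction <= 1))
  expect_equal(cumulative_distance_curve(pk, b, grid = max(d))$fraction, 1)

  expect_error(cumulative_distance_curve(pk[0, ], b), "0 peaks")
})

test_that("matched fractions agree with the curve and the counting oracle", {
  b <- blocks_tbl("c", c(1000L, 5000L), c(1150L, 5100L))
  inside <- tibble::tibble(chrom = "c", pos = c(1050, 5050))
  expect_equal(matched_fraction(inside, b)$fraction, 1)

  none <- matched_fraction(inside, b[0, ])
  expect_equal(none$fraction, 0)

  set.seed(10)
  pk <- tibble::tibble(chrom = "c", pos = sample(0:6000, 30))
  mf <- matched_fraction(pk, b, match_distance = 600)
  d <- oracle_edge_distance(pk$chrom, pk$pos, b)
  expect_equal(mf$matched, sum(d <= 600))
  cv <- cumulative_distance_curve(pk, b, grid = 600)
  expect_equal(mf$fraction, cv$fraction)
})

test_that("the random null hits closed-form coverage and is reproducible", {
  g <- one_chrom_genome(100000)
  # genome tiled by short adjacent blocks: every position within 250 bp of
  # an edge, so every repetition matches completely
  starts <- seq(0L, 99500L, 500L)
  full <- blocks_tbl("chr1", starts, starts + 500L)
  rn_full <- random_null(20, full, g, repetitions = 5, seed = 1)
  expect_true(all(rn_full$fractions == 1))

  # sparse non-overlapping blocks: coverage expectation sum(w + 2 d*)/G
  b <- blocks_tbl("chr1", c(10000L, 40000L, 70000L),
                  c(10200L, 40500L, 70100L))
  d_star <- 600
  expected <- sum((b$end - b$start) + 2 * d_star) / 100000
  rn <- random_null(200, b, g, match_distance = d_star, repetitions = 200,
                    seed = 2)
  se <- sd(rn$fractions) / sqrt(length(rn$fractions))
  expect_lt(abs(rn$mean_fraction - expected), 3 * se + 1e-12)

  rn_b <- random_null(200, b, g, match_distance = d_star, repetitions = 200,
                      seed = 2)
  expect_identical(rn$envelope, rn_b$envelope)
  expect_true(all(rn$envelope$lower <= rn$envelope$upper))
})

test_that("fisher_exact reproduces exact enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-7)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")

  set.seed(11)
  for (k in 1:50) {
    tab <- sample(0:12, 4, replace = TRUE)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(matrix(tab, 2)),
                 oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7)
  }
})

test_that("random peaks are statistically indistinguishable from the null", {
  g <- toy_genome()
  b <- generate_hotspots(g, hotspot_config(n_blocks = 150, seed = 12))
  lens <- setNames(g$length, g$chrom)
  pk <- withr::with_seed(13, {
    ci <- sample.int(2, 200, TRUE, prob = lens)
    tibble::tibble(chrom = g$chrom[ci],
                   pos = floor(runif(200) * lens[ci]),
                   height = runif(200, 1, 2))
  })
  pk$rank <- rank(-pk$height, ties.method = "first")
  cc <- compare_top_n(pk, b, g, n_peaks = 200, n_blocks = 150, seed = 14)
  expect_gt(cc$fisher_p, 0.01)
  td <- tidy(cc)
  inside <- td$fraction >= td$null_lower & td$fraction <= td$null_upper
  expect_gte(mean(inside), 0.9)
})

test_that("compare_top_n warns when fewer peaks exist than requested", {
  g <- toy_genome()
  b <- generate_hotspots(g, hotspot_config(n_blocks = 50, seed = 15))
  pk <- tibble::tibble(chrom = "chrA", pos = c(1000, 9000),
                       height = c(2, 1.5), rank = 1:2)
  expect_warning(cc <- compare_top_n(pk, b, g, n_peaks = 10, n_blocks = 50,
                                     repetitions = 10, seed = 16),
                 "only 2 peaks")
  expect_equal(glance(cc)$n_peaks, 2)
  gl <- glance(cc)
  expect_named(gl, c("n_peaks", "n_blocks", "match_distance", "matched",
                     "unmatched", "fraction", "null_fraction", "p_value"))
  expect_s3_class(autoplot(cc), "ggplot")
})

test_that("axis-domain labels apply a strict ratio threshold", {
  pos <- seq(0, 450, 50)
  prof <- flagged_profile("c", pos, c(0.4, 0.6, 0.5, rep(1, 7)), "8D/8A")
  sites <- tibble::tibble(chrom = "c", pos = c(0, 50, 100))
  lab <- classify_axis_domains(prof, sites)
  expect_equal(lab$label, c(0L, 1L, 0L))  # 0.5 itself is not "exceeded"
  expect_equal(lab$ratio, c(0.4, 0.6, 0.5))

  g <- one_chrom_genome(500)
  beyond <- tibble::tibble(chrom = "c", pos = 9999)
  prof2 <- flagged_profile("c", pos, rep(1, 10))
  expect_error(
    classify_axis_domains(prof2, beyond,
                          genome = make_genome(c(c = 500))),
    "beyond")
})
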