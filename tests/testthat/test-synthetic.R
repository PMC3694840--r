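test_that("axis sites flank their blocks at the configured offsets", {
  g <- toy_genome()
  expect_equal(nrow(generate_axis_sites(g, blocks_tbl(character(0),
                                                      integer(0),
                                                      integer(0)))), 0L)

  b1 <- blocks_tbl("chrA", 49910L, 50091L, heat = 10)  # centered at 50000
  s1 <- generate_axis_sites(g, b1, offset_range = c(2000, 2000), seed = 1)
  expect_true(s1$pos %in% c(48000, 52000))
  expect_equal(s1$strength, 10)

  b <- generate_hotspots(g, hotspot_config(n_blocks = 120, seed = 4))
  ax <- generate_axis_sites(g, b, seed = 5)
  expect_equal(nrow(ax), nrow(b))
  centers <- (b$start + b$end - 1) / 2
  expect_true(all(abs(ax$pos - centers) <= 8000))
  expect_true(all(ax$pos >= 0))
  # strength proportional to the local block heat
  expect_equal(ax$strength, b$heat)
})

test_that("background peaks land in end/pericentric windows, reproducibly", {
  g <- toy_genome()
  expect_equal(nrow(generate_background_peaks(g, n = 0)), 0L)

  bg1 <- generate_background_peaks(g, n = 20, seed = 9)
  bg2 <- generate_background_peaks(g, n = 20, seed = 9)
  expect_identical(bg1, bg2)

  lens <- setNames(g$length, g$chrom)
  L <- lens[bg1$chrom]
  in_window <- bg1$pos <= 20000 | bg1$pos >= L - 20000 |
    abs(bg1$pos - L / 2) <= 10000
  expect_true(all(in_window))
  expect_true(all(bg1$amplitude > 0))
})

test_that("a featureless noise-free profile is constant at background level", {
  g <- one_chrom_genome(5000)
  p <- simulate_profile(g, blocks_tbl(character(0), integer(0), integer(0)),
                        allele = "WT",
                        config = allele_config(noise_sigma = 0,
                                               background_level = 1.3))
  expect_true(all(p$value == 1.3))
  expect_equal(p$pos, seq(0, 4999, 50))
})

test_that("probe values equal the closed-form truncated-Gaussian sum", {
  g <- one_chrom_genome(20000)
  b <- blocks_tbl("chr1", c(3000L, 12000L), c(3200L, 12400L), heat = c(5, 20))
  ax <- tibble::tibble(chrom = "chr1", pos = c(7000, 16000),
                       strength = c(5, 20), block = c("hs0001", "hs0002"))
  bg <- tibble::tibble(chrom = "chr1", pos = 500, amplitude = 1.2, sd = 350)
  cfg <- allele_config(noise_sigma = 0)
  for (al in c("WT", "8A", "8D")) {
    p <- simulate_profile(g, b, ax, bg, al, cfg)
    # independent per-probe, per-component loop
    tg <- function(x, c0, s) ifelse(abs(x - c0) <= 2.5 * s,
                                    exp(-0.5 * ((x - c0) / s)^2), 0)
    expected <- vapply(p$pos, function(x) {
      v <- 1
      for (j in 1:2) {
        v <- v + cfg$hotspot_multiplier[[al]] * (b$heat[j] / mean(b$heat)) *
          tg(x, (b$start[j] + b$end[j] - 1) / 2, 400)
        v <- v + cfg$axis_multiplier[[al]] * (ax$strength[j] / mean(ax$strength)) *
          tg(x, ax$pos[j], 600)
      }
      v + bg$amplitude * tg(x, bg$pos, bg$sd)
    }, numeric(1))
    expect_equal(p$value, expected, tolerance = 1e-12)
  }
})

test_that("the 8A hotspot gain over wild type is 25% of the hotspot component", {
  g <- one_chrom_genome(20000)
  b <- blocks_tbl("chr1", 9900L, 10101L, heat = 8)  # center at 10000
  cfg <- allele_config(noise_sigma = 0)
  vA <- value_at(simulate_profile(g, b, allele = "8A", config = cfg),
                 "chr1", 10000)
  vW <- value_at(simulate_profile(g, b, allele = "WT", config = cfg),
                 "chr1", 10000)
  gain <- (vA - vW) / (vW - 1)
  expect_equal(gain, 0.25, tolerance = 1e-9)
  expect_gt(gain, 0.20)
  expect_lt(gain, 0.30)
})

test_that("allele ordering holds at every hotspot center and axis site", {
  g <- toy_genome()
  b <- generate_hotspots(g, hotspot_config(n_blocks = 100, seed = 6))
  ax <- generate_axis_sites(g, b, seed = 7)
  bg <- generate_background_peaks(g, n = 10, seed = 8, blocks = b,
                                  axis_sites = ax)
  cfg <- allele_config(noise_sigma = 0)
  p <- lapply(setNames(nm = c("WT", "8A", "8D")), function(al) {
    simulate_profile(g, b, ax, bg, al, cfg)
  })
  centers <- (b$start + b$end - 1) / 2
  hA <- value_at(p$`8A`, b$chrom, centers)
  hW <- value_at(p$`WT`, b$chrom, centers)
  hD <- value_at(p$`8D`, b$chrom, centers)
  expect_true(all(hA > hW & hW > hD))
  aA <- value_at(p$`8A`, ax$chrom, ax$pos)
  aW <- value_at(p$`WT`, ax$chrom, ax$pos)
  aD <- value_at(p$`8D`, ax$chrom, ax$pos)
  expect_true(all(aD > aW & aW > aA))
})

test_that("profiles are reproducible from (seed, config) and reject bad alleles", {
  g <- one_chrom_genome(30000)
  b <- blocks_tbl("chr1", c(5000L, 20000L), c(5200L, 20300L), heat = c(2, 9))
  cfg <- allele_config(seed = 12)
  p1 <- simulate_profile(g, b, allele = "8A", config = cfg)
  p2 <- simulate_profile(g, b, allele = "8A", config = cfg)
  expect_identical(p1$value, p2$value)
  pW <- simulate_profile(g, b, allele = "WT", config = cfg)
  expect_false(identical(p1$value, pW$value))  # distinct noise streams
  expect_error(simulate_profile(g, b, allele = "8E", config = cfg), "allele")
})
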