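test_that("exploration domain spans default f_low to 1.2x f_high on the grid", {
  p <- toy_profile(edges = c(100, 200, 400), step = 1, min_width = 10)
  d <- exploration_domain(p)
  expect_equal(d$lo, c(100, 200))
  expect_equal(d$hi, c(240, 480))

  # minimal-width band: the lower edge is the default f_low exactly
  q <- toy_profile(edges = c(70, 80, 200), step = 1, min_width = 10)
  expect_equal(exploration_domain(q)$lo[1], 70)

  # coarse 62 Hz grid anchored at a multiple of 62: the expanded upper
  # bound snaps DOWN to the largest grid point below 1.2 x f_high
  ab_like <- toy_profile(edges = c(248, 1000), step = 62, min_width = 62,
                         f_min = 248)
  d62 <- exploration_domain(ab_like)
  grid <- 248 + 62 * (0:100)
  expect_equal(d62$hi, max(grid[grid <= 1.2 * 1000]))
  expect_equal(d62$hi, 1178)
})

test_that("exploration domain requires at least one active electrode", {
  expect_error(toy_profile(deactivated = 1:3), "all electrodes deactivated")
})

test_that("chain_and_repair returns the default map unchanged", {
  for (p in all_shipped_profiles()) {
    b <- active_default_bands(p)
    m <- chain_and_repair(b$f_high, p)
    expect_equal(m$f_high, b$f_high)
    expect_equal(m$f_low, b$f_low)
  }
})

test_that("chain_and_repair resolves non-monotone vectors apex to base", {
  p <- toy_profile(edges = c(100, 300, 480, 600), step = 1, min_width = 10)
  domain <- data.frame(electrode = 1:3, lo = c(100, 200, 380),
                       hi = c(300, 480, 600))
  m <- chain_and_repair(c(250, 240, 400), p, domain)
  # hand trace: band 2's lower edge chains to 250, so its proposed upper
  # edge 240 must be lifted to 250 + min width = 260
  expect_equal(m$f_low, c(100, 250, 260))
  expect_equal(m$f_high, c(250, 260, 400))
  expect_equal(nrow(validate_fmap(m, p)), 0)
})

test_that("repair infeasibility names the first blocked electrode", {
  p <- toy_profile(edges = c(100, 120, 140), step = 1, min_width = 50)
  domain <- data.frame(electrode = 1:2, lo = c(100, 120), hi = c(144, 168))
  # 100 + 50 = 150 > 144 already blocks electrode 1
  expect_error(chain_and_repair(c(140, 160), p, domain),
               "infeasible at electrode 1")
})

test_that("center frequency is the geometric mean of the band edges", {
  expect_equal(center_frequency(100, 400), 200)
  expect_equal(center_frequency(440, 440), 440)
  expect_equal(center_frequency(70, 8500), sqrt(70 * 8500))
  expect_equal(center_frequency(70, 8500), 771.4, tolerance = 1e-4)
  expect_equal(center_frequency(100, 400, method = "arithmetic"), 250)
  expect_error(center_frequency(-1, 10), "positive")
})

test_that("validate_fmap flags planted contiguity and width defects", {
  p <- toy_profile(edges = c(100, 200, 300, 400), step = 1, min_width = 20)
  good <- default_fmap(p)
  expect_equal(nrow(validate_fmap(good, p)), 0)

  gap <- good; gap$f_low[2] <- 210
  v <- validate_fmap(gap, p)
  expect_equal(v$rule, "contiguity")
  expect_equal(v$electrode, 2L)

  narrow <- good; narrow$f_high[3] <- 310; narrow$f_low[3] <- 300
  v <- validate_fmap(narrow, p)
  expect_true("min_width" %in% v$rule)

  off <- good; off$f_high[1] <- 200.5; off$f_low[2] <- 200.5
  expect_true("quantization" %in% validate_fmap(off, p)$rule)
})

test_that("random proposals always repair to valid, idempotent maps", {
  set.seed(101)
  for (p in all_shipped_profiles()) {
    d <- exploration_domain(p)
    n <- nrow(d)
    for (rep in 1:60) {
      v <- runif(n, min = d$lo * 0.9, max = d$hi * 1.1)  # partly out of domain
      m <- chain_and_repair(v, p, d)
      expect_equal(nrow(validate_fmap(m, p, d)), 0)
      m2 <- chain_and_repair(m$f_high, p, d)
      expect_identical(m2$f_high, m$f_high)
      expect_identical(m2$f_low, m$f_low)
    }
  }
})

test_that("deactivated electrodes are excluded and their range absorbed", {
  p <- shipped_profile("medel12", deactivated = c(5L, 12L))
  b <- active_default_bands(p)
  expect_equal(b$electrode, setdiff(1:12, c(5, 12)))
  # electrode 6 absorbs electrode 5's range downward
  full <- shipped_profile("medel12")$default_bands
  expect_equal(b$f_low[b$electrode == 6], full$f_high[4])
  # chained default over actives is contiguous and valid
  expect_equal(nrow(validate_fmap(default_fmap(p), p)), 0)
})

test_that("profiles and maps round-trip through JSON and CSV", {
  p <- shipped_profile("cochlear22")
  f <- tempfile(fileext = ".json")
  write_device_profile(p, f)
  p2 <- read_device_profile(f)
  expect_equal(p2$default_bands, p$default_bands)
  expect_equal(p2$freq_step_hz, p$freq_step_hz)

  m <- default_fmap(p)
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_fmap(m, fj); write_fmap(m, fc)
  expect_equal(read_fmap(fj)$f_high, m$f_high)
  expect_equal(read_fmap(fc)$f_low, m$f_low)
})

test_that("base-first profiles are normalized to apex-first on load", {
  edges <- c(100, 200, 400, 800)
  apex <- device_profile("a", cbind(edges[-4], edges[-1]), 1, 10)
  base <- device_profile("a", cbind(rev(edges[-1]), rev(edges[-4]))[, 2:1],
                         1, 10, indexing = "base_first", deactivated = 1L)
  expect_equal(base$default_bands$f_low, apex$default_bands$f_low)
  expect_equal(base$deactivated, 3L)  # base-first electrode 1 is apex-first 3
})
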