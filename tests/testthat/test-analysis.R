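test_that("the packaged session table satisfies its structural invariants", {
  tab <- read_session_table()
  expect_equal(nrow(tab), 27)
  expect_equal(nrow(validate_session_table(tab)), 0)
  expect_true(all(tab$snr_db %in% c(-10, -7, -5, 0, 5, 10)))
  # abandoned sessions: patient 2 after 8 maps, patient 4 after 6 maps
  labs <- c(paste0("P", 1:4), paste0("C", 1:9))
  n_scored <- apply(tab[labs], 1, function(r) sum(!is.na(r)))
  expect_equal(n_scored[tab$patient == 2], 8, ignore_attr = TRUE)
  expect_equal(n_scored[tab$patient == 4], 6, ignore_attr = TRUE)
  expect_true(all(n_scored[!tab$patient %in% c(2, 4)] == 13))
})

test_that("violations are reported for corrupted tables", {
  tab <- read_session_table()
  tab$selected[1] <- "C1"  # not the row maximum (C3 scores 9)
  v <- validate_session_table(tab)
  expect_true("selected_not_max" %in% v$rule)

  tab2 <- read_session_table()
  tab2$C2[5] <- NA  # interior hole breaks the trailing-missing pattern
  expect_true("trailing_missing" %in% validate_session_table(tab2)$rule)
})

test_that("score summaries use the sample SD and report both SD and SEM", {
  tab <- read_session_table()
  s <- summarize_wrs(tab)
  expect_equal(s$initial$mean, mean(tab$initial_wrs))
  expect_equal(s$initial$sd, sd(tab$initial_wrs))          # n-1 denominator
  expect_equal(s$initial$sem, sd(tab$initial_wrs) / sqrt(27))
  expect_equal(s$final$median, sort(tab$final_wrs)[14])    # middle of n = 27
  expect_equal(s$final$mean_percent, 10 * mean(tab$final_wrs))

  const <- tab; const$initial_wrs <- 5
  sc <- summarize_wrs(const)
  expect_equal(sc$initial$sd, 0)
  expect_equal(sc$initial$median, 5)

  empty <- tab; empty$final_wrs <- NA
  expect_error(summarize_wrs(empty), "final")
})

test_that("selected maps are classified into parent and child generations", {
  tab <- read_session_table()
  counts <- best_generation_counts(tab)
  expect_equal(sum(counts), 27)
  all_p1 <- tab; all_p1$selected <- "P1"
  expect_equal(best_generation_counts(all_p1),
               c(parents = 27L, gen1 = 0L, gen2 = 0L, gen3 = 0L))
  bad <- tab; bad$selected[3] <- "X9"
  expect_error(best_generation_counts(bad), "unknown")
})

test_that("tie detection counts rows whose maximum is shared", {
  tab <- read_session_table()
  ties <- tie_counts(tab)
  expect_equal(ties$patients, c(2, 3, 4, 8, 9, 11, 20, 21, 24))

  one <- tab[1, ]
  one[paste0("P", 1:4)] <- c(1, 2, 3, 4)
  one[paste0("C", 1:9)] <- 5:13
  expect_equal(tie_counts(one)$count, 0)  # strictly distinct row
  one[paste0("C", 1:9)] <- 4
  expect_equal(tie_counts(one)$count, 1)  # shared maximum
})

test_that("score-to-percent conversion is a simple rescaling with bounds", {
  expect_equal(wrs_to_percent(4.1667), 41.667)
  expect_equal(wrs_to_percent(0), 0)
  expect_equal(wrs_to_percent(10), 100)
  expect_error(wrs_to_percent(10.5), "\\[0, 10\\]")
})

test_that("signed-rank exact branch equals brute-force enumeration", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    x <- sample(0:10, n, replace = TRUE)
    y <- pmin(10, pmax(0, x + sample(-3:3, n, replace = TRUE)))
    if (all(x == y)) y[1] <- y[1] + 1
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p.value, brute_force_signed_rank_p(x, y))
  }
})

test_that("signed-rank matches the reference implementation without ties", {
  set.seed(57)
  for (i in 1:25) {
    n <- sample(5:11, 1)
    x <- rnorm(n)
    y <- x + rnorm(n)  # continuous: no zeros, no ties a.s.
    got <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value)
  }
})

test_that("a constant shift of six pairs gives the textbook exact p-value", {
  x <- 1:6
  got <- wilcoxon_signed_rank(x, x + 10)
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 1 / 32)  # 2 * (1/64), all 2^6 sign assignments
})

test_that("exact and normal branches agree closely at n = 12", {
  set.seed(91)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- x + rnorm(12, sd = 1.5)
    p_exact <- wilcoxon_signed_rank(x, y, exact_limit = 12)$p.value
    p_norm <- wilcoxon_signed_rank(x, y, exact_limit = 0)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("all-zero differences degenerate to p = 1 with a warning", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  expect_equal(res$p.value, 1)
  expect_equal(res$method, "degenerate")
})

test_that("the full report confirms final scores improved over initial", {
  rep <- session_table_report()
  expect_gt(rep$summary$final$mean, rep$summary$initial$mean)
  expect_lt(rep$wilcoxon$p.value, 0.001)
  expect_equal(rep$n_patients, 27)
})
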