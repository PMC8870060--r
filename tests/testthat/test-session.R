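test_that("a full session evaluates 4 + 3x3 maps with pools drawn from 7, 10, 13", {
  p <- shipped_profile("medel12")
  lst <- simulated_listener(p, seed = 99)
  res <- run_session(p, make_simulated_fitness(lst), seed = 4)
  state <- res$state

  expect_true(state$complete)
  expect_equal(session_evaluated(state), 13)
  expect_equal(names(state$individuals),
               c(paste0("P", 1:4), paste0("C", 1:9)))
  expect_equal(vapply(state$individuals, `[[`, integer(1), "generation"),
               c(P1 = 0L, P2 = 0L, P3 = 0L, P4 = 0L,
                 C1 = 1L, C2 = 1L, C3 = 1L, C4 = 2L, C5 = 2L, C6 = 2L,
                 C7 = 3L, C8 = 3L, C9 = 3L))

  surv <- Filter(function(e) e$kind == "survivors", state$events)
  expect_equal(vapply(surv, function(e) e$payload$drawn_from, numeric(1)),
               c(4, 7, 10, 13))
  for (e in surv) expect_length(e$payload$pool, 4)

  # every generated map satisfies all constraints
  for (m in state$individuals)
    expect_equal(nrow(validate_fmap(m, p, state$domain)), 0)
})

test_that("the survivor pool always contains the best individual so far", {
  p <- shipped_profile("ab16")
  lst <- simulated_listener(p, seed = 17)
  res <- run_session(p, make_simulated_fitness(lst), seed = 8)
  state <- res$state
  scores <- vapply(state$individuals, `[[`, numeric(1), "score")
  for (e in Filter(function(e) e$kind == "survivors", state$events)) {
    n_seen <- e$payload$drawn_from
    seen <- scores[seq_len(n_seen)]
    expect_true(names(which.max(seen)) %in% e$payload$pool)
    # pool scores dominate the non-pool scores among those seen
    outside <- setdiff(names(seen), e$payload$pool)
    if (length(outside))
      expect_gte(min(scores[e$payload$pool]), max(seen[outside]))
  }
  # best of session is at least the best parent (elitism)
  expect_gte(res$best$score, max(scores[1:4]))
})

test_that("constant fitness keeps the first four maps as survivors", {
  p <- shipped_profile("medel12")
  res <- run_session(p, function(fmap, ctx) 5, seed = 2)
  expect_equal(res$state$pool, paste0("P", 1:4))
  # batch tie-break 'latest' picks the most recent of the tied maps
  expect_equal(res$best$id, "C9")
  expect_equal(session_best(res$state, choose = "P2")$id, "P2")
  expect_error(session_best(res$state, choose = "nope"), "not among")
})

test_that("aborting after the first child of generation 2 leaves 8 evaluated", {
  p <- shipped_profile("medel12")
  res <- run_session(p, scripted_fitness(c(4, 5, 6, 3, 7, 5, 6, 8)), seed = 3)
  expect_true(res$state$aborted)
  expect_equal(session_evaluated(res$state), 8)
  expect_equal(res$state$individuals$C4$generation, 2L)
  expect_equal(res$best$score, 8)  # best among the 8 scored

  # the six-evaluation abandon pattern: second child of generation 1
  res6 <- run_session(p, scripted_fitness(c(4, 5, 6, 3, 7, 5)), seed = 3)
  expect_equal(session_evaluated(res6$state), 6)
})

test_that("identical inputs give identical session transcripts", {
  p <- shipped_profile("oticon20")
  t1 <- run_session(p, make_simulated_fitness(simulated_listener(p, seed = 5)),
                    seed = 10)
  t2 <- run_session(p, make_simulated_fitness(simulated_listener(p, seed = 5)),
                    seed = 10)
  expect_identical(
    lapply(t1$state$individuals, function(m) list(m$f_high, m$score)),
    lapply(t2$state$individuals, function(m) list(m$f_high, m$score)))
  expect_identical(t1$best$id, t2$best$id)
})

test_that("make_generation steps one generation with pool recomputation", {
  p <- shipped_profile("medel12")
  lst <- simulated_listener(p, noise_mode = "noise_free", seed = 21)
  fit <- make_simulated_fitness(lst)
  cfg <- evolution_config(rng_seed = 6)
  state <- session_start(p, cfg)
  for (id in session_pending(state))
    state <- session_score(state, id, fit(state$individuals[[id]], NULL))
  expect_equal(length(state$individuals), 4)
  state <- make_generation(state, fit)
  expect_equal(length(state$individuals), 7)
  expect_equal(session_evaluated(state), 7)
  expect_error(session_next(state), NA)  # no pending scores
  expect_error(make_generation(session_next(state), fit), "pending")
})

test_that("scores are validated against the intermediate word count", {
  p <- toy_profile()
  state <- session_start(p, evolution_config(rng_seed = 1))
  id <- session_pending(state)[1]
  expect_error(session_score(state, id, 11), "0..10")
  expect_error(session_score(state, id, -1), "0..10")
  expect_error(session_score(state, "Zz", 5), "not awaiting")
  state <- session_score(state, id, 10)
  expect_equal(state$individuals[[id]]$score, 10)
})
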