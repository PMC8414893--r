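test_that("per-window counts match hand recounts on the fixture", {
  s <- make_hand_store()
  w <- slice_days(s, "free_adapt")
  expect_equal(total_visits(s, "a1", w[1, ]), 2)
  expect_equal(total_visits(s, "a1", w[2, ]), 1)
  expect_equal(total_visits(s, "a3", w[2, ]), 0)
  expect_equal(total_licks(s, "a1", w[1, ]), 3)
  expect_equal(total_licks(s, "a2", w[2, ]), 4)
  expect_equal(visits_with_nosepoke(s, "a1", w[1, ]), 1)  # only visit 1 poked
  expect_equal(visits_with_nosepoke(s, "a3", w[1, ]), 0)
})

test_that("drink-motivated fraction is % of visits with a lick, NA when no visits", {
  s <- make_hand_store()
  w <- slice_days(s, "free_adapt")
  expect_equal(drink_motivated_fraction(s, "a1", w[1, ]), 50)   # 1 of 2
  expect_equal(drink_motivated_fraction(s, "a3", w[1, ]), 100)
  expect_true(is.na(drink_motivated_fraction(s, "a3", w[2, ])))
})

test_that("place metrics use visit-level corner identity", {
  s <- make_hand_store()
  w <- slice_days(s, "free_adapt")
  # a1 day 1: visits to corners 1 and 2
  expect_equal(pct_correct_place(s, "a1", w[1, ], assigned_corner = 1), 50)
  expect_equal(pct_correct_place(s, "a1", w[1, ], assigned_corner = 3), 0)
  expect_true(is.na(pct_correct_place(s, "a3", w[2, ], assigned_corner = 1)))
  # correct visit needs both a poke and a lick: visit 1 has both
  expect_equal(correct_visit_with_lick(s, "a1", w[1, ], 1), 100)
  expect_equal(correct_visit_with_lick(s, "a1", w[1, ], 2), 0)  # visit 2: none
  expect_true(is.na(correct_visit_with_lick(s, "a1", w[1, ], 3)))
})

test_that("pct_correct under a no-preference chooser converges to 25%", {
  set.seed(31)
  n <- 10000
  corners <- sample.int(4, n, replace = TRUE)
  t0 <- seq(0, by = 8, length.out = n)
  s <- event_store(
    animals = data.frame(animal_id = "u1", genotype = "NonTg", cage_id = 1L),
    visits = data.frame(visit_id = seq_len(n), animal_id = "u1",
                        corner = corners, t_start = t0, t_end = t0 + 5),
    schedule = data.frame(phase = "free_adapt", t_start = 0,
                          duration_days = 1L))
  w <- slice_days(s, "free_adapt")
  p <- pct_correct_place(s, "u1", w[1, ], assigned_corner = 2) / 100
  # 99.9% binomial CI around 0.25 at n = 10,000
  expect_lt(abs(p - 0.25), 3.3 * sqrt(0.25 * 0.75 / n))
})

test_that("SRT outcome percentages partition initiated trials", {
  trials <- data.frame(
    outcome = rep(c("correct", "incorrect", "premature"), c(12, 5, 3)),
    reaction_time = c(runif(12, 0, 7), rep(NA, 8)))
  m <- srt_metrics(trials, total_visits = 40)
  expect_equal(m$pct_correct, 60)
  expect_equal(m$pct_incorrect, 25)
  expect_equal(m$pct_premature, 15)
  expect_equal(m$pct_correct + m$pct_incorrect + m$pct_premature, 100)
  expect_equal(m$pct_initiated, 50)

  all_pre <- data.frame(outcome = rep("premature", 4), reaction_time = NA_real_)
  m <- srt_metrics(all_pre, 10)
  expect_equal(m$pct_premature, 100)
  expect_true(is.na(m$mean_reaction_time))

  none <- trials[0, ]
  m <- srt_metrics(none, 10)
  expect_true(is.na(m$pct_correct))
  expect_equal(m$pct_initiated, 0)
})

test_that("SRT partition holds on reconstructed trials from simulated streams", {
  s <- small_cohort(21)$store
  w <- slice_days(s, "srt")
  asg <- s$assignments[s$assignments$phase == "srt", ]
  for (i in seq_len(min(6, nrow(asg)))) {
    id <- asg$animal_id[i]
    for (d in 1:nrow(w)) {
      tr <- reconstruct_srt_trials(s, id, w[d, ], asg$corner[i])
      if (nrow(tr) > 0) {
        m <- srt_metrics(tr, total_visits(s, id, w[d, ]))
        expect_equal(m$pct_correct + m$pct_incorrect + m$pct_premature, 100)
      }
    }
  }
})

test_that("avoidance and retention metrics count airpuff-corner poke visits", {
  s <- make_hand_store()
  w <- slice_days(s, "free_adapt")  # fixture events live here; geometry only
  am <- avoidance_metrics(s, "a1", airpuff_corner = 1, window = w[1, ])
  expect_equal(am$total_visits_24h, 2)
  expect_equal(am$airpuff_nosepoke_visits, 1)
  am <- avoidance_metrics(s, "a3", airpuff_corner = 1, window = w[1, ])
  expect_equal(am$airpuff_nosepoke_visits, 0)
  expect_equal(retention_error_pct(s, "a1", 1, w[1, ]), 50)
  expect_equal(retention_error_pct(s, "a1", 3, w[1, ]), 0)
  expect_true(is.na(retention_error_pct(s, "a3", 1, w[2, ])))
})

test_that("adaptation pass/fail follows the removal-reintroduction rule", {
  mk <- function(lick_times, id = "x1") {
    n <- length(lick_times)
    vis <- data.frame(visit_id = seq_len(max(n, 1)), animal_id = id, corner = 1L,
                      t_start = if (n) lick_times - 1 else 10,
                      t_end = if (n) lick_times + 1 else 20)
    lk <- if (n) data.frame(visit_id = seq_len(n), t = lick_times)
          else data.frame(visit_id = integer(), t = numeric())
    event_store(
      animals = data.frame(animal_id = id, genotype = "TG", cage_id = 1L),
      visits = vis, licks = lk)
  }
  # licking every day of adaptation -> passed
  daily <- 86400 * (0:8) + 1000
  out <- pass_fail_adaptation(mk(daily))
  expect_true(out$passed)
  expect_equal(out$reason, "none")

  # never licking: dry day 1, dry reintroduction day -> excluded on day 3
  out <- pass_fail_adaptation(mk(numeric(0)))
  expect_false(out$passed)
  expect_equal(out$reason, "no_licks_twice")
  expect_equal(out$failure_day, 3L)

  # dry day 1, drinks after reintroduction, keeps drinking -> passed
  # reintroduction at 86400 + 7 h = 111600; later windows advance from there
  lt <- c(120000, 250000, 330000, 420000, 500000, 590000, 670000)
  out <- pass_fail_adaptation(mk(lt))
  expect_true(out$passed)

  # dry day 1, drinks once after reintroduction, then dry again twice -> excluded
  out <- pass_fail_adaptation(mk(c(120000)))
  expect_false(out$passed)
})

test_that("percent_passed reproduces the two-decimal cohort summaries", {
  expect_equal(percent_passed(23, 20), 86.96)
  expect_equal(percent_passed(21, 12), 57.14)
  expect_equal(percent_passed(10, 0), 0)
  expect_error(percent_passed(0, 0), "positive")
  expect_error(percent_passed(5, 6), "0..n_started")
})

test_that("phase metric tables agree with the straight-line recount on one store", {
  res <- small_cohort(17)
  s <- res$store
  pf <- pass_fail_adaptation(s)
  passers <- pf$animal_id[pf$passed]
  for (ph in c("nosepoke_adapt", "reversal", "srt", "avoidance")) {
    got <- compute_phase_metrics(s, ph)
    want <- recount_phase(s, ph, sort(unique(got$animal_id)))
    merged <- merge(got, want, by = c("metric", "animal_id", "day"),
                    suffixes = c("", ".oracle"))
    expect_equal(nrow(merged), nrow(got))
    expect_equal(merged$value, merged$value.oracle, tolerance = 1e-12)
  }
  # only adaptation passers are tabulated
  expect_true(all(unique(compute_phase_metrics(s, "free_adapt")$animal_id)
                  %in% passers))
})
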