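# Per-animal, per-24-h-day dependent variables for every phase of the
# battery, plus the adaptation pass/fail (removal/exclusion) classifier.
# Zero-denominator days yield NA (missing), never 0: a score of 0 would
# fabricate behavior for an animal that produced no denominator events.

#' Number of visits attributed to a window
#' @param store An `event_store`.
#' @param animal_id Animal identifier.
#' @param window Row of [slice_days()] output.
#' @return Non-negative integer count.
#' @export
total_visits <- function(store, animal_id, window) {
  nrow(events_in(store, animal_id, window)$visits)
}

#' Number of licks attributed to a window (via the visit they belong to)
#' @inheritParams total_visits
#' @return Non-negative integer count.
#' @export
total_licks <- function(store, animal_id, window) {
  nrow(events_in(store, animal_id, window)$licks)
}

#' Number of visits with at least one nosepoke
#' @inheritParams total_visits
#' @return Count, at most `total_visits`.
#' @export
visits_with_nosepoke <- function(store, animal_id, window) {
  ev <- events_in(store, animal_id, window)
  sum(ev$visits$visit_id %in% ev$nosepokes$visit_id)
}

#' Percentage of visits with at least one lick (water-seeking motivation)
#'
#' `100 * (#visits with >= 1 lick) / (#visits)`; distinguishes visits
#' motivated by water seeking from exploratory visits.
#'
#' @inheritParams total_visits
#' @return Percentage in `[0, 100]`, or `NA` when the animal made no visits.
#' @export
drink_motivated_fraction <- function(store, animal_id, window) {
  ev <- events_in(store, animal_id, window)
  n <- nrow(ev$visits)
  if (n == 0) return(NA_real_)
  100 * sum(ev$visits$visit_id %in% ev$licks$visit_id) / n
}

#' Place-preference percent correct
#'
#' `100 * (visits to the assigned corner) / (total visits)`; correctness is
#' decided by corner identity alone, at the visit level.
#'
#' @inheritParams total_visits
#' @param assigned_corner The animal's reward corner for the phase.
#' @return Percentage, or `NA` when the animal made no visits.
#' @export
pct_correct_place <- function(store, animal_id, window, assigned_corner) {
  ev <- events_in(store, animal_id, window)
  n <- nrow(ev$visits)
  if (n == 0) return(NA_real_)
  100 * sum(ev$visits$corner == assigned_corner) / n
}

#' Percent of correct-corner visits with a nosepoke and a lick
#'
#' `100 * (correct-corner visits with >= 1 nosepoke and >= 1 lick) /
#' (correct-corner visits)`; separates drinking from exploratory visits to
#' the reward corner.
#'
#' @inheritParams pct_correct_place
#' @return Percentage, or `NA` when there were no correct-corner visits.
#' @export
correct_visit_with_lick <- function(store, animal_id, window, assigned_corner) {
  ev <- events_in(store, animal_id, window)
  correct <- ev$visits[ev$visits$corner == assigned_corner, , drop = FALSE]
  if (nrow(correct) == 0) return(NA_real_)
  with_both <- correct$visit_id %in% ev$nosepokes$visit_id &
    correct$visit_id %in% ev$licks$visit_id
  100 * sum(with_both) / nrow(correct)
}

#' Reconstruct SRT trials for one animal in one window
#'
#' Runs every assigned-corner visit through the trial state machine
#' ([srt_step()] via [srt_classify_visit()]); the first nosepoke of a visit
#' initiates at most one trial.
#'
#' @inheritParams pct_correct_place
#' @param assigned_corner The animal's SRT corner.
#' @return `data.frame(animal_id, day_index, t_init, outcome,
#'   reaction_time)`, one row per initiated trial.
#' @export
reconstruct_srt_trials <- function(store, animal_id, window, assigned_corner) {
  ev <- events_in(store, animal_id, window)
  vis <- ev$visits[ev$visits$corner == assigned_corner, , drop = FALSE]
  out <- lapply(seq_len(nrow(vis)), function(i) {
    pk <- ev$nosepokes$t[ev$nosepokes$visit_id == vis$visit_id[i]]
    rec <- srt_classify_visit(pk, vis$t_end[i])
    if (is.null(rec)) return(NULL)
    data.frame(animal_id = animal_id, day_index = window$day_index,
               t_init = rec$t_init, outcome = rec$outcome,
               reaction_time = rec$reaction_time, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(animal_id = character(), day_index = integer(),
                      t_init = numeric(), outcome = character(),
                      reaction_time = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' SRT dependent variables for one animal-day
#'
#' `pct_initiated` is over total visits (all corners); the outcome
#' percentages are over initiated trials, so that correct + incorrect +
#' premature = 100 whenever any trial was initiated. `mean_reaction_time`
#' averages the cue-onset-to-poke latency of correct trials.
#'
#' @param trials Trial records from [reconstruct_srt_trials()].
#' @param total_visits Total visits (all corners) in the same window.
#' @return Named list: `pct_initiated`, `pct_correct`, `pct_incorrect`,
#'   `pct_premature`, `mean_reaction_time` (each `NA` when its denominator
#'   is zero).
#' @export
srt_metrics <- function(trials, total_visits) {
  n_init <- nrow(trials)
  pct_initiated <- if (total_visits > 0) 100 * n_init / total_visits else NA_real_
  if (n_init == 0)
    return(list(pct_initiated = pct_initiated, pct_correct = NA_real_,
                pct_incorrect = NA_real_, pct_premature = NA_real_,
                mean_reaction_time = NA_real_))
  n_cor <- sum(trials$outcome == "correct")
  list(pct_initiated = pct_initiated,
       pct_correct = 100 * n_cor / n_init,
       pct_incorrect = 100 * sum(trials$outcome == "incorrect") / n_init,
       pct_premature = 100 * sum(trials$outcome == "premature") / n_init,
       mean_reaction_time = if (n_cor > 0)
         mean(trials$reaction_time[trials$outcome == "correct"]) else NA_real_)
}

#' Place-avoidance counts over the 24-h airpuff window
#'
#' @inheritParams total_visits
#' @param airpuff_corner The animal's airpuff corner.
#' @param window The single avoidance day window; defaults to day 1 of the
#'   avoidance phase.
#' @return `list(total_visits_24h, airpuff_nosepoke_visits)`; the latter
#'   counts visits to the airpuff corner containing at least one nosepoke
#'   (working-memory errors).
#' @export
avoidance_metrics <- function(store, animal_id, airpuff_corner,
                              window = slice_days(store, "avoidance")[1, ]) {
  ev <- events_in(store, animal_id, window)
  in_corner <- ev$visits[ev$visits$corner == airpuff_corner, , drop = FALSE]
  list(total_visits_24h = nrow(ev$visits),
       airpuff_nosepoke_visits =
         sum(in_corner$visit_id %in% ev$nosepokes$visit_id))
}

#' Retention-phase error percentage
#'
#' `100 * (visits to the former airpuff corner with >= 1 nosepoke) /
#' (total visits)` for one retention day.
#'
#' @inheritParams total_visits
#' @param former_airpuff_corner The corner that delivered airpuffs.
#' @return Percentage, or `NA` when the animal made no visits.
#' @export
retention_error_pct <- function(store, animal_id, former_airpuff_corner, window) {
  ev <- events_in(store, animal_id, window)
  n <- nrow(ev$visits)
  if (n == 0) return(NA_real_)
  err <- ev$visits$corner == former_airpuff_corner &
    ev$visits$visit_id %in% ev$nosepokes$visit_id
  100 * sum(err) / n
}

#' Adaptation pass/fail classification
#'
#' Walks each animal's lick stream through the three adaptation phases in
#' successive 24-h windows: zero licks in a full window removes the animal
#' (7 h off-cage), zero licks again in the 24 h after reintroduction
#' excludes it; a drinking window resets the removal state. Animals
#' surviving to the end of adaptation pass. A trailing partial window
#' (possible after a removal shifted the grid) cannot trigger a removal.
#'
#' @param store An `event_store` whose schedule contains the adaptation
#'   phases.
#' @return `data.frame(animal_id, genotype, passed, failure_day, reason)`;
#'   `failure_day` is the 1-based adaptation day containing the exclusion
#'   boundary (`NA` for passers), `reason` is `"none"` or
#'   `"no_licks_twice"`.
#' @export
pass_fail_adaptation <- function(store) {
  adapt <- store$schedule[store$schedule$phase %in%
                            c("free_adapt", "door_adapt", "nosepoke_adapt"), ]
  if (nrow(adapt) == 0) stop("no adaptation phases in schedule", call. = FALSE)
  s0 <- min(adapt$t_start)
  s_end <- max(adapt$t_start + adapt$duration_days * DAY_S)

  v <- store$visits; lk <- store$licks
  lick_animal <- v$animal_id[match(lk$visit_id, v$visit_id)]

  out <- lapply(seq_len(nrow(store$animals)), function(i) {
    id <- store$animals$animal_id[i]
    lt <- lk$t[lick_animal == id]
    t_cur <- s0; removed <- FALSE
    passed <- TRUE; failure_day <- NA_integer_; reason <- "none"
    while (t_cur + DAY_S <= s_end + 1e-9) {
      dry <- !any(lt >= t_cur & lt < t_cur + DAY_S)
      if (dry) {
        if (removed) {
          passed <- FALSE
          failure_day <- min(as.integer(ceiling((t_cur + DAY_S - s0) / DAY_S)),
                             as.integer(round((s_end - s0) / DAY_S)))
          reason <- "no_licks_twice"
          break
        }
        removed <- TRUE
        t_cur <- t_cur + DAY_S + REMOVAL_GAP_S
      } else {
        removed <- FALSE
        t_cur <- t_cur + DAY_S
      }
    }
    data.frame(animal_id = id, genotype = store$animals$genotype[i],
               passed = passed, failure_day = failure_day, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentage of animals passing adaptation
#'
#' @param n_started Animals that entered the cage (> 0).
#' @param n_passed Animals that passed adaptation (0..n_started).
#' @return `100 * n_passed / n_started`, rounded to two decimals.
#' @export
percent_passed <- function(n_started, n_passed) {
  if (length(n_started) != 1 || is.na(n_started) || n_started <= 0)
    stop("n_started must be a single positive count", call. = FALSE)
  if (n_passed < 0 || n_passed > n_started)
    stop("n_passed must be in 0..n_started", call. = FALSE)
  round(100 * n_passed / n_started, 2)
}

assigned_corner_of <- function(store, animal_id, phase) {
  a <- store$assignments
  hit <- a$corner[a$animal_id == animal_id & a$phase == phase]
  if (length(hit) == 1) hit else NA_integer_
}

#' Metrics defined for each phase
#' @format Named list: phase -> character vector of metric names.
#' @export
PHASE_METRICS <- list(
  free_adapt = c("total_visits", "total_licks"),
  door_adapt = c("total_visits", "total_licks"),
  nosepoke_adapt = c("total_visits", "total_licks", "visits_with_nosepoke",
                     "drink_motivated_fraction"),
  place_pref = c("total_visits", "total_licks", "pct_correct",
                 "correct_visit_with_lick"),
  reversal = c("total_visits", "total_licks", "pct_correct",
               "correct_visit_with_lick"),
  srt = c("total_visits", "total_licks", "pct_initiated", "pct_correct",
          "pct_incorrect", "pct_premature", "mean_reaction_time"),
  avoidance = c("total_visits", "airpuff_nosepoke_visits"),
  retention = c("total_visits", "retention_error_pct"))

#' Long-format metric table for one phase
#'
#' Computes every metric of `PHASE_METRICS[[phase]]` for every animal and
#' scheduled day. Only animals that passed adaptation are analyzed (the
#' excluded ones never reach the later tasks and would contribute
#' fabricated zero days to the adaptation tables); phases requiring a
#' corner assignment additionally drop animals without one. Count metrics
#' are 0 on event-free days; ratio metrics are `NA` when their denominator
#' is zero.
#'
#' @param store An `event_store`.
#' @param phase Phase name.
#' @return `data.frame(phase, metric, animal_id, genotype, day, value)`.
#' @export
compute_phase_metrics <- function(store, phase) {
  metrics <- PHASE_METRICS[[phase]]
  if (is.null(metrics))
    stop(sprintf("no metrics defined for phase '%s'", phase), call. = FALSE)
  windows <- slice_days(store, phase)
  nd <- nrow(windows)
  passed <- pass_fail_adaptation(store)
  animals <- store$animals[store$animals$animal_id %in%
                             passed$animal_id[passed$passed], , drop = FALSE]
  needs_corner <- phase %in% c("place_pref", "reversal", "srt",
                               "avoidance", "retention")
  corner <- if (needs_corner) {
    vapply(animals$animal_id, assigned_corner_of, integer(1),
           store = store, phase = phase)
  } else rep(NA_integer_, nrow(animals))
  if (needs_corner) {
    keep <- !is.na(corner)
    animals <- animals[keep, , drop = FALSE]; corner <- corner[keep]
  }
  na_tab <- function() {
    data.frame(phase = character(), metric = character(),
               animal_id = character(), genotype = character(),
               day = integer(), value = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(animals) == 0) return(na_tab())

  # one pass over the raw event tables, then per-(animal, day) aggregation
  v <- store$visits
  in_phase <- v$animal_id %in% animals$animal_id &
    v$t_start >= windows$t0[1] & v$t_start < windows$t1[nd]
  v <- v[in_phase, , drop = FALSE]
  day <- as.integer(floor((v$t_start - windows$t0[1]) / DAY_S)) + 1L
  n_pokes <- tabulate(match(store$nosepokes$visit_id, v$visit_id), nbins = nrow(v))
  n_licks <- tabulate(match(store$licks$visit_id, v$visit_id), nbins = nrow(v))
  a_idx <- match(v$animal_id, animals$animal_id)
  cell <- (a_idx - 1L) * nd + day                 # (animal, day) cell index
  n_cells <- nrow(animals) * nd
  by_cell <- function(x) {
    out <- numeric(n_cells)
    if (length(x)) {
      s <- rowsum(as.numeric(x), cell)
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }
  is_correct <- if (needs_corner) v$corner == corner[a_idx] else rep(FALSE, nrow(v))

  tv <- by_cell(rep(1, nrow(v)))
  vals <- list(total_visits = tv)
  if ("total_licks" %in% metrics) vals$total_licks <- by_cell(n_licks)
  if ("visits_with_nosepoke" %in% metrics)
    vals$visits_with_nosepoke <- by_cell(n_pokes > 0)
  if ("drink_motivated_fraction" %in% metrics)
    vals$drink_motivated_fraction <-
      ifelse(tv > 0, 100 * by_cell(n_licks > 0) / tv, NA_real_)
  if ("pct_correct" %in% metrics)
    vals$pct_correct <- ifelse(tv > 0, 100 * by_cell(is_correct) / tv, NA_real_)
  if ("correct_visit_with_lick" %in% metrics) {
    nc <- by_cell(is_correct)
    vals$correct_visit_with_lick <-
      ifelse(nc > 0,
             100 * by_cell(is_correct & n_pokes > 0 & n_licks > 0) / nc,
             NA_real_)
  }
  if ("airpuff_nosepoke_visits" %in% metrics)
    vals$airpuff_nosepoke_visits <- by_cell(is_correct & n_pokes > 0)
  if ("retention_error_pct" %in% metrics)
    vals$retention_error_pct <-
      ifelse(tv > 0, 100 * by_cell(is_correct & n_pokes > 0) / tv, NA_real_)
  if (phase == "srt") {
    srt_vals <- matrix(NA_real_, n_cells, 5,
                       dimnames = list(NULL, c("pct_initiated", "pct_correct",
                                               "pct_incorrect", "pct_premature",
                                               "mean_reaction_time")))
    for (i in seq_len(nrow(animals))) {
      for (d in seq_len(nd)) {
        trials <- reconstruct_srt_trials(store, animals$animal_id[i],
                                         windows[d, ], corner[i])
        sm <- srt_metrics(trials, tv[(i - 1L) * nd + d])
        srt_vals[(i - 1L) * nd + d, ] <- unlist(sm)
      }
    }
    for (m in colnames(srt_vals)) vals[[m]] <- srt_vals[, m]
  }

  out <- do.call(rbind, lapply(metrics, function(m)
    data.frame(phase = phase, metric = m,
               animal_id = rep(animals$animal_id, each = nd),
               genotype = rep(animals$genotype, each = nd),
               day = rep(seq_len(nd), nrow(animals)),
               value = vals[[m]], stringsAsFactors = FALSE)))
  out <- out[order(match(out$metric, metrics), out$animal_id, out$day), ]
  rownames(out) <- NULL
  out
}

#' Metric tables for all phases of a store
#'
#' @param store An `event_store`.
#' @param phases Phases to compute; defaults to every phase with metrics.
#' @return Long `data.frame` as in [compute_phase_metrics()].
#' @export
compute_all_metrics <- function(store, phases = names(PHASE_METRICS)) {
  phases <- intersect(phases, store$schedule$phase)
  out <- do.call(rbind, lapply(phases, compute_phase_metrics, store = store))
  rownames(out) <- NULL
  out
}
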