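# Stochastic mouse-agent simulator: seeded cohorts of agents interact with
# the phase controllers to produce complete event stores with the
# statistical structure the analysis assumes, with ground truth retained.
#
# Behavioral model per agent: visits arrive as a two-rate (light/dark)
# Poisson process; each visit is exploratory (uniform corner) with
# probability w_explore, otherwise water-seeking (highest-preference
# corner); corner preferences are reinforced after each rewarded drink
# (w_c <- w_c + alpha (1 - w_c), renormalized); drinking occurs only when
# the phase controller opens a door; SRT responses are premature with
# p_impulsive, otherwise attended with p_attend at an exponential latency;
# each airpuff multiplies the agent's return probability to the airpuff
# corner by (1 - avoid_learn).

REMOVAL_GAP_S <- 7 * 3600  # off-cage time after a 24-h no-drink removal

#' Default per-genotype mouse-agent parameters
#'
#' Reads the packaged calibration file (`inst/extdata/default_params.yaml`),
#' which documents every parameter, its units and its default.
#'
#' @return Named list with elements `NonTg` and `TG`.
#' @export
default_mouse_params <- function() {
  path <- system.file("extdata", "default_params.yaml", package = "intellipheno")
  yaml::read_yaml(path)$params
}

PARAM_FIELDS <- c("visit_rate_dark", "visit_rate_light", "day1_rate_mult",
                  "w_explore", "alpha", "p_drink_fail", "licks_per_bout_mean",
                  "p_poke_explore", "p_drink_explore", "p_attend",
                  "p_impulsive", "rt_scale", "avoid_learn")

check_params <- function(p, label) {
  missing <- setdiff(PARAM_FIELDS, names(p))
  if (length(missing))
    stop(sprintf("params$%s missing field(s): %s", label,
                 paste(missing, collapse = ", ")), call. = FALSE)
  probs <- c("w_explore", "alpha", "p_drink_fail", "p_poke_explore",
             "p_drink_explore", "p_attend", "p_impulsive", "avoid_learn")
  for (f in probs)
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(sprintf("params$%s$%s must be in [0, 1]", label, f), call. = FALSE)
  for (f in c("visit_rate_dark", "visit_rate_light", "licks_per_bout_mean",
              "rt_scale", "day1_rate_mult"))
    if (p[[f]] <= 0)
      stop(sprintf("params$%s$%s must be > 0", label, f), call. = FALSE)
  invisible(p)
}

#' Build a simulation configuration
#'
#' @param cages `data.frame(n_nontg, n_tg)`, one row per cage (at most 16
#'   animals per cage).
#' @param params Per-genotype parameter lists (`NonTg`, `TG`); defaults to
#'   [default_mouse_params()]. Individual fields may be overridden via
#'   `overrides`, e.g. `overrides = list(TG = list(p_attend = 0.65))`.
#' @param schedule Phase schedule; defaults to the 29-day battery.
#' @param seed Integer seed; every random draw of the cohort derives from it.
#' @param overrides Optional nested list of per-genotype parameter overrides.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cages = data.frame(n_nontg = 8, n_tg = 8),
                       params = default_mouse_params(),
                       schedule = default_schedule(), seed = 1L,
                       overrides = NULL) {
  for (g in names(overrides))
    params[[g]][names(overrides[[g]])] <- overrides[[g]]
  for (g in GENOTYPES) {
    if (is.null(params[[g]])) stop(sprintf("params$%s missing", g), call. = FALSE)
    check_params(params[[g]], g)
  }
  if (!all(c("n_nontg", "n_tg") %in% names(cages)))
    stop("cages must have columns n_nontg, n_tg", call. = FALSE)
  if (any(cages$n_nontg + cages$n_tg > 16))
    stop("infeasible config: a cage holds up to 16 mice", call. = FALSE)
  if (any(cages$n_nontg + cages$n_tg < 1))
    stop("infeasible config: empty cage", call. = FALSE)
  structure(list(cages = cages, params = params, schedule = schedule,
                 seed = as.integer(seed)), class = "sim_config")
}

# Poisson arrival times on [t_from, t_to), with the light/dark rate selected
# per segment (light = first 14 h of each session day) and an overall rate
# multiplier.
sim_arrivals <- function(t_from, t_to, p, rate_mult = 1) {
  # segment boundaries at every lights-on and lights-off transition
  days <- seq(floor(t_from / DAY_S), ceiling(t_to / DAY_S))
  marks <- sort(unique(c(t_from, t_to, days * DAY_S, days * DAY_S + LIGHT_S)))
  marks <- marks[marks >= t_from & marks <= t_to]
  out <- numeric(0)
  for (i in seq_len(length(marks) - 1)) {
    a <- marks[i]; b <- marks[i + 1]
    light <- (a %% DAY_S) < LIGHT_S
    rate <- if (light) p$visit_rate_light else p$visit_rate_dark
    n <- stats::rpois(1, rate_mult * rate * (b - a) / 3600)
    if (n > 0) out <- c(out, stats::runif(n, a, b))
  }
  sort(out)
}

# mutable per-agent state across days
agent_state <- function() {
  e <- new.env(parent = emptyenv())
  e$w <- rep(0.25, 4)     # corner-preference weights
  e$m <- 1.0              # return probability multiplier, airpuff corner
  e
}

reinforce <- function(st, corner, alpha) {
  st$w[corner] <- st$w[corner] + alpha * (1 - st$w[corner])
  st$w <- st$w / sum(st$w)
}

# Simulate one animal over [t_from, t_to): returns flat event vectors.
# phases_of(t) resolves the active phase; corners is the per-phase
# assignment map (may be NA for adaptation).
sim_animal_span <- function(t_from, t_to, p, st, drink_fail, corner_of_phase,
                            schedule, rate_mult = 1, span_end = Inf,
                            t_min = -Inf) {
  phase_at <- function(t) {
    i <- findInterval(t, schedule$t_start)
    schedule$phase[max(i, 1)]
  }
  arrivals <- sim_arrivals(t_from, t_to, p, rate_mult)
  arrivals <- arrivals[arrivals < span_end - 300]
  n <- length(arrivals)
  if (n == 0)
    return(list(corner = integer(0), t_start = numeric(0), t_end = numeric(0),
                pokes = list(), licks = list(), last_end = t_min))
  # pre-drawn randomness, indexed in the visit loop
  dur <- pmin(pmax(stats::rlnorm(n, log(20), 0.7), 4), 180)
  u_explore <- stats::runif(n) < p$w_explore
  u_corner <- sample.int(4, n, replace = TRUE)       # exploratory corner
  u_redirect <- sample.int(3, n, replace = TRUE)     # avoidance redirect
  u_go <- stats::runif(n)                            # airpuff-corner gate
  u_poke <- stats::runif(n) < p$p_poke_explore
  u_drink <- stats::runif(n) < p$p_drink_explore
  u_imp <- stats::runif(n) < p$p_impulsive
  u_att <- stats::runif(n) < p$p_attend
  rts <- pmin(stats::rexp(n, 1 / p$rt_scale), 6.95)
  poke_lat <- stats::runif(n, 0.3, 1.2)
  pre_lat <- stats::runif(n, 0.05, 1.90)

  corner <- integer(n); ts <- numeric(n); te <- numeric(n)
  pokes <- vector("list", n); licks <- vector("list", n)
  keep <- logical(n)
  prev_end <- t_min  # visits may not overlap the previous span's last visit

  for (i in seq_len(n)) {
    t0 <- arrivals[i]
    if (t0 <= prev_end + 1) next
    phase <- phase_at(t0)
    if (phase == "delay_offcage") next
    assigned <- corner_of_phase[[phase]]
    exploratory <- u_explore[i]
    cn <- if (exploratory) u_corner[i] else which.max(st$w)
    if (phase == "avoidance" && !is.na(assigned) && cn == assigned &&
        u_go[i] > st$m)
      cn <- setdiff(1:4, assigned)[u_redirect[i]]

    poked <- !exploratory || u_poke[i]
    pk <- numeric(0); lk <- numeric(0)
    t_end <- t0 + dur[i]
    drink <- FALSE

    if (phase == "srt" && !is.na(assigned) && cn == assigned && poked) {
      t_init <- t0 + poke_lat[i]
      pk <- t_init
      if (u_imp[i]) {                       # premature: poke in pre-cue delay
        pk <- c(pk, t_init + pre_lat[i])
        t_end <- max(t_end, t_init + pre_lat[i] + 1)
      } else if (u_att[i]) {                # correct: response during cue
        t_resp <- t_init + PRECUE_DELAY + rts[i]
        pk <- c(pk, t_resp)
        drink <- !drink_fail
        t_end <- max(t_end, t_resp + 1)
      } else {                              # incorrect: cue expires
        t_end <- max(t_end, t_init + PRECUE_DELAY + CUE_DURATION + 0.5)
      }
    } else {
      if (poked) pk <- t0 + poke_lat[i]
      door_event <- if (poked) "nosepoke" else "visit_entry"
      open <- door_action(phase, door_event, cn, assigned) == "open"
      if (phase == "avoidance" && poked && !is.na(assigned) &&
          airpuff_triggered(assigned, cn)) {
        st$m <- st$m * (1 - p$avoid_learn)
      }
      drink <- open && !drink_fail && (!exploratory || u_drink[i])
    }

    if (drink) {
      n_l <- 1 + stats::rpois(1, p$licks_per_bout_mean - 1)
      t_dr <- (if (length(pk)) max(pk) else t0) + 0.3
      lk <- t_dr + sort(stats::runif(n_l, 0, max(n_l * 0.15, 0.5)))
      t_end <- max(t_end, lk[n_l] + 0.5)
      reinforce(st, cn, p$alpha)
    }
    t_end <- min(t_end, span_end)
    if (length(pk) && max(pk) > t_end) pk <- pk[pk <= t_end]
    if (length(lk) && max(lk) > t_end) lk <- lk[lk <= t_end]
    if (t_end <= t0) next

    keep[i] <- TRUE
    corner[i] <- cn; ts[i] <- t0; te[i] <- t_end
    pokes[[i]] <- pk; licks[[i]] <- lk
    prev_end <- t_end
  }
  list(corner = corner[keep], t_start = ts[keep], t_end = te[keep],
       pokes = pokes[keep], licks = licks[keep], last_end = prev_end)
}

flatten_animal_events <- function(animal_id, spans, next_visit_id) {
  corner <- unlist(lapply(spans, `[[`, "corner"))
  t_start <- unlist(lapply(spans, `[[`, "t_start"))
  t_end <- unlist(lapply(spans, `[[`, "t_end"))
  pokes <- do.call(c, lapply(spans, `[[`, "pokes"))
  licks <- do.call(c, lapply(spans, `[[`, "licks"))
  nv <- length(corner)
  ids <- seq.int(next_visit_id, length.out = nv)
  npk <- lengths(pokes); nlk <- lengths(licks)
  list(
    visits = data.frame(visit_id = ids, animal_id = rep(animal_id, nv),
                        corner = corner, t_start = t_start, t_end = t_end,
                        stringsAsFactors = FALSE),
    nosepokes = data.frame(visit_id = rep(ids, npk),
                           side = rep("left", sum(npk)),
                           t = unlist(pokes), stringsAsFactors = FALSE),
    licks = data.frame(visit_id = rep(ids, nlk), t = unlist(licks),
                       stringsAsFactors = FALSE),
    next_visit_id = next_visit_id + nv)
}

#' Generate a complete synthetic cohort
#'
#' Simulates every animal through the full schedule: the three adaptation
#' phases first (agents that drew a drink-failure emit visits but no licks,
#' are removed at the first 24-h no-drink boundary, reintroduced after 7 h
#' off-cage, and excluded after a second dry 24 h); reward corners for place
#' preference are then assigned from adaptation visit habits
#' ([assign_corners()]), the reversal corner is the diagonal opposite, and
#' the SRT/airpuff corner is the reversal corner; surviving agents are then
#' simulated through the remaining phases. Nosepoke side is recorded
#' (uniformly `"left"`) but carries no contingency.
#'
#' @param config A [sim_config()].
#' @return `list(store = event_store, ground_truth = ...)`; the ground truth
#'   echoes the config plus each animal's drink-failure draw and corner
#'   assignments.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  schedule <- config$schedule
  span <- schedule_span(schedule)
  adapt_end <- schedule$t_start[schedule$phase == "place_pref"]
  sched_row <- function(ph) schedule[schedule$phase == ph, ]

  all_animals <- list(); all_visits <- list(); all_pokes <- list()
  all_licks <- list(); all_assign <- list(); gt_animals <- list()
  next_visit_id <- 1L

  no_corners <- stats::setNames(as.list(rep(NA_integer_, length(PHASE_LEVELS))),
                                PHASE_LEVELS)

  for (cage in seq_len(nrow(config$cages))) {
    n_non <- config$cages$n_nontg[cage]; n_tg <- config$cages$n_tg[cage]
    ids <- c(sprintf("C%d-N%02d", cage, seq_len(n_non)),
             sprintf("C%d-T%02d", cage, seq_len(n_tg)))
    genos <- c(rep("NonTg", n_non), rep("TG", n_tg))
    names(genos) <- ids

    states <- list(); fails <- logical(length(ids)); names(fails) <- ids
    adapt_events <- list()

    # pass 1: adaptation (agents in ascending id order; one RNG stream)
    for (k in seq_along(ids)) {
      id <- ids[k]; p <- config$params[[genos[k]]]
      fails[k] <- stats::runif(1) < p$p_drink_fail
      st <- agent_state()
      states[[id]] <- st
      spans <- list()
      if (fails[k]) {
        # dry day 1 -> removed for 7 h -> dry reintroduction day -> excluded
        d1_end <- span[1] + DAY_S
        spans[[1]] <- sim_animal_span(span[1], d1_end, p, st, TRUE,
                                      no_corners, schedule,
                                      p$day1_rate_mult, span[2])
        re_start <- d1_end + REMOVAL_GAP_S
        spans[[2]] <- sim_animal_span(re_start, re_start + DAY_S, p, st, TRUE,
                                      no_corners, schedule, 1, span[2],
                                      t_min = spans[[1]]$last_end)
      } else {
        spans[[1]] <- sim_animal_span(span[1], span[1] + DAY_S, p, st, FALSE,
                                      no_corners, schedule,
                                      p$day1_rate_mult, span[2])
        spans[[2]] <- sim_animal_span(span[1] + DAY_S, adapt_end, p, st, FALSE,
                                      no_corners, schedule, 1, span[2],
                                      t_min = spans[[1]]$last_end)
      }
      adapt_events[[id]] <- spans
    }

    # corner assignment from adaptation visit habits of surviving animals
    survivors <- ids[!fails]
    corner_pp <- stats::setNames(integer(0), character(0))
    if (length(survivors)) {
      counts <- t(vapply(survivors, function(id) {
        cs <- unlist(lapply(adapt_events[[id]], `[[`, "corner"))
        tabulate(cs, nbins = 4)
      }, numeric(4)))
      rownames(counts) <- survivors
      corner_pp <- assign_corners(counts, genos[survivors])
    }

    # pass 2: remaining phases for survivors
    for (k in seq_along(ids)) {
      id <- ids[k]; p <- config$params[[genos[k]]]
      spans <- adapt_events[[id]]
      if (!fails[k]) {
        cpp <- corner_pp[[id]]; crev <- reversal_corner(cpp)
        corners <- no_corners
        corners$place_pref <- cpp
        corners$reversal <- crev
        corners$srt <- crev
        corners$avoidance <- crev
        corners$retention <- crev
        spans[[3]] <- sim_animal_span(adapt_end, span[2], p, states[[id]],
                                      FALSE, corners, schedule, 1, span[2],
                                      t_min = spans[[2]]$last_end)
        for (ph in c("place_pref", "reversal", "srt", "avoidance", "retention"))
          all_assign[[length(all_assign) + 1]] <-
            data.frame(phase = ph, animal_id = id, corner = corners[[ph]],
                       stringsAsFactors = FALSE)
      }
      ev <- flatten_animal_events(id, spans, next_visit_id)
      next_visit_id <- ev$next_visit_id
      all_visits[[length(all_visits) + 1]] <- ev$visits
      all_pokes[[length(all_pokes) + 1]] <- ev$nosepokes
      all_licks[[length(all_licks) + 1]] <- ev$licks
      gt_animals[[length(gt_animals) + 1]] <- data.frame(
        animal_id = id, genotype = genos[k], cage_id = cage,
        drink_fail = fails[k],
        corner_place_pref = if (fails[k]) NA_integer_ else corner_pp[[id]],
        stringsAsFactors = FALSE)
    }

    all_animals[[cage]] <- data.frame(
      animal_id = ids, genotype = genos, cage_id = cage,
      status = ifelse(fails, "excluded", "active"), stringsAsFactors = FALSE)
  }

  store <- event_store(
    animals = do.call(rbind, all_animals),
    visits = do.call(rbind, all_visits),
    nosepokes = do.call(rbind, all_pokes),
    licks = do.call(rbind, all_licks),
    schedule = schedule,
    assignments = if (length(all_assign)) do.call(rbind, all_assign)
                  else empty_assignments())
  ground_truth <- list(seed = config$seed,
                       cages = config$cages,
                       params = config$params,
                       animals = do.call(rbind, gt_animals))
  list(store = store, ground_truth = ground_truth)
}

#' Remove an animal from the cage for 7 h and mark it reintroduced
#'
#' Deletes all of the animal's visits (and their nosepokes/licks) starting
#' in `[t_removal, t_removal + 7 h)` — the animal is in a standard cage over
#' that window — and sets its status to `removed_temporary`.
#'
#' @param store An `event_store`.
#' @param animal_id Animal to remove.
#' @param t_removal Removal time (seconds).
#' @return The modified store.
#' @export
remove_and_reintroduce <- function(store, animal_id, t_removal) {
  i <- match(animal_id, store$animals$animal_id)
  if (is.na(i)) stop(sprintf("unknown animal '%s'", animal_id), call. = FALSE)
  if (store$animals$status[i] == "excluded")
    stop(sprintf("animal '%s' is already excluded", animal_id), call. = FALSE)
  v <- store$visits
  drop <- v$animal_id == animal_id & v$t_start >= t_removal &
    v$t_start < t_removal + REMOVAL_GAP_S
  drop_ids <- v$visit_id[drop]
  store$visits <- v[!drop, , drop = FALSE]
  store$nosepokes <- store$nosepokes[!store$nosepokes$visit_id %in% drop_ids, , drop = FALSE]
  store$licks <- store$licks[!store$licks$visit_id %in% drop_ids, , drop = FALSE]
  store$animals$status[i] <- "removed_temporary"
  rownames(store$visits) <- rownames(store$nosepokes) <- rownames(store$licks) <- NULL
  validate_store(store)
  store
}
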