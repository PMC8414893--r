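# Task-phase controller logic: the serial-reaction-time (SRT) trial state
# machine, per-phase door policies, the airpuff trigger, reward-corner
# assignment, and corner geometry. These controllers are used both by the
# mouse-agent simulator and to re-derive trial outcomes from recorded events.

PRECUE_DELAY <- 2   # s between trial initiation and LED cue onset
CUE_DURATION <- 7   # s the LED stays on awaiting a response

#' Door policy of each phase
#'
#' Free adaptation: doors always open. Door adaptation: doors open on any
#' visit. Nosepoke adaptation and retention: doors open on a nosepoke in any
#' corner. Place preference / reversal: doors open on a nosepoke only in the
#' animal's assigned corner. SRT: doors open only on a correct trial
#' response. Avoidance: doors stay closed and no water is available.
#'
#' @format Named character vector, one policy per phase.
#' @export
DOOR_POLICY <- c(free_adapt = "always_open",
                 door_adapt = "open_on_visit",
                 nosepoke_adapt = "open_on_nosepoke_any_corner",
                 place_pref = "open_on_nosepoke_correct_corner",
                 reversal = "open_on_nosepoke_correct_corner",
                 srt = "open_on_correct_srt_response",
                 avoidance = "closed",
                 delay_offcage = "closed",
                 retention = "open_on_nosepoke_any_corner")

#' Fresh SRT trial state
#'
#' The machine is `idle` until the first nosepoke of a visit in the assigned
#' corner initiates a trial; a 2-s pre-cue delay (`precue`) precedes the 7-s
#' LED cue (`cue`); after any terminal outcome the machine is
#' `locked_until_exit` until the animal leaves the corner.
#'
#' @return State list with fields `state`, `t_init`, `last_t`.
#' @export
srt_new_state <- function() {
  list(state = "idle", t_init = NA_real_, last_t = -Inf)
}

#' Advance the SRT trial state machine by one event
#'
#' Events are `nosepoke`, `corner_exit` or `clock` (pure time advance), each
#' with a time `t`; they must arrive in non-decreasing time order. A nosepoke
#' while `idle` initiates a trial at `t_init`. A nosepoke strictly inside the
#' 2-s pre-cue delay is a `premature` response; a nosepoke between cue onset
#' (`t_init + 2`) and cue offset (`t_init + 9`) is `correct` with reaction
#' time `t - (t_init + 2)`; if the clock passes `t_init + 9` with no
#' response the trial is `incorrect`. A corner exit during an active trial
#' also resolves it as `incorrect` (the animal abandoned the cue). Any
#' terminal outcome locks the machine until a corner exit; pokes while
#' locked are outside-trial and ignored.
#'
#' @param state State from [srt_new_state()] or a previous step.
#' @param event `list(type = "nosepoke"|"corner_exit"|"clock", t = seconds)`.
#' @return `list(state =, record =)`; `record` is `NULL` or
#'   `list(t_init, outcome, reaction_time)` when the step resolves a trial.
#' @export
srt_step <- function(state, event) {
  if (!event$type %in% c("nosepoke", "corner_exit", "clock"))
    stop(sprintf("unknown SRT event type '%s'", event$type), call. = FALSE)
  t <- event$t
  if (t < state$last_t)
    stop(sprintf("out-of-order event times: %g after %g", t, state$last_t),
         call. = FALSE)
  state$last_t <- t
  record <- NULL

  # time-driven resolution: cue window expired with no response
  if (state$state %in% c("precue", "cue")) {
    if (t >= state$t_init + PRECUE_DELAY) state$state <- "cue"
    if (t > state$t_init + PRECUE_DELAY + CUE_DURATION) {
      record <- list(t_init = state$t_init, outcome = "incorrect",
                     reaction_time = NA_real_)
      state$state <- "locked_until_exit"
    }
  }

  if (event$type == "nosepoke") {
    if (state$state == "idle") {
      state$state <- "precue"
      state$t_init <- t
    } else if (state$state %in% c("precue", "cue")) {
      if (t < state$t_init + PRECUE_DELAY) {
        record <- list(t_init = state$t_init, outcome = "premature",
                       reaction_time = NA_real_)
      } else {
        record <- list(t_init = state$t_init, outcome = "correct",
                       reaction_time = t - (state$t_init + PRECUE_DELAY))
      }
      state$state <- "locked_until_exit"
    }
    # locked: outside-trial poke, recorded in the raw log but not classified
  } else if (event$type == "corner_exit") {
    if (state$state %in% c("precue", "cue")) {
      record <- list(t_init = state$t_init, outcome = "incorrect",
                     reaction_time = NA_real_)
    }
    state$state <- "idle"
    state$t_init <- NA_real_
  }
  list(state = state, record = record)
}

#' Classify the SRT trial (if any) of a single visit
#'
#' Feeds the visit's nosepokes, a clock advance to the exit time, and the
#' corner exit through [srt_step()]. At most one trial is initiated per
#' visit (the first nosepoke).
#'
#' @param poke_times Numeric vector of nosepoke times within the visit.
#' @param t_exit Visit end time.
#' @return `NULL` (no trial initiated) or `list(t_init, outcome,
#'   reaction_time)`.
#' @export
srt_classify_visit <- function(poke_times, t_exit) {
  st <- srt_new_state()
  records <- list()
  for (t in sort(poke_times)) {
    out <- srt_step(st, list(type = "nosepoke", t = t))
    st <- out$state
    if (!is.null(out$record)) records[[length(records) + 1]] <- out$record
  }
  out <- srt_step(st, list(type = "clock", t = t_exit))
  st <- out$state
  if (!is.null(out$record)) records[[length(records) + 1]] <- out$record
  out <- srt_step(st, list(type = "corner_exit", t = t_exit))
  if (!is.null(out$record)) records[[length(records) + 1]] <- out$record
  if (length(records) == 0) NULL else records[[1]]
}

#' Door decision for one event under a phase's controller rule
#'
#' A pure function of the phase rule, the event type, and whether the event
#' corner matches the animal's assigned corner.
#'
#' @param phase Phase name (selects the policy from [DOOR_POLICY]).
#' @param event_type `"visit_entry"`, `"nosepoke"` or
#'   `"correct_srt_response"`.
#' @param corner Corner of the event (1-4).
#' @param assigned_corner The animal's assigned corner for this phase, or
#'   `NA` when the phase has none.
#' @return `"open"` or `"stay_closed"`.
#' @export
door_action <- function(phase, event_type, corner = NA, assigned_corner = NA) {
  policy <- DOOR_POLICY[[phase]]
  open <- switch(policy,
    always_open = TRUE,
    open_on_visit = event_type %in% c("visit_entry", "nosepoke"),
    open_on_nosepoke_any_corner = event_type == "nosepoke",
    open_on_nosepoke_correct_corner =
      event_type == "nosepoke" && !is.na(assigned_corner) &&
        corner == assigned_corner,
    open_on_correct_srt_response = event_type == "correct_srt_response",
    closed = FALSE,
    stop(sprintf("no door policy for phase '%s'", phase), call. = FALSE))
  if (open) "open" else "stay_closed"
}

#' Does a nosepoke trigger the airpuff?
#'
#' During the 24-h place-avoidance phase a nosepoke in the animal's airpuff
#' corner (its SRT corner) administers a ~0.8 bar, 1-s airpuff; visits
#' without a nosepoke do not trigger it.
#'
#' @param airpuff_corner The animal's airpuff corner.
#' @param corner Corner of the event.
#' @param event_type Event type; only `"nosepoke"` can trigger.
#' @return Logical scalar.
#' @export
airpuff_triggered <- function(airpuff_corner, corner, event_type = "nosepoke") {
  event_type == "nosepoke" && corner == airpuff_corner
}

#' Diagonally opposite corner
#'
#' Corners are indexed 1-4 clockwise, so the diagonal opposite of corner `c`
#' is `((c + 1) mod 4) + 1`; the map is an involution. Used to place the
#' reversal reward corner opposite the place-preference corner.
#'
#' @param corner Integer vector of corners in 1-4.
#' @return Integer vector of opposite corners.
#' @export
reversal_corner <- function(corner) {
  stopifnot(all(corner %in% 1:4))
  c(3L, 4L, 1L, 2L)[corner]
}

# Exact feasibility of placing n animals (n_tg of genotype TG) into four
# corners with per-corner capacity `cap` and genotype imbalance <= L: for a
# corner holding c animals, |tg - (c - tg)| <= L constrains the TG count to
# [ceil((c-L)/2), floor((c+L)/2)] (intersected with [0, c]), so an instance
# is feasible iff some size tuple (c1..c4) summing to n brackets n_tg.
# Enumerates all (cap+1)^4 tuples.
assignment_feasible <- function(n, n_tg, cap, L = 1) {
  sizes <- as.matrix(expand.grid(rep(list(0:cap), 4)))
  sizes <- sizes[rowSums(sizes) == n, , drop = FALSE]
  if (nrow(sizes) == 0) return(FALSE)
  lo <- rowSums(pmax(ceiling((sizes - L) / 2), 0))
  hi <- rowSums(pmin(floor((sizes + L) / 2), sizes))
  any(lo <= n_tg & n_tg <= hi)
}

#' Assign reward corners from prior visit habits
#'
#' Each animal is assigned one of its least-visited corners (to eliminate
#' preferential corner bias), subject to a capacity of `max_per_corner`
#' animals per corner and a per-corner genotype imbalance of at most one
#' (so a full corner of four holds two of each genotype). Animals are
#' processed in ascending id order and, among feasible corners, the least
#' visited with the lowest index is preferred; when that greedy descent
#' dead-ends, a deterministic depth-first search over the same preference
#' order completes the assignment. When the genotype mix makes a balance
#' bound of one unattainable (e.g. six survivors of one genotype and one of
#' the other), the bound is relaxed by the minimum amount that admits an
#' assignment; capacity is never relaxed.
#'
#' @param visit_counts Numeric matrix, one row per animal (rownames are
#'   animal ids), four columns of per-corner visit counts.
#' @param genotypes Character vector (`"NonTg"`/`"TG"`) named by animal id.
#' @param max_per_corner Corner capacity, default 4.
#' @return Named integer vector: corner per animal id.
#' @export
assign_corners <- function(visit_counts, genotypes, max_per_corner = 4) {
  ids <- sort(rownames(visit_counts))
  n <- length(ids)
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(genotypes)) || !all(ids %in% names(genotypes)))
    stop("genotypes must be named by animal id", call. = FALSE)
  genotypes <- genotypes[ids]
  if (!all(genotypes %in% GENOTYPES))
    stop("unknown genotype in assignment input", call. = FALSE)
  if (n > 4 * max_per_corner)
    stop(sprintf("infeasible: %d animals exceed capacity %d", n, 4 * max_per_corner),
         call. = FALSE)
  n_tg <- sum(genotypes == "TG")
  # balance bound: 1 when attainable, otherwise relaxed by the minimum
  # amount (cohorts with unequal genotype attrition can be unbalanceable,
  # e.g. 6 + 1 survivors); capacity stays strict
  L <- NA_integer_
  for (cand in seq_len(max(1, n)))
    if (assignment_feasible(n, n_tg, max_per_corner, cand)) { L <- cand; break }
  if (is.na(L))
    stop("infeasible: genotype counts cannot be placed within corner capacity",
         call. = FALSE)

  counts <- visit_counts[ids, , drop = FALSE]
  # per-animal corner preference: least-visited first, ties to lowest index
  prefs <- lapply(seq_len(n), function(i) order(counts[i, ], seq_len(4)))

  occupancy <- matrix(0L, nrow = 2, ncol = 4,
                      dimnames = list(GENOTYPES, NULL))
  assignment <- integer(n)
  g_row <- ifelse(genotypes == "TG", 2L, 1L)
  # animals of each genotype still to be placed after position i
  rem_after <- matrix(vapply(1:2, function(g)
    rev(cumsum(rev(c(g_row == g, FALSE))))[-1], numeric(n)), nrow = n)

  dfs <- function(i) {
    if (i > n)
      return(all(abs(occupancy[1, ] - occupancy[2, ]) <= L))
    g <- g_row[i]; o <- 3L - g
    for (corner in prefs[[i]]) {
      if (sum(occupancy[, corner]) >= max_per_corner) next
      # prune only when later animals of the other genotype cannot restore
      # the per-corner balance; final balance is checked at the leaf
      if (occupancy[g, corner] + 1L - occupancy[o, corner] >
          L + rem_after[i, o]) next
      occupancy[g, corner] <<- occupancy[g, corner] + 1L
      assignment[i] <<- corner
      if (dfs(i + 1L)) return(TRUE)
      occupancy[g, corner] <<- occupancy[g, corner] - 1L
    }
    FALSE
  }
  if (!dfs(1L))
    stop("infeasible corner-assignment instance", call. = FALSE)
  stats::setNames(as.integer(assignment), ids)
}
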