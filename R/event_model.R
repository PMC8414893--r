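# Event-log data model for IntelliCage-style experiments: a relational store
# of animals, visits, nosepokes, licks and the phase schedule, with a
# tab-separated on-disk dialect, validation, and 24-h day slicing.

#' Phase names of the default 29-day testing battery, in schedule order
#'
#' Free, door and nosepoke adaptation (3 days each), place preference and
#' reversal (6 days each), serial reaction time (3 days), airpuff place
#' avoidance (1 day), an off-cage delay day, and retention (3 days).
#'
#' @format Character vector of length 9.
#' @export
PHASE_LEVELS <- c("free_adapt", "door_adapt", "nosepoke_adapt",
                  "place_pref", "reversal", "srt",
                  "avoidance", "delay_offcage", "retention")

#' Default phase durations in days (total 29)
#' @format Integer vector named by phase.
#' @export
PHASE_DAYS <- c(free_adapt = 3L, door_adapt = 3L, nosepoke_adapt = 3L,
                place_pref = 6L, reversal = 6L, srt = 3L,
                avoidance = 1L, delay_offcage = 1L, retention = 3L)

GENOTYPES <- c("NonTg", "TG")
STATUSES  <- c("active", "removed_temporary", "excluded")
SIDES     <- c("left", "right")

DAY_S   <- 86400
# Session epoch (t = 0) is lights-on at 06:00; lights are on 06:00-20:00,
# so each day is 14 h light followed by 10 h dark.
LIGHT_S <- 14 * 3600

#' Build the default 29-day phase schedule
#'
#' @param epoch Start time (seconds) of the first phase; by convention the
#'   epoch coincides with lights-on (06:00).
#' @param days Named integer vector of per-phase durations; defaults to
#'   [PHASE_DAYS].
#' @return A `data.frame` with columns `phase`, `t_start`, `duration_days`,
#'   phases contiguous and non-overlapping.
#' @export
default_schedule <- function(epoch = 0, days = PHASE_DAYS) {
  stopifnot(identical(names(days), PHASE_LEVELS))
  starts <- epoch + c(0, cumsum(as.numeric(days[-length(days)]))) * DAY_S
  data.frame(phase = PHASE_LEVELS, t_start = starts,
             duration_days = as.integer(days), stringsAsFactors = FALSE)
}

empty_animals <- function()
  data.frame(animal_id = character(), genotype = character(),
             cage_id = integer(), status = character(), stringsAsFactors = FALSE)
empty_visits <- function()
  data.frame(visit_id = integer(), animal_id = character(), corner = integer(),
             t_start = numeric(), t_end = numeric(), stringsAsFactors = FALSE)
empty_nosepokes <- function()
  data.frame(visit_id = integer(), side = character(), t = numeric(),
             stringsAsFactors = FALSE)
empty_licks <- function()
  data.frame(visit_id = integer(), t = numeric(), stringsAsFactors = FALSE)
empty_assignments <- function()
  data.frame(phase = character(), animal_id = character(), corner = integer(),
             stringsAsFactors = FALSE)

#' Construct an event store
#'
#' The event store is the single source of truth for all behavioral metrics:
#' an animal roster, visit records (whole-body corner entries bounded by
#' entry/exit times), nosepoke and lick events keyed to visits, the phase
#' schedule, and per-phase reward-corner assignments.
#'
#' @param animals `data.frame(animal_id, genotype, cage_id[, status])`.
#' @param visits `data.frame(visit_id, animal_id, corner, t_start, t_end)`.
#' @param nosepokes `data.frame(visit_id, side, t)`.
#' @param licks `data.frame(visit_id, t)`.
#' @param schedule Phase schedule as from [default_schedule()].
#' @param assignments `data.frame(phase, animal_id, corner)`; may be empty.
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `event_store`.
#' @export
event_store <- function(animals = empty_animals(), visits = empty_visits(),
                        nosepokes = empty_nosepokes(), licks = empty_licks(),
                        schedule = default_schedule(),
                        assignments = empty_assignments(), validate = TRUE) {
  if (is.null(animals$status)) animals$status <- rep("active", nrow(animals))
  store <- structure(list(
    animals = normalize_rows(animals, c("animal_id", "genotype", "cage_id", "status")),
    visits = normalize_rows(visits, c("visit_id", "animal_id", "corner", "t_start", "t_end")),
    nosepokes = normalize_rows(nosepokes, c("visit_id", "side", "t")),
    licks = normalize_rows(licks, c("visit_id", "t")),
    schedule = normalize_rows(schedule, c("phase", "t_start", "duration_days")),
    assignments = normalize_rows(assignments, c("phase", "animal_id", "corner"))
  ), class = "event_store")
  store <- sort_store(store)
  if (validate) validate_store(store)
  store
}

normalize_rows <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  for (col in intersect(cols, c("visit_id", "corner", "cage_id", "duration_days")))
    df[[col]] <- as.integer(df[[col]])
  for (col in intersect(cols, c("t", "t_start", "t_end")))
    df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(cols, c("animal_id", "genotype", "status", "side", "phase")))
    df[[col]] <- as.character(df[[col]])
  df
}

sort_store <- function(store) {
  o <- function(df, ...) { df <- df[order(...), , drop = FALSE]; rownames(df) <- NULL; df }
  store$animals <- o(store$animals, store$animals$animal_id)
  store$visits <- o(store$visits, store$visits$t_start, store$visits$visit_id)
  store$nosepokes <- o(store$nosepokes, store$nosepokes$t, store$nosepokes$visit_id)
  store$licks <- o(store$licks, store$licks$t, store$licks$visit_id)
  store$schedule <- o(store$schedule, store$schedule$t_start)
  store$assignments <- o(store$assignments,
                         match(store$assignments$phase, PHASE_LEVELS),
                         store$assignments$animal_id)
  store
}

#' @export
print.event_store <- function(x, ...) {
  span <- schedule_span(x$schedule)
  cat(sprintf(paste0("<event_store> %d animals (%d cages), %d visits, ",
                     "%d nosepokes, %d licks\n  schedule: %d phases, %.1f days\n"),
              nrow(x$animals), length(unique(x$animals$cage_id)), nrow(x$visits),
              nrow(x$nosepokes), nrow(x$licks), nrow(x$schedule),
              (span[2] - span[1]) / DAY_S))
  invisible(x)
}

schedule_span <- function(schedule) {
  c(min(schedule$t_start),
    max(schedule$t_start + schedule$duration_days * DAY_S))
}

fail_row <- function(table, row, msg)
  stop(sprintf("validation error in %s row %d: %s", table, row, msg), call. = FALSE)

#' Validate an event store
#'
#' Checks every structural invariant: unique identifiers, enum domains,
#' positive visit durations, pairwise non-overlapping visits per animal,
#' referential integrity (nosepokes/licks reference existing visits, visits
#' reference existing animals), event timestamps contained in their visit
#' interval, a contiguous non-overlapping schedule, and events within the
#' schedule span. Errors name the offending table and row.
#'
#' @param store An `event_store`.
#' @return The store, invisibly, if valid; otherwise an error.
#' @export
validate_store <- function(store) {
  a <- store$animals; v <- store$visits; np <- store$nosepokes
  lk <- store$licks; sc <- store$schedule; asg <- store$assignments

  if (anyDuplicated(a$animal_id))
    fail_row("animals", anyDuplicated(a$animal_id), "duplicate animal_id")
  if (length(bad <- which(!a$genotype %in% GENOTYPES)))
    fail_row("animals", bad[1], sprintf("genotype '%s' not in {%s}",
             a$genotype[bad[1]], paste(GENOTYPES, collapse = ", ")))
  if (length(bad <- which(!a$status %in% STATUSES)))
    fail_row("animals", bad[1], sprintf("unknown status '%s'", a$status[bad[1]]))
  if (length(bad <- which(is.na(a$cage_id) | a$cage_id < 1)))
    fail_row("animals", bad[1], "cage_id must be a positive integer")

  if (nrow(sc) == 0) stop("schedule is empty", call. = FALSE)
  if (length(bad <- which(!sc$phase %in% PHASE_LEVELS)))
    fail_row("schedule", bad[1], sprintf("unknown phase '%s'", sc$phase[bad[1]]))
  if (anyDuplicated(sc$phase))
    fail_row("schedule", anyDuplicated(sc$phase), "duplicate phase")
  if (nrow(sc) > 1) {
    ends <- sc$t_start + sc$duration_days * DAY_S
    gaps <- which(abs(sc$t_start[-1] - ends[-nrow(sc)]) > 1e-9)
    if (length(gaps))
      fail_row("schedule", gaps[1] + 1, "phases must be contiguous and non-overlapping")
  }
  span <- schedule_span(sc)

  if (anyDuplicated(v$visit_id))
    fail_row("visits", anyDuplicated(v$visit_id), "duplicate visit_id")
  if (length(bad <- which(!v$animal_id %in% a$animal_id)))
    fail_row("visits", bad[1], sprintf("unknown animal_id '%s'", v$animal_id[bad[1]]))
  if (length(bad <- which(is.na(v$corner) | v$corner < 1 | v$corner > 4)))
    fail_row("visits", bad[1], "corner must be in 1..4")
  if (length(bad <- which(!(v$t_start < v$t_end))))
    fail_row("visits", bad[1], "t_start must be < t_end")
  if (length(bad <- which(v$t_start < span[1] - 1e-9 | v$t_end > span[2] + 1e-9)))
    fail_row("visits", bad[1], "visit outside the schedule span")
  # per-animal non-overlap (sorted here; incoming rows may be in any order)
  if (nrow(v) > 1) {
    for (id in unique(v$animal_id)) {
      i <- which(v$animal_id == id)
      if (length(i) > 1) {
        i <- i[order(v$t_start[i])]
        ov <- which(v$t_start[i][-1] < v$t_end[i][-length(i)] - 1e-9)
        if (length(ov))
          fail_row("visits", i[ov[1] + 1],
                   sprintf("overlaps previous visit of animal '%s'", id))
      }
    }
  }

  check_events <- function(df, table) {
    if (nrow(df) == 0) return(invisible())
    m <- match(df$visit_id, v$visit_id)
    if (anyNA(m))
      fail_row(table, which(is.na(m))[1],
               sprintf("unknown visit_id %d", df$visit_id[which(is.na(m))[1]]))
    bad <- which(df$t < v$t_start[m] - 1e-9 | df$t > v$t_end[m] + 1e-9)
    if (length(bad))
      fail_row(table, bad[1],
               sprintf("timestamp %.3f outside its visit interval [%.3f, %.3f]",
                       df$t[bad[1]], v$t_start[m[bad[1]]], v$t_end[m[bad[1]]]))
  }
  if (length(bad <- which(!np$side %in% SIDES)))
    fail_row("nosepokes", bad[1], sprintf("unknown side '%s'", np$side[bad[1]]))
  check_events(np, "nosepokes")
  check_events(lk, "licks")

  if (nrow(asg)) {
    if (length(bad <- which(!asg$phase %in% PHASE_LEVELS)))
      fail_row("assignments", bad[1], sprintf("unknown phase '%s'", asg$phase[bad[1]]))
    if (length(bad <- which(!asg$animal_id %in% a$animal_id)))
      fail_row("assignments", bad[1],
               sprintf("unknown animal_id '%s'", asg$animal_id[bad[1]]))
    if (length(bad <- which(is.na(asg$corner) | asg$corner < 1 | asg$corner > 4)))
      fail_row("assignments", bad[1], "corner must be in 1..4")
    if (anyDuplicated(asg[, c("phase", "animal_id")]))
      fail_row("assignments", anyDuplicated(asg[, c("phase", "animal_id")]),
               "duplicate (phase, animal_id)")
  }
  invisible(store)
}

STORE_FILES <- c(animals = "animals.tsv", visits = "visits.tsv",
                 nosepokes = "nosepokes.tsv", licks = "licks.tsv",
                 schedule = "schedule.tsv", assignments = "assignments.tsv")

# Full-precision decimal rendering so that write -> read round-trips exactly.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write an event store to a directory of tab-separated files
#'
#' Writes `animals.tsv`, `visits.tsv`, `nosepokes.tsv`, `licks.tsv`,
#' `schedule.tsv` and `assignments.tsv` (UTF-8, `.` decimal, header row,
#' 17-significant-digit timestamps). Output is deterministically sorted
#' (animals by id, events by time) and byte-identical across repeated calls.
#'
#' @param store A validated `event_store`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  validate_store(store)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("I/O error: cannot create directory '%s'", dir), call. = FALSE)
  for (part in names(STORE_FILES)) {
    df <- store[[part]]
    for (col in intersect(names(df), c("t", "t_start", "t_end")))
      df[[col]] <- fmt_num(df[[col]])
    path <- file.path(dir, STORE_FILES[[part]])
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("I/O error: cannot write '%s'", path), call. = FALSE)
  }
  invisible(dir)
}

#' Read an event store from a directory of tab-separated files
#'
#' Counterpart of [write_store()]; the returned store is fully validated and
#' `read_store(write_store(s)) ` reproduces `s` field by field.
#'
#' @param dir Directory containing the five event tables (and
#'   `assignments.tsv`, which may be header-only).
#' @return A validated `event_store`.
#' @export
read_store <- function(dir) {
  if (!dir.exists(dir))
    stop(sprintf("I/O error: no such directory '%s'", dir), call. = FALSE)
  read_part <- function(part) {
    path <- file.path(dir, STORE_FILES[[part]])
    if (!file.exists(path))
      stop(sprintf("I/O error: missing file '%s'", path), call. = FALSE)
    utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8")
  }
  event_store(animals = read_part("animals"), visits = read_part("visits"),
              nosepokes = read_part("nosepokes"), licks = read_part("licks"),
              schedule = read_part("schedule"),
              assignments = read_part("assignments"))
}

#' Slice a phase into its 24-h day windows
#'
#' Day windows are half-open intervals `[t0 + (k-1)*86400, t0 + k*86400)`
#' anchored at the phase start (the moment the controller program switches),
#' so that the windows of a phase partition its span and no event belongs to
#' two windows.
#'
#' @param store An `event_store` (or a bare schedule `data.frame`).
#' @param phase Phase name, one of [PHASE_LEVELS].
#' @return `data.frame(phase, day_index, t0, t1)` with one row per scheduled
#'   day.
#' @export
slice_days <- function(store, phase) {
  schedule <- if (inherits(store, "event_store")) store$schedule else store
  row <- schedule[schedule$phase == phase, , drop = FALSE]
  if (nrow(row) != 1)
    stop(sprintf("unknown phase '%s' (not in schedule)", phase), call. = FALSE)
  k <- seq_len(row$duration_days)
  data.frame(phase = phase, day_index = k,
             t0 = row$t_start + (k - 1) * DAY_S,
             t1 = row$t_start + k * DAY_S)
}

#' Extract one animal's events inside a day window
#'
#' A visit belongs to a window iff its start time lies in the half-open
#' window; the visit's nosepokes and licks follow it (single attribution, so
#' per-day counts sum exactly to whole-phase counts even for visits that
#' straddle a day boundary).
#'
#' @param store An `event_store`.
#' @param animal_id Animal identifier.
#' @param window One row of [slice_days()] output (or any list with `t0`,
#'   `t1`).
#' @return `list(visits =, nosepokes =, licks =)`, each time-sorted.
#' @export
events_in <- function(store, animal_id, window) {
  if (!animal_id %in% store$animals$animal_id)
    stop(sprintf("unknown animal '%s'", animal_id), call. = FALSE)
  v <- store$visits
  keep <- v$animal_id == animal_id & v$t_start >= window$t0 & v$t_start < window$t1
  vis <- v[keep, , drop = FALSE]
  np <- store$nosepokes[store$nosepokes$visit_id %in% vis$visit_id, , drop = FALSE]
  lk <- store$licks[store$licks$visit_id %in% vis$visit_id, , drop = FALSE]
  rownames(vis) <- rownames(np) <- rownames(lk) <- NULL
  list(visits = vis, nosepokes = np, licks = lk)
}

#' Field-by-field equality of two event stores
#' @param a,b Event stores.
#' @return Logical scalar.
#' @export
stores_equal <- function(a, b) {
  all(vapply(names(STORE_FILES), function(part)
    isTRUE(all.equal(a[[part]], b[[part]], tolerance = 0)), logical(1)))
}
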