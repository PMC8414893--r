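# Shared fixtures and independent oracles. Every oracle here is a
# deliberately plain, straight-line computation kept separate from the
# package's own code paths.

# Hand-written three-animal fixture: 6 visits, 4 nosepokes, 10 licks,
# spanning days 1-2 of free adaptation (one visit exactly on the boundary).
make_hand_store <- function() {
  animals <- data.frame(
    animal_id = c("a1", "a2", "a3"),
    genotype = c("NonTg", "TG", "NonTg"),
    cage_id = 1L)
  visits <- data.frame(
    visit_id = 1:6,
    animal_id = c("a1", "a1", "a2", "a2", "a3", "a1"),
    corner = c(1L, 2L, 1L, 3L, 4L, 1L),
    t_start = c(100, 300, 150, 86500, 500, 86400),
    t_end = c(200, 400, 260, 86600, 560, 86460))
  nosepokes <- data.frame(
    visit_id = c(1L, 1L, 3L, 4L),
    side = c("left", "right", "left", "left"),
    t = c(120, 130, 160, 86550))
  licks <- data.frame(
    visit_id = c(1L, 1L, 1L, 3L, 3L, 4L, 4L, 4L, 4L, 5L),
    t = c(121, 122, 123, 161, 162, 86551, 86552, 86553, 86554, 510))
  event_store(animals = animals, visits = visits, nosepokes = nosepokes,
              licks = licks)
}

small_cohort <- function(seed, n_nontg = 4, n_tg = 4, overrides = NULL) {
  generate_cohort(sim_config(cages = data.frame(n_nontg = n_nontg, n_tg = n_tg),
                             seed = seed, overrides = overrides))
}

# --- SRT brute-force classifier -------------------------------------------
# Classifies the (single) trial of one visit directly from the rules: the
# first poke initiates; the next poke before +2 s is premature, within
# [+2, +9] is correct; otherwise the trial times out / is abandoned as
# incorrect. No state machine involved.
brute_srt <- function(poke_times, t_exit = Inf) {
  pk <- sort(poke_times)
  if (length(pk) == 0) return(NULL)
  t0 <- pk[1]
  later <- pk[pk > t0]
  resp <- later[later <= t0 + 9]
  if (length(resp) == 0)
    return(list(outcome = "incorrect", reaction_time = NA_real_))
  r <- resp[1]
  if (r < t0 + 2) list(outcome = "premature", reaction_time = NA_real_)
  else list(outcome = "correct", reaction_time = r - (t0 + 2))
}

# --- straight-line metric recount -----------------------------------------
# Recomputes one phase's metric table directly from the raw event rows:
# per-visit poke/lick tallies built once from the raw tables, then explicit
# per-animal-per-day subsetting and sums; SRT outcomes come from brute_srt,
# not from the package's state machine.
recount_phase <- function(store, phase, animal_ids) {
  sched <- store$schedule[store$schedule$phase == phase, ]
  nd <- sched$duration_days
  v <- store$visits; np <- store$nosepokes; lk <- store$licks
  asg <- store$assignments
  npk_tab <- table(np$visit_id)
  nlk_tab <- table(lk$visit_id)
  pk_by_visit <- split(np$t, np$visit_id)
  count_of <- function(tab, ids) {
    x <- as.integer(tab[as.character(ids)])
    ifelse(is.na(x), 0L, x)
  }
  rows <- list()
  for (id in animal_ids) {
    corner <- asg$corner[asg$animal_id == id & asg$phase == phase]
    if (length(corner) == 0) corner <- NA_integer_
    for (d in seq_len(nd)) {
      w0 <- sched$t_start + (d - 1) * 86400; w1 <- w0 + 86400
      vi <- v[v$animal_id == id & v$t_start >= w0 & v$t_start < w1, ]
      n <- nrow(vi)
      has_pk <- count_of(npk_tab, vi$visit_id) > 0
      nlk <- count_of(nlk_tab, vi$visit_id)
      vals <- list(total_visits = n, total_licks = sum(nlk),
                   visits_with_nosepoke = sum(has_pk),
                   drink_motivated_fraction =
                     if (n > 0) 100 * sum(nlk > 0) / n else NA_real_)
      if (!is.na(corner)) {
        corr <- vi$corner == corner
        vals$pct_correct <- if (n > 0) 100 * sum(corr) / n else NA_real_
        vals$correct_visit_with_lick <- if (sum(corr) > 0)
          100 * sum(corr & has_pk & nlk > 0) / sum(corr) else NA_real_
        vals$airpuff_nosepoke_visits <- sum(corr & has_pk)
        vals$retention_error_pct <-
          if (n > 0) 100 * sum(corr & has_pk) / n else NA_real_
        if (phase == "srt") {
          outcomes <- character(0); rts <- numeric(0)
          for (j in which(corr)) {
            pk <- pk_by_visit[[as.character(vi$visit_id[j])]]
            if (is.null(pk)) pk <- numeric(0)
            rec <- brute_srt(pk, vi$t_end[j])
            if (!is.null(rec)) {
              outcomes <- c(outcomes, rec$outcome)
              if (rec$outcome == "correct") rts <- c(rts, rec$reaction_time)
            }
          }
          ni <- length(outcomes)
          vals$pct_initiated <- if (n > 0) 100 * ni / n else NA_real_
          vals$pct_correct <- if (ni > 0) 100 * sum(outcomes == "correct") / ni else NA_real_
          vals$pct_incorrect <- if (ni > 0) 100 * sum(outcomes == "incorrect") / ni else NA_real_
          vals$pct_premature <- if (ni > 0) 100 * sum(outcomes == "premature") / ni else NA_real_
          vals$mean_reaction_time <- if (length(rts) > 0) mean(rts) else NA_real_
        }
      }
      for (m in intersect(PHASE_METRICS[[phase]], names(vals)))
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, animal_id = id, day = d, value = vals[[m]])
    }
  }
  do.call(rbind, rows)
}

# --- cell-means RM-ANOVA oracle -------------------------------------------
# Direct sums-of-squares decomposition from explicit cell, group, day and
# subject means.
oracle_rm_anova <- function(y, group) {
  group <- factor(group)
  n <- nrow(y); d <- ncol(y); g <- nlevels(group)
  n_g <- as.vector(table(group))
  grand <- mean(y)
  subj <- rowMeans(y)
  grp <- tapply(subj, group, mean)
  day <- colMeans(y)
  cellm <- matrix(NA_real_, g, d)
  for (i in seq_len(g)) for (j in seq_len(d))
    cellm[i, j] <- mean(y[group == levels(group)[i], j])
  ss_group <- d * sum(n_g * (grp - grand)^2)
  ss_subj <- d * sum((subj - grp[group])^2)
  ss_day <- n * sum((day - grand)^2)
  ss_int <- 0
  for (i in seq_len(g)) for (j in seq_len(d))
    ss_int <- ss_int + n_g[i] * (cellm[i, j] - grp[i] - day[j] + grand)^2
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_group - ss_subj - ss_day - ss_int
  list(
    f_between = (ss_group / (g - 1)) / (ss_subj / (n - g)),
    f_within = (ss_day / (d - 1)) / (ss_resid / ((n - g) * (d - 1))),
    f_interaction = (ss_int / ((g - 1) * (d - 1))) /
      (ss_resid / ((n - g) * (d - 1))))
}

# Constraint checker for corner assignments.
check_assignment <- function(assignment, genotypes, max_per_corner = 4) {
  tab <- table(factor(assignment, levels = 1:4),
               factor(genotypes[names(assignment)], levels = c("NonTg", "TG")))
  all(rowSums(tab) <= max_per_corner) & all(abs(tab[, 1] - tab[, 2]) <= 1)
}
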