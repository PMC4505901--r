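#' Summary statistics of a set of weight ratios
#'
#' Sample mean, standard deviation (n - 1 denominator), extremes and count.
#' For a single value the SD is reported as NA (undefined by convention).
#'
#' @param values Numeric vector, n >= 1.
#' @return List with `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_ratios <- function(values) {
  if (length(values) == 0L) stop("empty ratio list")
  if (!all(is.finite(values))) stop("ratios must be finite")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       min = min(values), max = max(values), n = length(values))
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Two-sided Mann-Whitney U test. Without ties and with n1 + n2 <= 40 the
#' p-value is exact, computed by dynamic programming over the null
#' distribution of U (the count of arrangements of the two samples
#' attaining each U). With ties, or for larger samples, mid-ranks are used
#' with the normal approximation, tie-corrected variance and continuity
#' correction (the convention of common statistical toolboxes).
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `U` (statistic for `x`), `p` (two-sided),
#'   `method` ("exact" or "normal").
#' @export
mann_whitney_exact <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # mid-ranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 + n2 <= 40L) {
    counts <- u_distribution_counts(n1, n2)     # counts of U = 0..n1*n2
    total <- sum(counts)
    u <- as.integer(round(U1))
    p_lo <- sum(counts[seq_len(u + 1L)]) / total        # P(U <= u)
    p_hi <- sum(counts[(u + 1L):(n1 * n2 + 1L)]) / total  # P(U >= u)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U1, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tab <- table(r)
  tiesum <- sum(tab^3 - tab)
  N <- n1 + n2
  s2 <- n1 * n2 / 12 * ((N + 1) - tiesum / (N * (N - 1)))
  z <- (abs(U1 - mu) - 0.5) / sqrt(s2)
  z <- max(z, 0)
  list(U = U1, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

# exact null distribution of U: counts[u + 1] = number of arrangements of
# n1 + n2 distinct values with U = u. DP over the recursion
#   f(i, j, u) = f(i - 1, j, u - j) + f(i, j - 1, u)
u_distribution_counts <- function(n1, n2) {
  umax <- n1 * n2
  # f[j + 1, u + 1] for current i
  f <- matrix(0, n2 + 1L, umax + 1L)
  f[, 1L] <- 1  # i = 0: only U = 0, any j
  for (i in seq_len(n1)) {
    g <- matrix(0, n2 + 1L, umax + 1L)
    g[1L, 1L] <- 1  # j = 0: U = 0
    for (j in seq_len(n2)) {
      # adding an x above j y's shifts U by j
      shifted <- c(rep(0, j), f[j + 1L, seq_len(umax + 1L - j)])
      g[j + 1L, ] <- shifted + g[j, ]
    }
    f <- g
  }
  f[n2 + 1L, ]
}

#' Overlap of the two tasks' ratio distributions within a group
#'
#' Reports whether the ranges of the step-tracking and pursuit weight
#' ratios overlap, and by how much. Clear separation of the two tasks'
#' distributions marks intact task-dependent switching of motor commands;
#' overlap marks its loss.
#'
#' @param step,pursuit Numeric ratio vectors for the two tasks.
#' @return List with `overlap` (logical), `overlap_width` (positive width
#'   of the intersection, 0 when disjoint), `gap` (positive gap when
#'   disjoint), `step_range`, `pursuit_range`.
#' @export
compare_tasks <- function(step, pursuit) {
  if (length(step) == 0L || length(pursuit) == 0L)
    stop("both task vectors must be present")
  lo <- max(min(step), min(pursuit))
  hi <- min(max(step), max(pursuit))
  list(overlap = hi >= lo,
       overlap_width = max(0, hi - lo),
       gap = max(0, lo - hi),
       step_range = range(step), pursuit_range = range(pursuit))
}

#' Group-wise comparison of task weight ratios
#'
#' Full between-group/within-group statistical report for a cohort of
#' per-subject, per-task B/K ratios: per group-task summaries, Mann-Whitney
#' U and Student two-sample t-tests between groups for each task, and the
#' within-group step-vs-pursuit distribution overlap.
#'
#' @param cohort Data.frame with columns `subject_id`, `group`, `task`,
#'   `ratio` (long format; see [read_cohort_ratios()]).
#' @param paired_t Use a paired t-test across tasks within group instead of
#'   the between-group two-sample test? (default FALSE; between-group tests
#'   are always two-sample).
#' @return An object of class `wrist_group_comparison`: list with
#'   `summaries` (data.frame), `between_groups` (per task: U, p_mw, t,
#'   p_t), `within_groups` (per group: overlap report), `groups`, `tasks`.
#' @export
compare_groups <- function(cohort, paired_t = FALSE) {
  need <- c("subject_id", "group", "task", "ratio")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  groups <- unique(cohort$group)
  tasks <- unique(cohort$task)
  summaries <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(tasks, function(tk) {
      v <- cohort$ratio[cohort$group == g & cohort$task == tk]
      s <- summarize_ratios(v)
      data.frame(group = g, task = tk, mean = s$mean, sd = s$sd,
                 min = s$min, max = s$max, n = s$n)
    }))))
  between <- NULL
  if (length(groups) == 2L) {
    between <- do.call(rbind, lapply(tasks, function(tk) {
      a <- cohort$ratio[cohort$group == groups[1] & cohort$task == tk]
      b <- cohort$ratio[cohort$group == groups[2] & cohort$task == tk]
      mw <- mann_whitney_exact(a, b)
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(task = tk, U = mw$U, p_mw = mw$p, mw_method = mw$method,
                 t = unname(tt$statistic), p_t = tt$p.value)
    }))
  }
  within <- lapply(stats::setNames(groups, groups), function(g) {
    if (!all(c("step", "pursuit") %in%
             cohort$task[cohort$group == g])) return(NULL)
    compare_tasks(
      cohort$ratio[cohort$group == g & cohort$task == "step"],
      cohort$ratio[cohort$group == g & cohort$task == "pursuit"])
  })
  structure(list(summaries = summaries, between_groups = between,
                 within_groups = within, groups = groups, tasks = tasks),
            class = "wrist_group_comparison")
}

#' @export
print.wrist_group_comparison <- function(x, digits = 3, ...) {
  cat("Group comparison of B/K weight ratios\n\n")
  s <- x$summaries
  cat("| group | task | mean | sd | min | max | n |\n")
  cat("|---|---|---|---|---|---|---|\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("| %s | %s | %.3g | %.3g | %.3g | %.3g | %d |\n",
                s$group[i], s$task[i], s$mean[i], s$sd[i],
                s$min[i], s$max[i], s$n[i]))
  if (!is.null(x$between_groups)) {
    cat("\nBetween-group tests (per task):\n")
    b <- x$between_groups
    for (i in seq_len(nrow(b)))
      cat(sprintf(
        "  %s: Mann-Whitney U = %.1f, p = %.3g (%s); t = %.2f, p = %.3g\n",
        b$task[i], b$U[i], b$p_mw[i], b$mw_method[i], b$t[i], b$p_t[i]))
  }
  for (g in names(x$within_groups)) {
    w <- x$within_groups[[g]]
    if (is.null(w)) next
    cat(sprintf("  %s: task ranges %s (width %.3g)\n", g,
                if (w$overlap) "OVERLAP" else "disjoint",
                if (w$overlap) w$overlap_width else w$gap))
  }
  invisible(x)
}
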