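# Life stages in developmental order; order matters for the no-regression check.
STAGE_LEVELS <- c("egg", "larva", "protonymph", "deutonymph", "adult")

COHORT_COLUMNS <- c(
  "individual_id", "age", "alive", "stage",
  "eggs_laid", "kills_egg", "kills_immature", "kills_adult"
)

#' Construct a validated cohort table
#'
#' A cohort table holds one row per predator-day for a single treatment
#' (rearing origin): identity, age in days since egg deposition, survival
#' status, life stage, eggs laid that day, and prey killed that day split by
#' prey stage (egg / immature / adult).
#'
#' Validation enforces the observational protocol: non-negative ages and
#' counts, zero counts on a death row, no records after death, a contiguous
#' daily age series per individual, and a life stage that never regresses.
#' Individuals whose last record is an alive row (censored) are accepted with
#' a warning: downstream they are treated as dying the day after last
#' observation, since the design follows every female to death and censoring
#' is a data defect rather than a design feature.
#'
#' @param records data.frame with columns `individual_id`, `age`, `alive`
#'   (logical or 0/1), `stage` (one of egg, larva, protonymph, deutonymph,
#'   adult), `eggs_laid`, `kills_egg`, `kills_immature`, `kills_adult`.
#' @param treatment single character label for the cohort (e.g. "Ld").
#' @return A `cohort_table`: the validated data.frame, ordered by individual
#'   and age, with attributes `treatment` and `n_individuals`.
#' @examples
#' rec <- data.frame(
#'   individual_id = "f1", age = 0:2, alive = c(1, 1, 0),
#'   stage = c("egg", "egg", "egg"), eggs_laid = 0,
#'   kills_egg = c(0, 1, 0), kills_immature = 0, kills_adult = 0
#' )
#' cohort_table(rec, treatment = "demo")
#' @export
cohort_table <- function(records, treatment) {
  stopifnot(is.data.frame(records), length(treatment) == 1L)
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[COHORT_COLUMNS]
  records$individual_id <- as.character(records$individual_id)
  records$alive <- as.logical(records$alive)
  records$stage <- as.character(records$stage)
  for (col in c("age", "eggs_laid", "kills_egg", "kills_immature", "kills_adult")) {
    records[[col]] <- as.integer(records[[col]])
  }
  records <- records[order(records$individual_id, records$age), , drop = FALSE]
  rownames(records) <- NULL
  validate_cohort_records(records)
  structure(
    records,
    treatment = as.character(treatment),
    n_individuals = length(unique(records$individual_id)),
    class = c("cohort_table", "data.frame")
  )
}

validate_cohort_records <- function(records) {
  if (nrow(records) == 0) stop("cohort has no records")
  if (any(is.na(records[c("age", "alive", "eggs_laid", "kills_egg",
                          "kills_immature", "kills_adult")]))) {
    stop("cohort contains missing values in age/alive/count columns")
  }
  if (any(records$age < 0)) stop("negative ages present")
  counts <- as.matrix(records[c("eggs_laid", "kills_egg", "kills_immature", "kills_adult")])
  if (any(counts < 0)) stop("negative counts present")
  bad_stage <- setdiff(unique(records$stage), STAGE_LEVELS)
  if (length(bad_stage) > 0) {
    stop("unknown life stage(s): ", paste(bad_stage, collapse = ", "))
  }
  censored <- character(0)
  for (id in unique(records$individual_id)) {
    rec <- records[records$individual_id == id, , drop = FALSE]
    ages <- rec$age
    if (any(diff(ages) != 1L)) {
      stop("individual '", id, "': age series has gaps or duplicates")
    }
    dead <- which(!rec$alive)
    if (length(dead) > 0) {
      if (length(dead) > 1 || dead[1] != nrow(rec)) {
        stop("individual '", id, "': records exist after the death row")
      }
      if (sum(counts[records$individual_id == id, ][dead[1], ]) != 0) {
        stop("individual '", id, "': nonzero counts on the death row")
      }
    } else {
      censored <- c(censored, id)
    }
    stage_idx <- match(rec$stage, STAGE_LEVELS)
    if (any(diff(stage_idx) < 0)) {
      stop("individual '", id, "': life stage regresses with age")
    }
  }
  if (length(censored) > 0) {
    warning("individual(s) censored (no death row), treated as dying the day ",
            "after last observation: ", paste(censored, collapse = ", "))
  }
  invisible(records)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> treatment:", attr(x, "treatment"),
      "| individuals:", attr(x, "n_individuals"),
      "| predator-days:", nrow(x), "\n")
  NextMethod()
}

#' Read a cohort from CSV
#'
#' Expects one row per predator-day with header
#' `individual_id,age,alive,stage,eggs_laid,kills_egg,kills_immature,kills_adult`
#' (UTF-8, comma-separated). `alive` is 0/1.
#'
#' @param path path to the CSV file.
#' @param treatment label attached to the cohort.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, treatment) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  records <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e))
  )
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("'", path, "': header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("age", "alive", "eggs_laid", "kills_egg", "kills_immature", "kills_adult")) {
    v <- records[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("'", path, "' line ", bad + 1L, ": non-numeric value in column '", col, "'")
    }
  }
  cohort_table(records, treatment)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; the reader round-trips its output exactly.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  out$alive <- as.integer(out$alive)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Age-period partition of the predator life cycle
#'
#' Splits life into three periods: development plus preoviposition
#' (ages 0..b1), a window comparable to the generation time (b1+1..b2), and
#' residual life (b2+1 to death). Defaults b1 = 9, b2 = 29 match a phytoseiid
#' partition of 0-9 / 10-29 / 30+ days.
#'
#' @param b1,b2 integer boundary ages, `0 < b1 < b2`.
#' @return A `period_partition` object.
#' @export
period_partition <- function(b1 = 9, b2 = 29) {
  b1 <- as.integer(b1); b2 <- as.integer(b2)
  if (!(b1 > 0 && b2 > b1)) stop("require 0 < b1 < b2")
  structure(list(b1 = b1, b2 = b2), class = "period_partition")
}

period_of_age <- function(age, partition) {
  findInterval(age, c(-Inf, partition$b1 + 1L, partition$b2 + 1L))
}

period_labels <- function(partition) {
  c(sprintf("0-%d", partition$b1),
    sprintf("%d-%d", partition$b1 + 1L, partition$b2),
    sprintf(">=%d", partition$b2 + 1L))
}

#' Build age-specific life-table schedules from a cohort
#'
#' Computes, for integer ages x = 0..x_max (x_max = last age any individual
#' was alive):
#' \describe{
#'   \item{lx}{fraction of the starting cohort alive at age x (non-increasing,
#'     lx\[0\] = 1 when observation starts at age 0).}
#'   \item{mx}{mean eggs laid per *living* female at age x.}
#'   \item{kx}{mean prey killed per *living* female at age x, with the
#'     stage-resolved components `kx_egg`, `kx_immature`, `kx_adult` summing
#'     to kx exactly.}
#' }
#' Rates are conditional on survival — a dead predator cannot kill — so
#' mortality enters the demographic rates only through lx. Ages at which no
#' individual is alive get rate 0. Censored individuals count as dead from
#' the day after their last observation.
#'
#' @param cohort a [cohort_table()].
#' @return A `life_schedule` data.frame with columns
#'   `x, lx, mx, kx, kx_egg, kx_immature, kx_adult` and attributes
#'   `treatment`, `n_individuals`.
#' @export
build_life_schedule <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- attr(cohort, "n_individuals")
  live <- cohort[cohort$alive, , drop = FALSE]
  if (nrow(live) == 0) stop("cohort has no alive records")
  x_max <- max(live$age)
  ages <- 0:x_max
  f_age <- factor(live$age, levels = ages)
  alive_n <- as.integer(table(f_age))
  sum_by_age <- function(col) {
    as.numeric(tapply(live[[col]], f_age, sum, default = 0))
  }
  mean_by_age <- function(col) ifelse(alive_n > 0, sum_by_age(col) / alive_n, 0)
  kx_egg <- mean_by_age("kills_egg")
  kx_imm <- mean_by_age("kills_immature")
  kx_adu <- mean_by_age("kills_adult")
  schedule <- data.frame(
    x = ages,
    lx = alive_n / n,
    mx = mean_by_age("eggs_laid"),
    kx = kx_egg + kx_imm + kx_adu,
    kx_egg = kx_egg,
    kx_immature = kx_imm,
    kx_adult = kx_adu
  )
  structure(schedule,
            treatment = attr(cohort, "treatment"),
            n_individuals = n,
            class = c("life_schedule", "data.frame"))
}

#' @export
print.life_schedule <- function(x, ...) {
  cat("<life_schedule> treatment:", attr(x, "treatment"),
      "| n =", attr(x, "n_individuals"),
      "| ages 0 -", max(x$x), "\n")
  NextMethod()
}

#' Write a life schedule to CSV
#'
#' Columns `x, lx, mx, kx, kx_egg, kx_immature, kx_adult`.
#'
#' @param schedule a `life_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_life_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "life_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot survival, predation and net predation schedules
#'
#' Three stacked panels: lx, kx and the net predation curve lx*kx against
#' age, the standard graphical summary of a predation life table.
#'
#' @param x a `life_schedule`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.life_schedule <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$x, x$lx, type = "s", xlab = "", ylab = "lx",
                 main = attr(x, "treatment"), ylim = c(0, 1), ...)
  graphics::plot(x$x, x$kx, type = "h", xlab = "", ylab = "kx (prey/day)", ...)
  graphics::plot(x$x, x$lx * x$kx, type = "h",
                 xlab = "age (days)", ylab = "lx * kx", ...)
  invisible(x)
}

#' Per-period summaries of daily kills and fecundity
#'
#' For each life-cycle period of `partition`, summarises over individuals the
#' per-individual daily mean (and per-individual total) of prey kills — in
#' total and by prey stage — and of eggs laid. An individual's daily mean in
#' a period is its period total divided by the number of days it was alive
#' within the period; individuals with no living day in a period do not
#' contribute to that period (a period with no survivors is reported as
#' undefined, not zero).
#'
#' Fecundity summaries by default cover ovipositing females only (those
#' laying at least one egg within the period), matching how period fecundity
#' tables for such experiments are conventionally reported; use
#' `fecundity = "all"` to include every female alive in the period.
#'
#' @param cohort a [cohort_table()].
#' @param partition a [period_partition()].
#' @param fecundity `"ovipositing"` (default) or `"all"`.
#' @return A data.frame with one row per (period, variable): n, mean daily
#'   rate, SD and SE over individuals, and the mean/SD of per-individual
#'   period totals. Variables: kills, kills_egg, kills_immature, kills_adult,
#'   eggs.
#' @export
period_summary <- function(cohort, partition = period_partition(),
                           fecundity = c("ovipositing", "all")) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(partition, "period_partition"))
  fecundity <- match.arg(fecundity)
  live <- cohort[cohort$alive, , drop = FALSE]
  live$period <- period_of_age(live$age, partition)
  live$kills <- live$kills_egg + live$kills_immature + live$kills_adult
  vars <- c(kills = "kills", kills_egg = "kills_egg",
            kills_immature = "kills_immature", kills_adult = "kills_adult",
            eggs = "eggs_laid")
  labels <- period_labels(partition)
  out <- list()
  for (p in 1:3) {
    seg <- live[live$period == p, , drop = FALSE]
    for (v in names(vars)) {
      if (nrow(seg) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          period = labels[p], variable = v, n = 0L,
          daily_mean = NA_real_, daily_sd = NA_real_, daily_se = NA_real_,
          total_mean = NA_real_, total_sd = NA_real_, defined = FALSE
        )
        next
      }
      totals <- tapply(seg[[vars[[v]]]], seg$individual_id, sum)
      days <- tapply(seg$age, seg$individual_id, length)
      if (v == "eggs" && fecundity == "ovipositing") {
        keep <- totals > 0
        totals <- totals[keep]; days <- days[keep]
      }
      n_ind <- length(totals)
      if (n_ind == 0) {
        out[[length(out) + 1L]] <- data.frame(
          period = labels[p], variable = v, n = 0L,
          daily_mean = NA_real_, daily_sd = NA_real_, daily_se = NA_real_,
          total_mean = NA_real_, total_sd = NA_real_, defined = FALSE
        )
        next
      }
      daily <- as.numeric(totals) / as.numeric(days)
      out[[length(out) + 1L]] <- data.frame(
        period = labels[p], variable = v, n = n_ind,
        daily_mean = mean(daily),
        daily_sd = if (n_ind > 1) stats::sd(daily) else 0,
        daily_se = if (n_ind > 1) stats::sd(daily) / sqrt(n_ind) else 0,
        total_mean = mean(as.numeric(totals)),
        total_sd = if (n_ind > 1) stats::sd(as.numeric(totals)) else 0,
        defined = TRUE
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "treatment") <- attr(cohort, "treatment")
  res
}
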