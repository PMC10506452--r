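# Euler-Lotka residual: f(k) = sum_x e^(-k x) * net_x - 1, strictly
# decreasing in k whenever any net production occurs at x > 0.
lotka_residual <- function(k, x, net) {
  sum(exp(-k * x) * net) - 1
}

# Shared root solver for Lotka-type equations on a discrete schedule.
# Brent's method on a bracket; the bracket is widened upward if needed.
lotka_root <- function(x, net, tolerance = 1e-10, lower = -1, upper = 10) {
  keep <- net > 0
  x <- x[keep]; net <- net[keep]
  total <- sum(net)
  if (total == 0) stop("schedule has zero net production; no rate defined")
  if (all(x == 0)) stop("all net production at age 0; Euler-Lotka rate undefined")
  if (sum(net[x == 0]) >= 1) {
    stop("net production at age 0 is >= 1; the Euler-Lotka residual never ",
         "falls below zero and no finite rate exists")
  }
  while (lotka_residual(upper, x, net) > 0) upper <- upper * 2
  while (lotka_residual(lower, x, net) < 0) lower <- lower - 1
  root <- stats::uniroot(lotka_residual, x = x, net = net,
                         lower = lower, upper = upper,
                         tol = .Machine$double.eps^0.5, maxiter = 2000L)$root
  # polish on the residual scale so |f(root)| <= tolerance
  for (i in 1:100) {
    f <- lotka_residual(root, x, net)
    if (abs(f) <= tolerance) break
    # Newton step; derivative is -sum(x e^{-kx} net) < 0
    d <- -sum(x * exp(-root * x) * net)
    root <- root - f / d
  }
  if (total <= 1) {
    warning("net production per individual is <= 1; rate is non-positive")
  }
  root
}

#' Net consumption rate and mean predation time
#'
#' `K0 = sum_x lx * kx` is the number of prey killed per predator over a
#' generation, corrected by age-specific mortality. `Tk` is the mean age of
#' net prey consumption, `sum_x x * lx * kx / sum_x lx * kx` — the time over
#' which a cohort effectively predates at rate K0.
#'
#' @param schedule a `life_schedule` from [build_life_schedule()].
#' @return list with `K0`, `Tk` and `Tk_defined` (`FALSE` with `Tk = NA`
#'   when the predation schedule is all zero).
#' @examples
#' sched <- manual_schedule(lx = c(1, 1, 0.5), kx = c(0, 2, 4))
#' net_rates(sched) # K0 = 4, Tk = 1.5
#' @export
net_rates <- function(schedule) {
  stopifnot(inherits(schedule, "life_schedule"))
  net <- schedule$lx * schedule$kx
  K0 <- sum(net)
  if (K0 <= 0) {
    return(list(K0 = 0, Tk = NA_real_, Tk_defined = FALSE))
  }
  list(K0 = K0, Tk = sum(schedule$x * net) / K0, Tk_defined = TRUE)
}

#' Solve the Euler-Lotka equation for the pest kill rate
#'
#' The pest kill rate km is the lifetime-weighted average daily killing of
#' the pest: the unique real root of
#' \deqn{\sum_x e^{-k_m x} l_x k_x = 1,}
#' the Euler-Lotka equation with age-specific predation substituted for
#' age-specific fertility. The residual is strictly decreasing in k for any
#' non-degenerate schedule, so the root is unique; it is located by Brent
#' bracketing and polished by Newton steps until the residual is below
#' `tolerance`.
#'
#' @param schedule a `life_schedule`.
#' @param tolerance bound on the Euler-Lotka residual at the returned root.
#' @return km (per day). If the net lifetime predation K0 is at most 1 the
#'   root is non-positive and a warning is raised; K0 = 0 is an error.
#' @examples
#' # all net predation at age 2 with total 4: km = log(4)/2
#' sched <- manual_schedule(lx = c(1, 1, 1), kx = c(0, 0, 4))
#' solve_kill_rate(sched)
#' @export
solve_kill_rate <- function(schedule, tolerance = 1e-10) {
  stopifnot(inherits(schedule, "life_schedule"), tolerance > 0)
  lotka_root(schedule$x, schedule$lx * schedule$kx, tolerance)
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Applies the same solver to the fertility schedule lx * mx, optionally
#' scaled by the fraction of offspring that are female. Also returns the net
#' reproductive rate `R0 = sum lx * mx * female_fraction` and the mean
#' generation time `T = sum x * lx * mx / sum lx * mx`.
#'
#' @param schedule a `life_schedule`.
#' @param female_fraction proportion of eggs that are daughters, in (0, 1].
#'   Default 1 (raw eggs).
#' @param tolerance residual bound, as in [solve_kill_rate()].
#' @return list with `R0`, `T`, `rm`.
#' @export
solve_intrinsic_rate <- function(schedule, female_fraction = 1, tolerance = 1e-10) {
  stopifnot(inherits(schedule, "life_schedule"),
            female_fraction > 0, female_fraction <= 1)
  net <- schedule$lx * schedule$mx * female_fraction
  if (sum(net) <= 0) stop("fertility schedule is all zero; rm undefined")
  list(
    R0 = sum(net),
    T = sum(schedule$x * net) / sum(net),
    rm = lotka_root(schedule$x, net, tolerance)
  )
}

#' Doubling time of an exponential rate
#'
#' `ln(2) / rate`: the days a population growing (or predating) at `rate`
#' needs to double.
#'
#' @param rate per-day rate, must be positive.
#' @return days.
#' @examples
#' doubling_time(0.515) # 1.35 days
#' @export
doubling_time <- function(rate) {
  stopifnot(is.numeric(rate))
  if (any(rate <= 0)) stop("doubling time requires a positive rate")
  log(2) / rate
}

#' All demographic rates for one schedule
#'
#' Convenience wrapper computing K0, Tk, km (Euler-Lotka root), the
#' log-ratio approximation `km_approx = ln(K0)/Tk`, R0, T, rm and the
#' doubling times of km and rm. `km_approx` is reported descriptively: by
#' Jensen's inequality `ln(K0)/Tk <= km`, with equality only when all net
#' predation falls at a single age, so the two can differ appreciably for
#' spread-out predation schedules. `Tk_implied = ln(K0)/km` is the single-age
#' predation time that would reproduce km exactly.
#'
#' @param schedule a `life_schedule`.
#' @param female_fraction passed to [solve_intrinsic_rate()]; set `NA` to
#'   skip the fertility-based rates (e.g. schedules without oviposition).
#' @param tolerance Euler-Lotka residual bound.
#' @return A `demographic_rates` list.
#' @export
demographic_rates <- function(schedule, female_fraction = 1, tolerance = 1e-10) {
  nr <- net_rates(schedule)
  if (nr$K0 <= 0) stop("no net predation; demographic rates undefined")
  km <- solve_kill_rate(schedule, tolerance)
  fert <- if (!is.na(female_fraction) && sum(schedule$lx * schedule$mx) > 0) {
    solve_intrinsic_rate(schedule, female_fraction, tolerance)
  } else {
    list(R0 = NA_real_, T = NA_real_, rm = NA_real_)
  }
  structure(list(
    treatment = attr(schedule, "treatment"),
    K0 = nr$K0,
    Tk = nr$Tk,
    km = km,
    km_approx = log(nr$K0) / nr$Tk,
    Tk_implied = log(nr$K0) / km,
    R0 = fert$R0,
    T = fert$T,
    rm = fert$rm,
    doubling_km = if (km > 0) doubling_time(km) else NA_real_,
    doubling_rm = if (!is.na(fert$rm) && fert$rm > 0) doubling_time(fert$rm) else NA_real_
  ), class = "demographic_rates")
}

#' @export
print.demographic_rates <- function(x, ...) {
  cat("<demographic_rates>", if (!is.null(x$treatment)) x$treatment else "", "\n")
  cat(sprintf("  K0 (net consumption)    %10.2f prey/female\n", x$K0))
  cat(sprintf("  Tk (mean predation age) %10.2f d\n", x$Tk))
  cat(sprintf("  km (pest kill rate)     %10.4f /d   doubling %.2f d\n",
              x$km, x$doubling_km))
  cat(sprintf("  ln(K0)/Tk               %10.4f /d\n", x$km_approx))
  if (!is.na(x$rm)) {
    cat(sprintf("  R0 %8.2f   T %6.2f d   rm %7.4f /d   doubling %.2f d\n",
                x$R0, x$T, x$rm, x$doubling_rm))
  }
  invisible(x)
}

#' Assemble a life schedule directly from vectors
#'
#' Mainly for worked examples and tests: builds a `life_schedule` from
#' explicit lx / kx (and optionally mx) vectors without an underlying
#' cohort. `lx` must start at 1 and be non-increasing.
#'
#' @param lx survival proportions, `lx[1]` at age 0.
#' @param kx daily kill rates, same length.
#' @param mx daily fecundities, same length (default all zero).
#' @param treatment optional label.
#' @return A `life_schedule`.
#' @export
manual_schedule <- function(lx, kx, mx = rep(0, length(lx)), treatment = "manual") {
  stopifnot(length(lx) == length(kx), length(mx) == length(lx))
  if (abs(lx[1] - 1) > 1e-12 || any(diff(lx) > 1e-12) || any(lx < 0 | lx > 1)) {
    stop("lx must start at 1, lie in [0,1] and be non-increasing")
  }
  if (any(kx < 0) || any(mx < 0)) stop("kx and mx must be non-negative")
  structure(data.frame(
    x = seq_along(lx) - 1L, lx = lx, mx = mx, kx = kx,
    kx_egg = kx, kx_immature = 0, kx_adult = 0
  ), treatment = treatment, n_individuals = NA_integer_,
  class = c("life_schedule", "data.frame"))
}
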