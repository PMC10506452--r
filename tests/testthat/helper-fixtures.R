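# Independent plain bisection root-finder for the Euler-Lotka residual
# sum(exp(-k*x) * net) - 1 on a fixed bracket. Used as the oracle against
# the package's solver; deliberately shares no code with it.
bisect_lotka <- function(x, net, lo = -1, hi = 10, iters = 200) {
  f <- function(k) sum(exp(-k * x) * net) - 1
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Build a cohort from per-individual daily kill (and optionally egg)
# vectors: individual i is alive on ages 0..length(kills[[i]])-1, then dies.
toy_cohort <- function(kills, eggs = NULL, treatment = "toy") {
  recs <- lapply(seq_along(kills), function(i) {
    k <- kills[[i]]
    e <- if (is.null(eggs)) rep(0L, length(k)) else eggs[[i]]
    days <- length(k)
    data.frame(
      individual_id = sprintf("i%02d", i),
      age = c(0:(days - 1L), days),
      alive = c(rep(TRUE, days), FALSE),
      stage = "adult",
      eggs_laid = c(e, 0L),
      kills_egg = c(k, 0L),
      kills_immature = 0L,
      kills_adult = 0L
    )
  })
  cohort_table(do.call(rbind, recs), treatment)
}

# random valid predation schedule for solver property tests; guarantees
# K0 > 1 and some predation at a positive age
random_schedule <- function() {
  len <- sample(5:40, 1)
  lx <- cumprod(c(1, runif(len - 1, 0.8, 1)))
  kx <- rpois(len, lambda = runif(1, 0.5, 8)) * rbinom(len, 1, 0.8)
  kx[1] <- 0 # no kills at age 0, else no finite Euler-Lotka root may exist
  if (sum(lx * kx) <= 1.1 || sum(kx[-1]) == 0) return(random_schedule())
  manual_schedule(lx = lx, kx = kx)
}

# deterministic pseudovalue vector with exact mean m and SE-of-mean se
matched_pseudovalues <- function(m, se, n = 15) {
  z <- seq(-1, 1, length.out = n)
  m + (z - mean(z)) / stats::sd(z) * se * sqrt(n)
}
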