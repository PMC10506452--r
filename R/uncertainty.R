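#' Generic leave-one-out jackknife of a statistic
#'
#' Core resampling engine: for a statistic `theta_fn` evaluated on a set of
#' items, forms the pseudovalues `v_i = n * theta(all) - (n - 1) * theta(-i)`,
#' whose mean is the bias-reduced jackknife estimate and whose standard
#' deviation over sqrt(n) estimates its standard error. A t-based
#' `(1 - alpha)` interval on n - 1 degrees of freedom completes the summary.
#'
#' @param theta_fn function taking a vector of item indices and returning a
#'   scalar statistic computed from those items.
#' @param n number of items.
#' @param alpha significance level for the interval (default 0.05).
#' @return list with `full_estimate`, `pseudovalues`, `estimate` (pseudovalue
#'   mean), `se`, `interval`, `df`, `alpha`, `n`.
#' @export
jackknife_estimate <- function(theta_fn, n, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  theta_all <- theta_fn(seq_len(n))
  theta_loo <- vapply(seq_len(n), function(i) theta_fn(setdiff(seq_len(n), i)),
                      numeric(1))
  pseudo <- n * theta_all - (n - 1) * theta_loo
  est <- mean(pseudo)
  se <- stats::sd(pseudo) / sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  list(
    full_estimate = theta_all,
    pseudovalues = pseudo,
    estimate = est,
    se = se,
    interval = c(est - tcrit * se, est + tcrit * se),
    df = n - 1L,
    alpha = alpha,
    n = n
  )
}

#' Jackknife a Lotka-type rate over the individuals of a cohort
#'
#' Re-fits the whole pipeline — rebuild the life schedule from the n - 1
#' remaining individuals, re-solve the Euler-Lotka equation — for each
#' leave-one-out subset, and summarises the rate by jackknife pseudovalues
#' with a t-interval. This propagates between-individual variation in
#' survival, predation and fecundity into an interval of uncertainty for the
#' nonlinear rate.
#'
#' @param cohort a [cohort_table()] with at least 2 individuals.
#' @param rate_kind `"km"` (pest kill rate) or `"rm"` (intrinsic rate of
#'   increase).
#' @param alpha significance level (default 0.05).
#' @param female_fraction passed to [solve_intrinsic_rate()] when
#'   `rate_kind = "rm"`.
#' @param tolerance Euler-Lotka residual bound.
#' @return A `jackknife_result`: treatment, n, `full_estimate`,
#'   `pseudovalues`, `estimate`, `se`, `interval`, `alpha`.
#' @export
jackknife_rate <- function(cohort, rate_kind = c("km", "rm"), alpha = 0.05,
                           female_fraction = 1, tolerance = 1e-10) {
  stopifnot(inherits(cohort, "cohort_table"))
  rate_kind <- match.arg(rate_kind)
  ids <- unique(cohort$individual_id)
  n <- length(ids)
  if (n < 2) stop("jackknife requires at least 2 individuals")
  treatment <- attr(cohort, "treatment")
  # Per-age net production of a sub-cohort: since kx is the mean over
  # individuals alive at x and lx the alive fraction, lx * kx reduces to
  # (summed counts at age x) / n. One count matrix therefore gives every
  # leave-one-out schedule without rebuilding cohorts.
  live <- cohort[cohort$alive, , drop = FALSE]
  x_max <- max(live$age)
  counts <- if (rate_kind == "km") {
    live$kills_egg + live$kills_immature + live$kills_adult
  } else {
    live$eggs_laid * female_fraction
  }
  cmat <- matrix(0, nrow = n, ncol = x_max + 1L,
                 dimnames = list(ids, NULL))
  idx <- cbind(match(live$individual_id, ids), live$age + 1L)
  cmat[idx] <- counts
  ages <- 0:x_max
  rate_of <- function(keep) {
    net <- colSums(cmat[keep, , drop = FALSE]) / length(keep)
    if (sum(net) <= 0) {
      stop("leave-one-out sub-cohort (dropping individual '",
           paste(setdiff(ids, ids[keep]), collapse = ","),
           "') has zero net ", if (rate_kind == "km") "predation" else "fertility",
           "; jackknife aborted")
    }
    lotka_root(ages, net, tolerance)
  }
  jk <- jackknife_estimate(rate_of, n, alpha)
  structure(c(list(treatment = treatment, rate_kind = rate_kind), jk),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> %s %s: %.4f (full %.4f) +/- %.4f SE, %d%% CI [%.4f, %.4f], n = %d\n",
              x$treatment, x$rate_kind, x$estimate, x$full_estimate, x$se,
              round(100 * (1 - x$alpha)), x$interval[1], x$interval[2], x$n))
  invisible(x)
}

# Construct a jackknife_result from summary components (pseudovalues given
# directly); used when comparing groups whose pseudovalues come from
# elsewhere.
#' Bundle precomputed pseudovalues as a jackknife result
#'
#' Builds a `jackknife_result` from an explicit pseudovalue vector, e.g. to
#' feed [newman_keuls()] with groups whose leave-one-out fits were run
#' separately.
#'
#' @param pseudovalues numeric vector of jackknife pseudovalues.
#' @param treatment group label.
#' @param alpha significance level.
#' @param full_estimate optional all-data estimate (defaults to the
#'   pseudovalue mean).
#' @return A `jackknife_result`.
#' @export
jackknife_from_pseudovalues <- function(pseudovalues, treatment, alpha = 0.05,
                                        full_estimate = mean(pseudovalues)) {
  n <- length(pseudovalues)
  stopifnot(n >= 2)
  est <- mean(pseudovalues)
  se <- stats::sd(pseudovalues) / sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  structure(list(
    treatment = treatment, rate_kind = "supplied",
    full_estimate = full_estimate, pseudovalues = pseudovalues,
    estimate = est, se = se,
    interval = c(est - tcrit * se, est + tcrit * se),
    df = n - 1L, alpha = alpha, n = n
  ), class = "jackknife_result")
}

#' Newman-Keuls sequential comparison of jackknifed rates
#'
#' Ranks the group estimates and applies the sequential studentized-range
#' procedure: the stretch of r adjacent ordered means spanning groups i..j is
#' declared heterogeneous when its extreme difference exceeds
#' `q(1 - alpha; r, df)` times the standard error of that difference; a
#' non-significant stretch is not subdivided, so all pairs inside it are
#' declared not different. Degrees of freedom are pooled over groups,
#' `df = sum(n_i - 1)`.
#'
#' Two error terms are available. `"pairwise"` (default) uses the
#' group-specific jackknife variances, `SE_diff = sqrt(se_i^2 + se_j^2)` —
#' appropriate when pseudovalue dispersion differs between groups, as
#' jackknifed nonlinear rates typically do. `"pooled"` uses the classical
#' common error term `sqrt(2 * s2_pooled / n_h)` from the pooled pseudovalue
#' variance (n_h the harmonic mean group size).
#'
#' @param groups list of `jackknife_result` objects (>= 2), e.g. from
#'   [jackknife_rate()] or [jackknife_from_pseudovalues()].
#' @param alpha significance level (default 0.05).
#' @param method `"pairwise"` or `"pooled"` error term.
#' @return A `nk_comparison`: `table` (treatment, estimate, se, n, letters,
#'   ordered by estimate), `different` (logical matrix of pairwise
#'   decisions), `alpha`, `method`, `df`.
#' @export
newman_keuls <- function(groups, alpha = 0.05, method = c("pairwise", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(groups) >= 2)
  ok <- vapply(groups, inherits, logical(1), what = "jackknife_result")
  if (!all(ok)) stop("groups must be jackknife_result objects")
  ns <- vapply(groups, `[[`, numeric(1), "n")
  if (any(ns < 2)) stop("every group needs at least 2 pseudovalues")
  labels <- vapply(groups, `[[`, character(1), "treatment")
  est <- vapply(groups, `[[`, numeric(1), "estimate")
  se <- vapply(groups, `[[`, numeric(1), "se")
  # ties in ranked means broken by label order (deterministic)
  ord <- order(est, labels)
  labels <- labels[ord]; est <- est[ord]; se <- se[ord]; ns <- ns[ord]
  k <- length(est)
  df <- sum(ns - 1)
  # pooled pseudovalue variance; var_i = se_i^2 * n_i
  s2_pooled <- sum((ns - 1) * se^2 * ns) / df
  n_h <- k / sum(1 / ns)
  se_diff <- function(i, j) {
    if (method == "pairwise") sqrt(se[i]^2 + se[j]^2)
    else sqrt(2 * s2_pooled / n_h)
  }
  different <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  # sequential rule, stretches processed from the full range downward: a
  # stretch contained in an already-accepted homogeneous stretch is not
  # tested (and its pairs stay "not different"); otherwise its extreme
  # difference is compared with the studentized range at r means
  homogeneous <- list()
  protected <- function(lo, hi) {
    any(vapply(homogeneous, function(h) h[1] <= lo && hi <= h[2], logical(1)))
  }
  for (r in k:2) {
    for (lo in 1:(k - r + 1L)) {
      hi <- lo + r - 1L
      if (protected(lo, hi)) next
      qobs <- (est[hi] - est[lo]) / se_diff(lo, hi)
      qcrit <- stats::qtukey(1 - alpha, nmeans = r, df = df)
      if (qobs > qcrit) {
        different[lo, hi] <- different[hi, lo] <- TRUE
      } else {
        homogeneous[[length(homogeneous) + 1L]] <- c(lo, hi)
      }
    }
  }
  letters_vec <- nk_letters(different)
  tab <- data.frame(treatment = labels, estimate = est, se = se, n = ns,
                    letters = letters_vec, row.names = NULL)
  structure(list(table = tab, different = different, alpha = alpha,
                 method = method, df = df),
            class = "nk_comparison")
}

# Compact letter display for decisions on means ordered ascending. Under the
# sequential rule, non-different sets are contiguous stretches of the
# ordering, so letters are the maximal stretches of mutual non-difference.
nk_letters <- function(different) {
  k <- nrow(different)
  runs <- list()
  for (lo in 1:k) {
    hi <- lo
    while (hi < k && !any(different[lo:(hi + 1L), lo:(hi + 1L)])) hi <- hi + 1L
    runs[[length(runs) + 1L]] <- c(lo, hi)
  }
  # keep maximal runs only
  keep <- vapply(seq_along(runs), function(i) {
    !any(vapply(seq_along(runs), function(j) {
      j != i && runs[[j]][1] <= runs[[i]][1] && runs[[j]][2] >= runs[[i]][2]
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  out <- character(k)
  for (i in seq_along(runs)) {
    idx <- runs[[i]][1]:runs[[i]][2]
    out[idx] <- paste0(out[idx], letters[i])
  }
  out
}

#' @export
print.nk_comparison <- function(x, ...) {
  cat(sprintf("<nk_comparison> Newman-Keuls sequential test, alpha = %g, %s error, df = %d\n",
              x$alpha, x$method, x$df))
  print(x$table, row.names = FALSE)
  cat("groups sharing a letter are not declared different\n")
  invisible(x)
}
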