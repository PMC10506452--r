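test_that("jackknife of a sample mean reduces to the classical SE exactly", {
  set.seed(71)
  xs <- rnorm(12, mean = 3, sd = 2)
  jk <- jackknife_estimate(function(idx) mean(xs[idx]), n = length(xs))
  # pseudovalues of the mean are the data themselves
  expect_equal(sort(jk$pseudovalues), sort(xs))
  expect_equal(jk$estimate, mean(xs))
  expect_equal(jk$se, sd(xs) / sqrt(length(xs)))
  # interval geometry
  tcrit <- qt(0.975, length(xs) - 1)
  expect_equal(diff(jk$interval), 2 * tcrit * jk$se)
  expect_true(jk$interval[1] <= jk$estimate && jk$estimate <= jk$interval[2])
})

test_that("a cohort of identical clones has zero jackknife SE", {
  kills <- rep(list(c(0L, 1L, 3L, 5L, 5L, 5L)), 5)
  co <- toy_cohort(kills)
  jk <- jackknife_rate(co, "km")
  expect_equal(jk$se, 0)
  expect_equal(jk$estimate, jk$full_estimate)
  expect_equal(jk$interval, rep(jk$estimate, 2))
})

test_that("pseudovalues match a hand enumeration on a 3-individual cohort", {
  kills <- list(c(0L, 2L, 4L), c(0L, 3L, 3L, 2L), c(1L, 5L, 2L))
  co <- toy_cohort(kills)
  jk <- jackknife_rate(co, "km")
  # brute force: rebuild each leave-one-out schedule and bisect the root
  km_of <- function(keep) {
    sub <- toy_cohort(kills[keep])
    sched <- build_life_schedule(sub)
    bisect_lotka(sched$x, sched$lx * sched$kx)
  }
  theta_all <- km_of(1:3)
  pseudo <- sapply(1:3, function(i) 3 * theta_all - 2 * km_of(setdiff(1:3, i)))
  expect_equal(jk$full_estimate, theta_all, tolerance = 1e-8)
  expect_equal(jk$pseudovalues, pseudo, tolerance = 1e-7)
  expect_equal(jk$estimate, mean(pseudo), tolerance = 1e-7)
})

test_that("a leave-one-out subset without predation aborts with a diagnostic", {
  kills <- list(c(0L, 2L, 4L), c(0L, 0L, 0L), c(0L, 0L))
  co <- toy_cohort(kills)
  expect_error(jackknife_rate(co, "km"), "zero net predation")
})

test_that("jackknife intervals cover the large-cohort kill rate at nominal level", {
  cfg <- preset_configs()$Ld
  big <- simulate_cohort(cfg, n_females = 3000, seed = 99)
  km_limit <- solve_kill_rate(build_life_schedule(big))
  set.seed(100)
  n_rep <- 200
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(cfg, n_females = 15, seed = NULL)
    jk <- jackknife_rate(co, "km")
    covered[r] <- jk$interval[1] <= km_limit && km_limit <= jk$interval[2]
  }
  expect_gte(mean(covered), 0.90)  # nominal 0.95, loose stochastic bound
})

test_that("Newman-Keuls separates far groups and never splits identical ones", {
  a <- jackknife_from_pseudovalues(matched_pseudovalues(1, 0.1), "A")
  b <- jackknife_from_pseudovalues(matched_pseudovalues(1, 0.1), "B")
  same <- newman_keuls(list(a, b))
  expect_false(same$different["A", "B"])
  expect_equal(unique(same$table$letters), "a")

  # means 10 SE-of-difference apart: q = 10 > any q crit at these df
  c2 <- jackknife_from_pseudovalues(matched_pseudovalues(1 + 10 * sqrt(2) * 0.1, 0.1), "C")
  far <- newman_keuls(list(a, c2))
  qcrit <- qtukey(0.95, 2, 28)
  qobs <- (c2$estimate - a$estimate) / sqrt(a$se^2 + c2$se^2)
  expect_gt(qobs, qcrit)
  expect_true(far$different["A", "C"])
  expect_setequal(far$table$letters, c("a", "b"))
})

test_that("letter display is consistent with the pairwise decisions", {
  set.seed(81)
  for (rep in 1:20) {
    groups <- lapply(1:4, function(i) {
      jackknife_from_pseudovalues(rnorm(10, mean = runif(1, 0, 1), sd = 0.3),
                                  paste0("G", i))
    })
    nk <- newman_keuls(groups)
    tab <- nk$table
    for (i in 1:3) for (j in (i + 1):4) {
      share <- length(intersect(strsplit(tab$letters[i], "")[[1]],
                                strsplit(tab$letters[j], "")[[1]])) > 0
      differ <- nk$different[tab$treatment[i], tab$treatment[j]]
      expect_identical(share, !differ)
    }
  }
})

test_that("no pair is declared different when the full range is non-significant", {
  # dominance over Tukey HSD on the widest stretch
  set.seed(91)
  for (rep in 1:30) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) {
      jackknife_from_pseudovalues(rnorm(12, mean = runif(1, 0, 0.3), sd = 0.5),
                                  paste0("G", i))
    })
    nk <- newman_keuls(groups)
    est <- vapply(groups, `[[`, numeric(1), "estimate")
    se <- vapply(groups, `[[`, numeric(1), "se")
    io <- order(est)
    widest_q <- (max(est) - min(est)) /
      sqrt(se[io[1]]^2 + se[io[k]]^2)
    if (widest_q <= qtukey(0.95, k, nk$df)) {
      expect_false(any(nk$different))
    }
  }
})

test_that("groups with too few pseudovalues are rejected", {
  a <- jackknife_from_pseudovalues(matched_pseudovalues(1, 0.1), "A")
  expect_error(newman_keuls(list(a)), "2")
  expect_error(jackknife_from_pseudovalues(0.5, "B"), "n >= 2")
})
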