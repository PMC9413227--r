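test_that("normality screen accepts normal and rejects skewed samples", {
  set.seed(3)
  res <- normality_screen(list(norm = rnorm(500), expo = rexp(500)))
  expect_true(res$normal[res$group == "norm"])
  expect_false(res$normal[res$group == "expo"])
  expect_true(all(res$statistic > 0))

  const <- normality_screen(list(flat = rep(1, 10)))
  expect_true(const$degenerate)
  expect_false(const$normal)
  expect_error(normality_screen(list(tiny = c(1, 2))), "fewer than 3")
})

test_that("kruskal-wallis matches a hand midrank computation", {
  # identical groups: no effect
  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # {1,2,3} vs {4,5,6}: ranks 1..6, R1 = 6, R2 = 15
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7)
  expect_identical(kw$df, 1L)
  expect_equal(kw$p_value, 1 - pchisq(27 / 7, 1))

  # descriptors carry mean/sd/median/quartiles
  expect_identical(kw$descriptors$group, c("a", "b"))
  expect_equal(kw$descriptors$mean, c(2, 5))
  expect_equal(kw$descriptors$median, c(2, 5))

  expect_error(kruskal_wallis(list(a = numeric(0), b = 1:3)), "empty group")
})

test_that("a two-sigma shift is detected at n = 100", {
  set.seed(13)
  kw <- kruskal_wallis(list(a = rnorm(100), b = rnorm(100, mean = 2)))
  expect_lt(kw$p_value, 0.05)
  expect_true(kw$significant)
})

test_that("the statistic is invariant under monotone transforms", {
  set.seed(17)
  a <- rlnorm(40); b <- rlnorm(40, 0.4)
  h1 <- kruskal_wallis(list(a = a, b = b))$H
  h2 <- kruskal_wallis(list(a = log(a), b = log(b)))$H
  h3 <- kruskal_wallis(list(a = rank(c(a, b))[1:40],
                            b = rank(c(a, b))[41:80]))$H
  expect_equal(h1, h2)
  expect_equal(h1, h3)
})

test_that("p-values under label permutation are approximately uniform", {
  set.seed(29)
  x <- rnorm(30)
  ps <- replicate(200, {
    lab <- sample(rep(c("a", "b"), 15))
    kruskal_wallis(split(x, lab))$p_value
  })
  # the permutation distribution is discrete, so check uniformity coarsely
  expect_lt(abs(mean(ps) - 0.5), 0.07)
  expect_lte(mean(ps <= 0.05), 0.12)
  expect_gte(mean(ps <= 0.5), 0.38)
})

test_that("site comparison table has the designed structure", {
  set.seed(31)
  mk <- function(pop, comp, stim, v) {
    data.frame(value = v, population = pop, compartment = comp,
               stim_compartment = stim)
  }
  comps <- c("big", "small_left", "small_right")
  d <- do.call(rbind, lapply(comps, function(st) {
    do.call(rbind, lapply(comps, function(cp) {
      rbind(mk("Cx", cp, st, rnorm(12, 100, 10)),
            mk("Hp", cp, st, rnorm(12, 100, 10)))
    }))
  }))
  tab <- site_comparisons(d)
  expect_identical(sum(tab$comparison == "between_population"), 9L)
  expect_identical(sum(startsWith(tab$comparison, "within_")), 6L)
  expect_identical(attr(tab, "n_comparisons"), nrow(tab))

  # single population: only within-population rows remain
  tab1 <- site_comparisons(d[d$population == "Cx", ])
  expect_identical(sum(tab1$comparison == "between_population"), 0L)
  expect_identical(sum(tab1$comparison == "within_Cx"), 3L)

  expect_error(site_comparisons(d[, -1]), "missing column")
})

test_that("identical populations produce near-alpha false positives", {
  set.seed(41)
  fp <- 0; total <- 0
  for (i in 1:200) {
    d <- data.frame(value = rnorm(40), population = rep(c("Cx", "Hp"), 20),
                    compartment = "big", stim_compartment = "big")
    tab <- site_comparisons(d)
    fp <- fp + sum(tab$significant[tab$comparison == "between_population"])
    total <- total + sum(tab$comparison == "between_population")
  }
  expect_gt(fp / total, 0.01)
  expect_lt(fp / total, 0.10)
})

test_that("sentinel-coded late latencies separate populations by construction", {
  set.seed(43)
  d <- rbind(
    data.frame(value = 650, population = "Hp",
               compartment = rep(c("big", "small_left", "small_right"), each = 8),
               stim_compartment = "big"),
    data.frame(value = runif(24, 100, 400), population = "Cx",
               compartment = rep(c("big", "small_left", "small_right"), each = 8),
               stim_compartment = "big")
  )
  tab <- site_comparisons(d)
  bp <- tab[tab$comparison == "between_population", ]
  expect_identical(nrow(bp), 3L)
  expect_true(all(bp$significant))
})
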