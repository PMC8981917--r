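test_that("normality gate routes as expected on simulated data", {
  # for normal groups the gate's parametric rate sits at its nominal
  # joint level, about 1 - (alpha_SW + alpha_Levene) ~ 0.90
  routes <- vapply(1:100, function(s) {
    tab <- gen_dose_response(c(10, 10, 10), c(2, 2, 2), 10, seed = s)
    normality_gate(tab)$route
  }, "")
  expect_lte(abs(mean(routes == "parametric") - 0.90), 0.06)

  # a heavily skewed group is caught
  skew <- vapply(1:60, function(s) {
    tab <- gen_dose_response(c(10, 10), c(2, 2), 20, seed = s)
    tab$value[tab$group == "g2"] <- withr::with_seed(s, rexp(20, 0.2))
    normality_gate(tab)$route
  }, "")
  expect_gte(mean(skew == "nonparametric"), 0.9)

  # constant group forces non-parametric with a warning
  tab <- data.frame(group = rep(c("a", "b"), each = 4),
                    value = c(rep(5, 4), c(1, 2, 3, 4)))
  expect_warning(g <- normality_gate(tab), "zero-variance")
  expect_equal(g$route, "nonparametric")
})

test_that("ANOVA + Tukey: hand-computed F, degenerate cases, letters", {
  # textbook one-way layout, k = 3, n = 4
  vals <- list(a = c(6, 8, 4, 5), b = c(8, 12, 9, 11), c = c(13, 9, 11, 8))
  tab <- data.frame(group = rep(names(vals), each = 4), value = unlist(vals))
  cmp <- anova_tukey(tab)
  gm <- mean(tab$value)
  ssb <- 4 * sum((vapply(vals, mean, 0) - gm)^2)
  ssw <- sum(unlist(lapply(vals, function(v) sum((v - mean(v))^2))))
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(cmp$statistic, f_hand, tolerance = 1e-9)
  expect_equal(cmp$p_value, pf(f_hand, 2, 9, lower.tail = FALSE),
               tolerance = 1e-9)

  # identical group patterns: F = 0, p = 1, shared letter
  tab0 <- data.frame(group = rep(c("a", "b"), each = 3), value = rep(1:3, 2))
  cmp0 <- anova_tukey(tab0)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(unname(cmp0$letters), c("a", "a"))

  expect_error(anova_tukey(data.frame(group = "a", value = 1)), "2 groups")
  expect_error(anova_tukey(data.frame(group = rep(c("a", "b"), each = 3),
                                      value = rep(7, 6))), "identical")
})

test_that("Kruskal-Wallis H matches the hand rank formula; Conover separates groups", {
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 3), value = 1:9)
  cmp <- kruskal_conover(tab)
  # ranks 1..9, group mean ranks 2, 5, 8: H = 12/(9*10) * 3*(9+0+9) = 7.2
  expect_equal(cmp$statistic, 7.2, tolerance = 1e-9)
  expect_equal(cmp$p_value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-9)
  expect_true(all(diag(cmp$pairwise_p) == 1))
  expect_equal(cmp$pairwise_p, t(cmp$pairwise_p))

  # two identical groups: H = 0, p = 1
  tab0 <- data.frame(group = rep(c("a", "b"), each = 3), value = rep(1:3, 2))
  cmp0 <- kruskal_conover(tab0)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)

  expect_warning(kruskal_conover(data.frame(group = c("a", "a", "b", "b"),
                                            value = c(1, 2, 3, 4))), "n < 5")
  # Holm adjustment never decreases pairwise p
  tab2 <- gen_dose_response(c(5, 9, 14), c(1, 1, 1), 6, seed = 2)
  raw <- kruskal_conover(tab2)$pairwise_p
  holm <- kruskal_conover(tab2, p_adjust = "holm")$pairwise_p
  expect_true(all(holm >= raw - 1e-12))
})

test_that("omnibus type-I error is calibrated and H is asymptotically chi-square", {
  ps <- vapply(1:400, function(s) {
    tab <- gen_dose_response(c(10, 10, 10), c(2, 2, 2), 10, seed = 20000 + s)
    kruskal_conover(tab)$p_value
  }, 0)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
  # under the null, p-values are approximately uniform; compare the
  # empirical CDF on a grid (the chi-square p-values are discrete-ish
  # at small n, so a raw KS test would complain about ties)
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_dist <- max(abs(vapply(grid, function(q) mean(ps <= q), 0) - grid))
  expect_lt(ecdf_dist, 0.05)
})

test_that("H relates to the two-sample rank statistic for k = 2", {
  # for two groups, H equals the squared standardized Wilcoxon statistic
  set.seed(3)
  x <- rnorm(12); y <- rnorm(12)
  tab <- data.frame(group = rep(c("a", "b"), each = 12), value = c(x, y))
  H <- kruskal_conover(tab)$statistic
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  n <- 12; N <- 24
  z <- (w$statistic - n * n / 2) / sqrt(n * n * (N + 1) / 12)
  expect_equal(H, unname(z^2), tolerance = 1e-9)
})

test_that("Spearman matrix: monotone pairs, Bonferroni arithmetic, invariance", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6), z = c(6, 4, 2))
  cm <- spearman_matrix(d)
  expect_equal(cm$rho["x", "y"], 1)
  expect_equal(cm$rho["x", "z"], -1)
  expect_equal(cm$m_comparisons, 3)

  set.seed(11)
  d2 <- data.frame(a = rnorm(20), b = rnorm(20))
  d2$c <- d2$a + rnorm(20, 0, 0.5)
  cm2 <- spearman_matrix(d2)
  expect_equal(cm2$p_adjusted["a", "b"],
               min(1, 3 * cm2$p_raw["a", "b"]))
  # invariant under strictly monotone transforms
  d3 <- transform(d2, a = exp(a), c = c^3)
  cm3 <- spearman_matrix(d3)
  expect_equal(cm3$rho, cm2$rho, tolerance = 1e-12)

  # constant variable yields NA
  d4 <- data.frame(u = rep(1, 5), v = 1:5)
  cm4 <- spearman_matrix(d4)
  expect_true(is.na(cm4$rho["u", "v"]))
})

test_that("compact letters: forced assignments and the defining invariant", {
  g3 <- c("A", "B", "C")
  pm <- function(pab, pac, pbc) {
    m <- diag(1, 3); dimnames(m) <- list(g3, g3)
    m["A", "B"] <- m["B", "A"] <- pab
    m["A", "C"] <- m["C", "A"] <- pac
    m["B", "C"] <- m["C", "B"] <- pbc
    m
  }
  expect_equal(unname(compact_letters(pm(0.5, 0.01, 0.01))), c("a", "a", "b"))
  expect_equal(unname(compact_letters(pm(0.9, 0.9, 0.9))), c("a", "a", "a"))
  expect_equal(unname(compact_letters(pm(0.01, 0.01, 0.01))), c("a", "b", "c"))

  # invariant on randomized matrices: share a letter iff p >= alpha
  set.seed(17)
  for (rep in 1:200) {
    k <- sample(3:6, 1)
    m <- diag(1, k)
    m[upper.tri(m)] <- runif(k * (k - 1) / 2)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(paste0("g", 1:k), paste0("g", 1:k))
    lets <- compact_letters(m, 0.05)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(strsplit(lets[i], "")[[1]],
                                strsplit(lets[j], "")[[1]])) > 0
      expect_equal(share, m[i, j] >= 0.05,
                   label = sprintf("rep %d pair %d-%d shares letter", rep, i, j))
    }
  }
})

test_that("letters on comparison objects satisfy the invariant", {
  tab <- gen_dose_response(c(5, 5.2, 12), c(1, 1, 1), 8, seed = 4)
  for (cmp in list(kruskal_conover(tab), anova_tukey(tab))) {
    lets <- cmp$letters
    g <- names(lets)
    for (i in 1:2) for (j in (i + 1):3) {
      share <- length(intersect(strsplit(lets[[g[i]]], "")[[1]],
                                strsplit(lets[[g[j]]], "")[[1]])) > 0
      expect_equal(share, cmp$pairwise_p[g[i], g[j]] >= cmp$alpha)
    }
  }
})
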