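test_that("equal condition means across subjects give F = 0", {
  wide <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(3, 4, 1, 2))
  # all columns share mean 2.5
  r <- one_way_rm_anova(wide, posthoc = "none")
  expect_equal(r$F, 0, tolerance = 1e-12)
})

test_that("with two conditions the RM-ANOVA F equals the squared paired t", {
  set.seed(40)
  x <- rnorm(9); y <- rnorm(9, 0.8)
  r <- one_way_rm_anova(cbind(c1 = x, c2 = y), correction = "none", posthoc = "none")
  t2 <- paired_t(x, y)$statistic^2
  expect_equal(r$F, t2, tolerance = 1e-10)
  expect_equal(r$p, paired_t(x, y)$p, tolerance = 1e-10)
})

test_that("a spherical condition covariance gives Greenhouse-Geisser epsilon 1", {
  # centered orthogonal equal-norm error columns => sample covariance = c I
  err <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))
  wide <- sweep(err, 2, c(0, 2, 5), "+")
  r <- one_way_rm_anova(wide)
  expect_equal(r$epsilon, 1, tolerance = 1e-12)
  expect_equal(r$df1, ncol(wide) - 1)
})

test_that("epsilon shrinks below 1 when sphericity is broken", {
  set.seed(41)
  base <- rnorm(8)
  wide <- cbind(a = base + rnorm(8, 0, 0.1), b = base + rnorm(8, 0, 0.1),
                c = rnorm(8, 0, 3))
  r <- one_way_rm_anova(wide)
  expect_lt(r$epsilon, 1)
  expect_gte(r$epsilon, 1 / (ncol(wide) - 1))
  expect_equal(r$df1, r$epsilon * 2, tolerance = 1e-12)
})

test_that("long and wide inputs agree and missing cells are rejected", {
  set.seed(42)
  wide <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("CD", "E1", "E2")))
  long <- data.frame(subject = rep(1:4, 3),
                     condition = rep(colnames(wide), each = 4),
                     value = as.vector(wide))
  expect_equal(one_way_rm_anova(wide)$F, one_way_rm_anova(long)$F)
  expect_error(one_way_rm_anova(long[-1, ]), "missing cells")
})

test_that("Dunnett adjusted p-values dominate unadjusted ones and match multcomp", {
  set.seed(43)
  n <- 8
  wide <- cbind(CD = rnorm(n), E1 = rnorm(n, -1), E2 = rnorm(n, -0.4),
                E3 = rnorm(n, 0.2))
  r <- one_way_rm_anova(wide, reference = "CD")
  expect_true(all(r$posthoc$p_adjusted >= r$posthoc$p_unadjusted - 1e-12))
  expect_true(all(r$posthoc$p_adjusted <= 1))

  skip_if_not_installed("multcomp")
  long <- data.frame(subject = factor(rep(seq_len(n), 4)),
                     condition = factor(rep(colnames(wide), each = n),
                                        levels = colnames(wide)),
                     value = as.vector(wide))
  fit <- stats::aov(value ~ condition + subject, data = long)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(r$posthoc$p_adjusted, as.numeric(ref), tolerance = 0.01)
})

test_that("mixed ANOVA reproduces the aov error decomposition", {
  set.seed(44)
  d <- expand.grid(subject = sprintf("r%02d", 1:12), day = c("CD", "TD"))
  d$group <- ifelse(as.integer(sub("r", "", d$subject)) <= 6, "Paired", "Unpaired")
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "Paired" & d$day == "TD", -1.5, 0)
  m <- mixed_two_way_anova(d)
  a <- summary(stats::aov(value ~ group * day + Error(factor(subject) / day), data = d))
  between <- a[["Error: factor(subject)"]][[1]]
  within <- a[["Error: factor(subject):day"]][[1]]
  expect_equal(m$table$F[1], between["group", "F value"], tolerance = 1e-10)
  expect_equal(m$table$F[3], within["day", "F value"], tolerance = 1e-10)
  expect_equal(m$table$F[4], within["group:day", "F value"], tolerance = 1e-10)
  expect_equal(m$table$p[4], within["group:day", "Pr(>F)"], tolerance = 1e-10)
})

test_that("the sums of squares partition the total to 1e-9 relative", {
  set.seed(45)
  d <- expand.grid(subject = sprintf("r%02d", 1:10), day = paste0("E", 1:4))
  d$group <- ifelse(as.integer(sub("r", "", d$subject)) <= 5, "A", "B")
  d$value <- rnorm(nrow(d), sd = 3)
  m <- mixed_two_way_anova(d)
  ss_tot <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(m$table$ss), ss_tot, tolerance = 1e-9)
  wide <- matrix(rnorm(24), 6, 4)
  r <- one_way_rm_anova(wide)
  expect_equal(sum(r$table$ss), sum((wide - mean(wide))^2), tolerance = 1e-9)
})

test_that("a duplicated day with identical values has zero day effect", {
  set.seed(46)
  vals <- rnorm(10)
  d <- data.frame(subject = rep(sprintf("r%02d", 1:10), 2),
                  day = rep(c("d1", "d2"), each = 10),
                  group = rep(rep(c("A", "B"), each = 5), 2),
                  value = rep(vals, 2))
  m <- mixed_two_way_anova(d, posthoc = "none")
  expect_equal(m$table$F[3], 0, tolerance = 1e-12)
})

test_that("design violations are rejected", {
  d <- data.frame(subject = c(1, 1, 2, 2), day = c("a", "b", "a", "b"),
                  group = c("A", "B", "B", "B"), value = rnorm(4))
  expect_error(mixed_two_way_anova(d), "exactly one group")
  d2 <- data.frame(subject = c(1, 1, 2), day = c("a", "b", "a"),
                   group = "A", value = rnorm(3))
  expect_error(mixed_two_way_anova(d2), "unbalanced")
})

test_that("Sidak adjustment is at least the unadjusted p and LSD leaves it alone", {
  set.seed(47)
  d <- expand.grid(subject = sprintf("r%02d", 1:8), day = c("E1", "E2", "E3"))
  d$group <- ifelse(as.integer(sub("r", "", d$subject)) <= 4, "A", "B")
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "A" & d$day != "E1", 1, 0)
  ms <- mixed_two_way_anova(d, posthoc = "sidak")
  ml <- mixed_two_way_anova(d, posthoc = "lsd")
  expect_true(all(ms$posthoc_between$p_adjusted >=
                    ms$posthoc_between$p_unadjusted - 1e-12))
  expect_equal(ml$posthoc_between$p_adjusted, ml$posthoc_between$p_unadjusted)
  expect_equal(ms$posthoc_between$t, ml$posthoc_between$t)
})
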