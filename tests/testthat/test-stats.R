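# Hand-computed sums-of-squares oracle for a balanced within-subject design
ss_oracle_oneway <- function(Y) {
  n <- nrow(Y); p <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- p * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (p - 1)) / (ss_err / ((n - 1) * (p - 1)))
  F
}

test_that("one-way rm-ANOVA F matches the sums-of-squares oracle", {
  set.seed(42)
  n <- 9; p <- 3
  Y <- matrix(rnorm(n * p), n, p) + outer(rnorm(n), rep(1, p)) +
    outer(rep(1, n), c(0, 0.4, 0.9))
  d <- data.frame(subject = rep(1:n, p), cond = rep(letters[1:p], each = n),
                  value = as.vector(Y))
  res <- rm_anova(d, "cond")
  expect_equal(res$F, ss_oracle_oneway(Y), tolerance = 1e-10)
  # cross-check against the base-R Error() stratum fit
  a <- summary(stats::aov(value ~ cond + Error(factor(subject) / cond),
                          data = d))
  F_aov <- a[["Error: factor(subject):cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-10)
})

test_that("two-way rm-ANOVA matches aov for every effect", {
  set.seed(7)
  n <- 8; a <- 3; b <- 3
  d <- expand.grid(subject = 1:n, A = letters[1:a], B = LETTERS[1:b])
  d$value <- rnorm(nrow(d)) + as.integer(d$A) * 0.5 +
    as.integer(d$A) * as.integer(d$B) * 0.2 + rnorm(n)[d$subject]
  res <- rm_anova(d, c("A", "B"))
  fit <- summary(stats::aov(
    value ~ A * B + Error(factor(subject) / (A * B)), data = d))
  expect_equal(res$F[res$effect == "A"],
               fit[["Error: factor(subject):A"]][[1]]["A", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "B"],
               fit[["Error: factor(subject):B"]][[1]]["B", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "A:B"],
               fit[["Error: factor(subject):A:B"]][[1]]["A:B", "F value"],
               tolerance = 1e-10)
  expect_true(all(res$gg_epsilon > 0 & res$gg_epsilon <= 1 + 1e-12))
  expect_equal(res$df1_gg, res$gg_epsilon * res$df1)
})

test_that("rm-ANOVA degenerate and invariance properties hold", {
  set.seed(1)
  n <- 10
  Y <- matrix(rnorm(n * 3), n, 3)
  d <- data.frame(subject = rep(1:n, 3), cond = rep(1:3, each = n),
                  value = as.vector(Y))
  # identical condition means (with real error variance): F collapses to 0
  Y0 <- matrix(rnorm(n * 3), n, 3)
  Y0 <- sweep(Y0, 2, colMeans(Y0))
  d0 <- data.frame(subject = rep(1:n, 3), cond = rep(1:3, each = n),
                   value = as.vector(Y0))
  expect_lt(rm_anova(d0, "cond")$F, 1e-20)
  # 2-level factor: sphericity holds trivially
  d2 <- d[d$cond != 3, ]
  r2 <- rm_anova(d2, "cond")
  expect_identical(r2$gg_epsilon, 1)
  # shift and scale invariance of F
  f0 <- rm_anova(d, "cond")$F
  d$value <- d$value + 100
  expect_equal(rm_anova(d, "cond")$F, f0, tolerance = 1e-10)
  d$value <- d$value * 3.7
  expect_equal(rm_anova(d, "cond")$F, f0, tolerance = 1e-10)
  # missing cell is an error, not imputed
  expect_error(rm_anova(d[-1, ], "cond"), "incomplete")
})

test_that("Mauchly test agrees with the base-R implementation", {
  set.seed(12)
  n <- 12; p <- 4
  Y <- matrix(rnorm(n * p), n, p) %*% diag(c(1, 1.8, 0.6, 1.2))
  d <- data.frame(subject = rep(1:n, p), cond = rep(1:p, each = n),
                  value = as.vector(Y))
  res <- rm_anova(d, "cond")
  m <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(res$mauchly_W, unname(m$statistic), tolerance = 1e-8)
  # base R adds Box's second-order series term to the chi-square tail; the
  # first-order approximation used here agrees to ~1e-3 at this n
  expect_equal(res$mauchly_p, m$p.value, tolerance = 2e-3)
})

test_that("t-test suite handles nulls, pairing, families and degeneracy", {
  v <- c(-2, -1, 0, 1, 2)
  r <- t_test_suite(v)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r3 <- t_test_suite(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_equal(unique(round(r3$corrected_alpha, 3)), 0.017)

  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  paired <- t_test_suite(list(x), partner = list(y))
  onediff <- t_test_suite(list(x - y))
  expect_equal(paired$t, onediff$t)
  expect_equal(paired$p, onediff$p)

  degen <- t_test_suite(rep(1, 5), mu0 = 1)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
})
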