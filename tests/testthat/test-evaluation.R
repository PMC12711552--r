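test_that("confusion metrics match their closed forms", {
  y_true <- rep(c("AC", "AC", "SCC", "SCC"), c(90, 10, 80, 20))
  y_pred <- rep(c("AC", "SCC", "SCC", "AC"), c(90, 10, 80, 20))
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(m$sensitivity, 0.900)
  expect_equal(m$specificity, 0.800)
  expect_equal(m$ppv, 90 / 110, tolerance = 1e-12)
  expect_equal(m$npv, 80 / 90, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.850)

  perfect <- confusion_metrics(y_true, y_true)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 1))

  # all predicted SCC: sensitivity 0, NPV = 1 - prevalence, PPV undefined
  all_scc <- confusion_metrics(y_true, rep("SCC", length(y_true)))
  expect_equal(all_scc$sensitivity, 0)
  expect_equal(all_scc$npv, 0.5)
  expect_true(is.na(all_scc$ppv))
  expect_error(confusion_metrics(c("AC"), c("AC", "SCC")), "lengths differ")
})

test_that("AUROC equals the pair-counting and trapezoidal forms", {
  expect_equal(auroc(c(0.35, 0.8, 0.1, 0.4), c("AC", "AC", "SCC", "SCC")),
               0.75)
  expect_equal(auroc(rep(0.5, 10), rep(c("AC", "SCC"), 5)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c("AC", "AC", "SCC", "SCC")), 1)
  expect_error(auroc(1:3, rep("AC", 3)), "both classes")

  set.seed(33)
  for (rep in 1:100) {
    n <- sample(6:40, 1)
    y <- c("AC", "SCC", sample(c("AC", "SCC"), n - 2, replace = TRUE))
    s <- rnorm(n)
    expect_equal(auroc(s, y), trapezoid_auc(s, y), tolerance = 1e-12)
  }
  # complement identity on tie-free scores
  s <- rnorm(30); y <- rep(c("AC", "SCC"), 15)
  expect_equal(auroc(s, y) + auroc(-s, y), 1)
})

test_that("bootstrap intervals bracket the point estimate and collapse when constant", {
  d <- data.frame(x = rep(1, 50))
  ci <- bootstrap_ci(function(dd) mean(dd$x), d, B = 200, seed = 1)
  expect_equal(ci$lo, 1)
  expect_equal(ci$hi, 1)
  set.seed(2)
  d2 <- data.frame(x = rbinom(100, 1, 0.7))
  ci2 <- bootstrap_ci(function(dd) mean(dd$x), d2, B = 500, seed = 3)
  expect_lte(ci2$lo, mean(d2$x))
  expect_gte(ci2$hi, mean(d2$x))
  # deterministic given the seed
  ci3 <- bootstrap_ci(function(dd) mean(dd$x), d2, B = 500, seed = 3)
  expect_identical(ci2$replicates, ci3$replicates)
})

test_that("case-level resampling keeps clustered slides together", {
  d <- data.frame(case = rep(c("a", "b", "c"), each = 2),
                  x = c(1, 1, 2, 2, 3, 3))
  # a metric that errors unless both members of each resampled case agree
  fn <- function(dd) {
    tab <- table(dd$case)
    if (any(tab %% 2 != 0)) stop("split case")
    mean(dd$x)
  }
  ci <- bootstrap_ci(fn, d, case_ids = d$case, B = 200, seed = 0)
  expect_equal(ci$n_redrawn, 0)
})

test_that("DeLong matches a brute-force structural-components double loop", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    y <- c("AC", "SCC", sample(c("AC", "SCC"), n - 2, replace = TRUE))
    sa <- rnorm(n); sb <- 0.3 * sa + rnorm(n)
    dl <- delong_test(sa, sb, y)
    # direct double loop
    pos <- y == "AC"; xs_a <- sa[pos]; ys_a <- sa[!pos]
    xs_b <- sb[pos]; ys_b <- sb[!pos]
    m <- sum(pos); nn <- sum(!pos)
    psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
    v10a <- v10b <- numeric(m); v01a <- v01b <- numeric(nn)
    for (i in 1:m) for (j in 1:nn) {
      v10a[i] <- v10a[i] + psi(xs_a[i], ys_a[j]) / nn
      v10b[i] <- v10b[i] + psi(xs_b[i], ys_b[j]) / nn
      v01a[j] <- v01a[j] + psi(xs_a[i], ys_a[j]) / m
      v01b[j] <- v01b[j] + psi(xs_b[i], ys_b[j]) / m
    }
    vd <- (var(v10a) + var(v10b) - 2 * cov(v10a, v10b)) / m +
      (var(v01a) + var(v01b) - 2 * cov(v01a, v01b)) / nn
    expect_lt(abs(dl$var_diff - vd), 1e-10)
    expect_equal(dl$auroc_a, mean(v10a), tolerance = 1e-12)
  }
})

test_that("DeLong is symmetric and degenerate-safe", {
  set.seed(18)
  y <- rep(c("AC", "SCC"), each = 20)
  sa <- rnorm(40); sb <- rnorm(40)
  d1 <- delong_test(sa, sb, y)
  d2 <- delong_test(sb, sa, y)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  same <- delong_test(sa, sa, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(delong_test(sa[1:10], sb, y), "paired")
})

test_that("DeLong AUROCs agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  y <- rep(c(1, 0), each = 25)
  sa <- y + rnorm(50); sb <- 0.5 * y + rnorm(50)
  dl <- delong_test(sa, sb, y)
  ra <- pROC::roc(y, sa, quiet = TRUE)
  rb <- pROC::roc(y, sb, quiet = TRUE)
  expect_equal(dl$auroc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p, pt$p.value, tolerance = 1e-9)
})

test_that("calibration bins partition the sample and behave on point masses", {
  set.seed(20)
  p <- runif(500); y <- rbinom(500, 1, p)
  cal <- calibration(p, y)
  expect_equal(sum(cal$bin_count), 500)
  expect_true(all(cal$observed_fraction >= 0 & cal$observed_fraction <= 1))
  cal2 <- calibration(rep(0.5, 40), rep(c(1, 0), 20))
  expect_equal(nrow(cal2), 1)
  expect_equal(cal2$observed_fraction, 0.5)
  expect_equal(cal2$mean_predicted, 0.5)
})

test_that("decision curves reproduce their closed-form references", {
  y <- rep(c(1, 0), c(30, 70))
  th <- seq(0.01, 0.99, 0.01)
  # perfect classifier: NB(t) = prevalence everywhere
  dc <- decision_curve(as.numeric(y), y, th)
  expect_equal(dc$net_benefit, rep(0.3, length(th)), tolerance = 1e-12)
  expect_true(all(dc$treat_none == 0))
  # a classifier that calls everyone positive traces the treat-all curve
  dca <- decision_curve(rep(1, 100), y, th)
  expect_equal(dca$net_benefit, dca$treat_all, tolerance = 1e-12)
  expect_equal(dca$treat_all, 0.3 - 0.7 * th / (1 - th), tolerance = 1e-12)
  # near t = 0 the treat-all net benefit tends to the prevalence
  expect_equal(decision_curve(rep(1, 100), y, 0.001)$net_benefit, 0.3,
               tolerance = 1e-2)
})

test_that("the evaluation report assembles the metric panel with CIs", {
  set.seed(21)
  y <- rep(c("AC", "SCC"), c(30, 70))
  p <- ifelse(y == "AC", rbeta(100, 4, 2), rbeta(100, 2, 4))
  rep_ <- eval_report(y, p, B = 200, seed = 0)
  expect_setequal(rep_$metric, c("accuracy", "sensitivity", "specificity",
                                 "ppv", "npv", "auroc"))
  expect_true(all(rep_$lo <= rep_$estimate & rep_$estimate <= rep_$hi))
  expect_equal(attr(rep_, "n_pos"), 30)
  expect_output(print(rep_), "auroc")
})

test_that("plots render without error", {
  set.seed(22)
  y <- rep(c("AC", "SCC"), 25)
  p <- ifelse(y == "AC", rbeta(50, 3, 2), rbeta(50, 2, 3))
  path <- tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot_roc(p, y))
  expect_no_error(plot(calibration(p, y)))
  expect_no_error(plot(decision_curve(p, y)))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
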