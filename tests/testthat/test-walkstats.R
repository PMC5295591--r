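# Per-line summaries and the adaptive-walk comparison statistics, checked
# against hand arithmetic and stats-package oracles.

totals8 <- c(31, 18, 11, 21, 10, 12, 22, 19)
steps8 <- evolved_step_table()$steps

# line summary built from the published count matrix without simulation
counts_summary <- function() {
  cm <- evolved_line_counts()
  ann <- do.call(rbind, lapply(colnames(cm), function(l) {
    do.call(rbind, lapply(rownames(cm), function(cl) {
      n <- cm[cl, l]
      if (n == 0) return(NULL)
      data.frame(line_id = l, mclass = cl,
                 severity = ifelse(cl == "coding_other", "radical",
                                   "not_applicable"),
                 stringsAsFactors = FALSE)[rep(1, n), ]
    }))
  }))
  summarize_lines(ann, evolved_step_table())
}

test_that("summarize_lines reconstructs the count matrix and percentages", {
  s <- counts_summary()
  expect_equal(unname(s$class_matrix[mutation_classes(), ]),
               unname(evolved_line_counts()))
  expect_equal(unname(s$class_matrix["all_mutations", ]), totals8)
  expect_equal(round(s$treatment_pct["intergenic", "S"], 1), 38.3)
  expect_equal(round(s$treatment_pct["coding_nonsynonymous", "S"], 1), 30.9)
  expect_equal(round(s$treatment_pct["intergenic", "L"], 1), 41.3)
  ls <- s$line_summary
  expect_equal(ls$total, ls$intergenic + ls$intron + ls$coding_total)
  expect_equal(ls$protein_changing,
               ls$coding_nonsynonymous + ls$coding_other)
  expect_equal(ls$steps, steps8)
  # empty input gives an all-zero matrix
  empty <- summarize_lines(data.frame(line_id = character(),
                                      mclass = character(),
                                      severity = character()),
                           evolved_step_table())
  expect_true(all(empty$class_matrix == 0))
})

test_that("mean_se uses the n-1 sample SD over sqrt(n)", {
  t <- mean_se(totals8)
  expect_equal(t$mean, 18.0)
  expect_equal(round(t$se, 2), 2.48)
  p <- mean_se(c(11, 10, 2, 7, 4, 6, 8, 7))
  expect_equal(round(p$mean, 2), 6.88)
  expect_equal(round(p$se, 2), 1.04)
  expect_equal(mean_se(rep(5, 4))$se, 0)
  expect_true(is.na(mean_se(3)$se))
  expect_error(mean_se(numeric(0)))
})

test_that("step ratios reproduce the published magnitudes", {
  expect_equal(round(step_ratio(18.0, 2.13), 2), 8.45)
  expect_equal(round(step_ratio(10.38, 2.13), 2), 4.87)
  expect_equal(round(step_ratio(6.88, 2.13), 2), 3.23)
  expect_equal(step_ratio(7, 7), 1)
  expect_error(step_ratio(10, 0), "positive")
})

test_that("pearson_with_p matches cor.test and the direct t formula", {
  r <- pearson_with_p(c(1, 2, 3, 4), c(2, 1, 4, 3))
  R <- cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  t <- R * sqrt(2) / sqrt(1 - R^2)
  expect_equal(r$R, R)
  expect_equal(r$p, 2 * pt(-abs(t), 2))
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(mine$R, unname(ct$estimate))
    expect_equal(mine$p, ct$p.value, tolerance = 1e-12)
  }
  perfect <- pearson_with_p(1:5, 2 * (1:5) + 3)
  expect_equal(perfect$R, 1)
  expect_equal(perfect$p, 0)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
  # affine invariance
  x <- c(3, 1, 4, 1, 5, 9); y <- c(2, 7, 1, 8, 2, 8)
  expect_equal(pearson_with_p(x, y)$p,
               pearson_with_p(10 + 5 * x, -2 * y)$p)
})

test_that("leave-one-out flags the outlier line and boundary n works", {
  loo <- leave_one_out(steps8, totals8, evolved_step_table()$line_id)
  row <- loo[loo$excluded == "25S", ]
  expect_equal(round(row$R, 3), 0.884)
  expect_equal(round(row$p, 4), 0.0083)
  expect_true(row$significance_changed)   # 0.147 -> 0.0083 crosses 0.05
  expect_equal(nrow(loo), 8L)
  small <- leave_one_out(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(unique(small$n), 3L)
  expect_error(leave_one_out(1:3, 3:1), "at least 4")
})

test_that("variance F-test puts the larger variance on top, one-tailed", {
  s <- totals8[1:4]; l <- totals8[5:8]
  f <- variance_f_test(s, l)
  expect_equal(round(f$var_a, 1), 68.9)
  expect_equal(f$var_b, 32.25)
  expect_equal(round(f$F, 2), 2.14)
  expect_equal(f$p, pf(f$F, 3, 3, lower.tail = FALSE))
  expect_gt(f$p, 0.27); expect_lt(f$p, 0.28)
  same <- variance_f_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(same$F, 1)
  expect_equal(same$p, 0.5)
  expect_error(variance_f_test(c(1, 1), c(2, 3)), "zero variance")
})

test_that("proportion contrasts reproduce the published means, SEs and p", {
  ls <- counts_summary()$line_summary
  syn <- proportion_contrast(ls, "synonymous_of_coding_snps")
  expect_equal(round(syn$mean_S, 3), 0.497)
  expect_equal(round(syn$se_S, 3), 0.191)
  expect_equal(round(syn$mean_L, 3), 0.323)
  expect_equal(round(syn$se_L, 3), 0.056)
  # Welch oracle from stats::t.test
  sS <- ls$coding_synonymous / (ls$coding_synonymous + ls$coding_nonsynonymous)
  tt <- t.test(sS[ls$treatment == "S"], sS[ls$treatment == "L"],
               alternative = "greater")
  expect_equal(syn$p, tt$p.value, tolerance = 1e-12)
  neu <- proportion_contrast(ls, "putatively_neutral")
  expect_equal(round(neu$mean_S, 3), 0.644)
  expect_equal(round(neu$se_S, 3), 0.077)
  expect_equal(round(neu$mean_L, 3), 0.592)
  expect_equal(round(neu$se_L, 3), 0.032)
  # equal group means (with within-group spread) give one-tailed p = 0.5
  ls2 <- ls
  ls2$coding_synonymous <- rep(c(1L, 3L, 2L, 2L), 2)
  ls2$coding_nonsynonymous <- rep(c(3L, 1L, 2L, 2L), 2)
  eq <- proportion_contrast(ls2, "synonymous_of_coding_snps")
  expect_equal(eq$p, 0.5)
  # zero-denominator lines are excluded with a warning
  ls3 <- ls
  ls3$coding_synonymous[1] <- 0L
  ls3$coding_nonsynonymous[1] <- 0L
  expect_warning(proportion_contrast(ls3, "synonymous_of_coding_snps"),
                 "excluded")
})

test_that("substitution rate scales as count over (bp x generations x lines)", {
  r <- substitution_rate(144, 29.67e6, 800, 8)
  expect_equal(signif(r$rate, 3), 7.58e-10)
  expect_equal(substitution_rate(0, 1e6, 10, 2)$rate, 0)
  expect_equal(substitution_rate(144, 29.67e6, 1600, 8)$rate, r$rate / 2)
  pc <- substitution_rate(10, 1e6, 100, 2,
                          per_chromosome = data.frame(
                            chrom = c("c1", "c2"), mutations = c(6, 4),
                            callable_bp = c(6e5, 4e5)))
  expect_equal(pc$per_chromosome$rate, c(6 / (6e5 * 100 * 2),
                                         4 / (4e5 * 100 * 2)))
  expect_error(substitution_rate(1, 0, 1, 1), "positive")
})

test_that("coding-share goodness of fit matches the hand chi-square", {
  t <- coding_fraction_test(83, 144, 0.5)
  expect_equal(round(100 * t$proportion, 1), 57.6)
  expect_equal(round(t$chi2, 2), 3.36)
  expect_equal(round(t$p, 3), 0.067)
  exact <- coding_fraction_test(72, 144, 0.5)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)
  expect_error(coding_fraction_test(150, 144, 0.5), "exceeds")
})

test_that("group statistics are invariant to line order", {
  ls <- counts_summary()$line_summary
  set.seed(3)
  ls2 <- ls[sample(nrow(ls)), ]
  a <- proportion_contrast(ls, "putatively_neutral")
  b <- proportion_contrast(ls2, "putatively_neutral")
  expect_equal(a$p, b$p)
  expect_equal(variance_f_test(ls$total[ls$treatment == "S"],
                               ls$total[ls$treatment == "L"])$p,
               variance_f_test(ls2$total[ls2$treatment == "S"],
                               ls2$total[ls2$treatment == "L"])$p)
})

test_that("half-up rounding hits printed precision where round() banks", {
  expect_equal(round_half_up(2.125, 2), 2.13)
  expect_equal(round_half_up(-2.125, 2), -2.13)
  expect_equal(round_half_up(2.124, 2), 2.12)
})
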