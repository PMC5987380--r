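test_that("significance bands follow the half-open colour rule exactly", {
  p <- c(0.0009, 0.001, 0.0099, 0.01, 0.049, 0.05, 0.9, NA)
  expect_equal(as.character(significance_bands(p)),
               c("red", "yellow", "yellow", "green", "green", "blue",
                 "blue", NA))
  expect_equal(levels(significance_bands(0.5)),
               c("red", "yellow", "green", "blue"))
})

test_that("the factorial ANOVA detects a pure genotype shift and nothing else", {
  tab <- factorial_table(5)
  set.seed(12)
  tab$y <- rnorm(60) + ifelse(tab$genotype == "B", 10, 0)
  ft <- fit_factorial_anova(tab, "y")
  expect_lt(ft$p[["genotype"]], 0.001)
  expect_true(all(ft$p[names(ft$p) != "genotype"] > 0.001))
  expect_gt(ft$r_squared, 0.9)
})

test_that("degenerate and malformed factorial tables are handled", {
  tab <- factorial_table(5)
  tab$y <- 1
  ft <- fit_factorial_anova(tab, "y")
  expect_true(ft$degenerate)
  expect_equal(ft$r_squared, 0)
  expect_true(all(is.na(ft$p)))
  expect_error(residual_checks(ft), "degenerate")
  tab2 <- factorial_table(2)
  tab2$y <- rnorm(nrow(tab2))
  drop <- which(tab2$genotype == "A" & tab2$sex == "M" & tab2$age == 10)
  expect_error(fit_factorial_anova(tab2[-drop, ], "y"), "empty factorial cell")
  expect_error(fit_factorial_anova(tab2[-drop[1], ], "y"),
               "fewer than 2 replicates")
})

test_that("p-values are invariant to animal order; Type I = Type III when balanced", {
  tab <- factorial_table(5)
  set.seed(5)
  tab$y <- rnorm(60) + as.numeric(tab$age) / 20
  ft <- fit_factorial_anova(tab, "y")
  set.seed(99)
  ft2 <- fit_factorial_anova(tab[sample(nrow(tab)), ], "y")
  expect_equal(ft$p, ft2$p, tolerance = 1e-12)
  # sequential (Type I) ANOVA agrees on the balanced design
  a1 <- anova(ft$fit)
  expect_equal(unname(ft$p),
               a1[c("genotype", "sex", "age", "genotype:sex",
                    "genotype:age", "sex:age", "genotype:sex:age"),
                  "Pr(>F)"],
               tolerance = 1e-10)
})

test_that("residual diagnostics flag the failures they should", {
  tab <- factorial_table(5)
  set.seed(31)
  flags <- replicate(30, {
    tab$y <- rnorm(60)
    rc <- residual_checks(fit_factorial_anova(tab, "y"))
    c(rc$normality_flag, rc$homogeneity_flag)
  })
  expect_gte(mean(!flags[1, ]), 0.9)
  expect_gte(mean(!flags[2, ]), 0.9)
  set.seed(32)
  sw_hits <- mean(replicate(30, {
    tab$y <- exp(rnorm(60, sd = 1.5))
    residual_checks(fit_factorial_anova(tab, "y"))$normality_flag
  }))
  expect_gte(sw_hits, 0.9)
  set.seed(33)
  bt_hits <- mean(replicate(30, {
    tab$y <- rnorm(60, sd = ifelse(tab$genotype == "A" & tab$sex == "M" &
                                     tab$age == 10, 4, 0.25))
    residual_checks(fit_factorial_anova(tab, "y"))$homogeneity_flag
  }))
  expect_gte(bt_hits, 0.9)
})

test_that("group summaries carry t-based 95% intervals", {
  tab <- factorial_table(5)
  tab$y <- rnorm(60)
  tab$y[tab$genotype == "A" & tab$sex == "M" & tab$age == 10] <- 1:5
  gs <- group_summary(tab, "y")
  row <- gs[gs$genotype == "A" & gs$sex == "M" & gs$age == "10", ]
  expect_equal(row$mean, 3)
  expect_equal(row$ci_half_width, qt(0.975, 4) * sd(1:5) / sqrt(5),
               tolerance = 1e-12)
  expect_equal(round(row$ci_half_width, 3), 1.963)
  # zero-variance cell
  tab$y[tab$genotype == "B" & tab$sex == "F" & tab$age == 40] <- 7
  gs2 <- group_summary(tab, "y")
  expect_equal(gs2$ci_half_width[gs2$genotype == "B" & gs2$sex == "F" &
                                   gs2$age == "40"], 0)
  # single-animal cells are flagged with undefined intervals
  tab1 <- factorial_table(1)
  tab1$y <- rnorm(nrow(tab1))
  gs3 <- group_summary(tab1, "y")
  expect_true(all(gs3$flagged))
  expect_true(all(is.na(gs3$ci_half_width)))
})

test_that("the per-percentile map validates its grid and supports BH", {
  prof <- do.call(rbind, lapply(1:24, function(i) {
    data.frame(animal = sprintf("a%02d", i),
               genotype = rep(c("A", "B"), 12)[i],
               sex = rep(c("M", "M", "F", "F"), 6)[i],
               age = rep(c(10, 20, 40), each = 8)[i],
               percent = 40:50,
               y = rnorm(11))
  }))
  sm <- heatmap_statmap(prof, "y")
  expect_s3_class(sm, "statmap_result")
  expect_equal(nrow(sm), 11 * 7)
  expect_true(all(sm$p >= 0 & sm$p <= 1))
  smf <- heatmap_statmap(prof, "y", fdr = TRUE)
  expect_true(all(smf$p >= sm$p - 1e-12))
  bad <- prof[!(prof$animal == "a01" & prof$percent == 45), ]
  expect_error(heatmap_statmap(bad, "y"), "common percentile grid")
  p <- plot_statmap(sm)
  expect_s3_class(p, "ggplot")
})
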