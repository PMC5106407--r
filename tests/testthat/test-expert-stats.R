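test_that("pooled label statistics match the three-expert table", {
  tbl <- expert_table()
  ps <- pooled_label_stats(tbl)
  expect_equal(ps$mean, 2.83, tolerance = 0.005)
  expect_equal(ps$sd, 2.269, tolerance = 0.001)

  ## all-identical labels
  one <- data.frame(image_id = "a", expert_id = "e", stage = "No DR")
  ps1 <- pooled_label_stats(rbind(one, one))
  expect_equal(ps1$mean, 1)
  expect_equal(ps1$sd, 0)

  ## flat-loop oracle on a random table
  set.seed(5)
  stages <- sample(retinopathy_stages(), 50, replace = TRUE)
  rnd <- data.frame(image_id = sprintf("i%02d", 1:50),
                    expert_id = "e1", stage = stages)
  ps2 <- pooled_label_stats(rnd)
  codes <- numeric(0)
  for (s in stages) codes <- c(codes, which(retinopathy_stages() == s))
  expect_equal(ps2$mean, sum(codes) / length(codes))
  expect_equal(ps2$sd, sqrt(sum((codes - mean(codes))^2) / (length(codes) - 1)))

  expect_error(pooled_label_stats(rnd[0, ]), "empty")
})

test_that("categorisation schemes reproduce the printed group counts", {
  expect_equal(categorise("Severe DR with maculopathy", "II"),
               "Non-proliferative DR")
  for (s in c("I", "II", "III"))
    expect_equal(categorise("No DR", s), "No DR")

  stages <- consensus_stages()
  c1 <- table(categorise(stages, "I"))
  expect_equal(unname(c1[["DR"]]), 324)
  expect_equal(unname(c1[["No DR"]]), 276)

  c2 <- table(categorise(stages, "II"))
  expect_equal(unname(c2[["No DR"]]), 276)
  expect_equal(unname(c2[["Non-proliferative DR"]]), 301)
  expect_equal(unname(c2[["Proliferative DR"]]), 16)
  expect_equal(unname(c2[["ADED"]]), 7)

  ## conservation: categories always sum to the table total
  for (s in c("I", "II", "III"))
    expect_equal(sum(table(categorise(stages, s))), 600)
  expect_error(categorise("No DR", "IV"))
})

test_that("five-number summaries reproduce the boxplot medians", {
  tbl <- expert_table()
  expect_equal(unname(five_number_summary(tbl, "expert1")["median"]), 1)
  expect_equal(unname(five_number_summary(tbl, "expert2")["median"]), 2)
  expect_equal(unname(five_number_summary(tbl, "expert3")["median"]), 1)

  single <- data.frame(image_id = c("a", "b"), expert_id = "e",
                       stage = "Mild DR with maculopathy")
  fn <- five_number_summary(single, "e")
  expect_true(all(fn == 3))
  expect_error(five_number_summary(tbl, "expert9"), "unknown")
})

test_that("crosstab matches the printed counts and percentages", {
  tbl <- expert_table()
  ct <- crosstab_chi_square(tbl)
  expect_equal(unname(ct$counts["No DR", "expert1"]), 326)
  expect_equal(unname(ct$percent["No DR", "expert1"]), 54.3)
  expect_lt(ct$p, 0.0005)              # the table prints p = 0.000
  ## column percentages sum to 100 within rounding slack
  expect_true(all(abs(colSums(ct$percent) - 100) <= 0.2))

  ## identical experts: chi-square exactly zero
  half <- tbl[tbl$expert_id == "expert1", ]
  dup <- rbind(half, transform(half, expert_id = "clone"))
  ## the severe-without row is non-zero for expert1, so no dropping here
  ct0 <- suppressWarnings(crosstab_chi_square(dup))
  expect_equal(ct0$chi2, 0)

  ## formula oracle on a random 3x3 table
  set.seed(12)
  stages3 <- retinopathy_stages()[1:3]
  rnd <- data.frame(
    image_id = rep(sprintf("i%03d", 1:60), 3),
    expert_id = rep(c("a", "b", "c"), each = 60),
    stage = sample(stages3, 180, replace = TRUE))
  ctr <- suppressWarnings(crosstab_chi_square(rnd))
  obs <- ctr$counts[rowSums(ctr$counts) > 0, , drop = FALSE]
  exp_cnt <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(ctr$chi2, sum((obs - exp_cnt)^2 / exp_cnt))
  expect_equal(ctr$df, (nrow(obs) - 1) * (ncol(obs) - 1))
})

test_that("one-way ANOVA reproduces the post hoc pattern", {
  tbl <- expert_table()
  an <- one_way_anova(tbl)
  expect_lt(an$p_overall, 0.0005)
  ## experts 2 and 3 are indistinguishable after Bonferroni
  expect_equal(unname(an$pairwise["expert2", "expert3"]), 1)
  expect_lt(an$pairwise["expert1", "expert2"], 0.05)
  expect_lt(an$pairwise["expert1", "expert3"], 0.05)
  ## adjusted p values are capped at 1
  expect_true(all(an$pairwise <= 1, na.rm = TRUE))

  ## identical groups: pairwise p = 1
  half <- tbl[tbl$expert_id == "expert1", ]
  dup <- rbind(half, transform(half, expert_id = "clone"))
  an0 <- one_way_anova(dup)
  expect_equal(unname(an0$pairwise["expert1", "clone"]), 1)

  ## F statistic equals the textbook decomposition on a small table
  set.seed(3)
  small <- data.frame(
    image_id = rep(sprintf("i%02d", 1:12), 2),
    expert_id = rep(c("a", "b"), each = 12),
    stage = sample(retinopathy_stages()[1:5], 24, replace = TRUE))
  anx <- one_way_anova(small)
  codes <- stage_code(small$stage)
  grp <- split(codes, small$expert_id)
  gm <- mean(codes)
  ssb <- sum(vapply(grp, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(grp, function(g) sum((g - mean(g))^2), 0))
  f_oracle <- (ssb / (length(grp) - 1)) / (ssw / (length(codes) - length(grp)))
  expect_equal(anx$f_statistic, f_oracle)

  expect_error(one_way_anova(data.frame(image_id = "a", expert_id = "e",
                                        stage = "No DR")), "2 experts")
})

test_that("grading tables round-trip through CSV with validation", {
  tbl <- head(expert_table(), 20)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_grading_table(tbl, path)
  back <- read_grading_table(path)
  expect_equal(back$stage, tbl$stage)

  bad <- transform(tbl, stage = "nonsense")
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_grading_table(path), "unknown")

  dup <- rbind(tbl[1, ], tbl[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_grading_table(path), "more than one grade")
})

test_that("stage coding is a bijection in scale order", {
  stages <- retinopathy_stages()
  expect_length(stages, 10)
  expect_equal(stage_code(stages), 1:10)
  expect_equal(stage_code("ADED"), 10)
  expect_error(stage_code("DR"), "unknown")
  ## cross-module consistency: expert counts expand to 600 per expert
  tbl <- expert_table()
  expect_equal(unname(table(tbl$expert_id)), rep(600L, 3), ignore_attr = TRUE)
})
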