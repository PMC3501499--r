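test_that("summarize_groups reproduces published tissue summaries", {
  s <- summarize_groups(table3(), "d18O_co3")
  inc <- s[s$tissue == "incisor", ]
  expect_equal(round_report(inc$mean), 26.5)
  expect_equal(round_report(inc$sd), 1.2)
  m1 <- s[s$tissue == "M1", ]
  expect_equal(round_report(m1$mean), 25.8)
  expect_equal(round_report(m1$sd), 1.1)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  expect_equal(s$range_width, s$max - s$min)
})

test_that("summarize_groups edge cases and invariances", {
  const <- make_records(paste0("S", 1:4), "bone", d18O_co3 = rep(25, 4))
  s <- summarize_groups(const, "d18O_co3")
  expect_equal(s$sd, 0)
  expect_equal(s$range_width, 0)
  expect_error(summarize_groups(const, "d18O_hydroxyl"),
               class = "rodiso_invalid_input")
  tab <- table3()
  expect_equal(summarize_groups(tab[sample(nrow(tab)), ], "d18O_po4"),
               summarize_groups(tab, "d18O_po4"))
  # missing values excluded and counted, not imputed
  with_na <- make_records(paste0("S", 1:3), "bone",
                          d18O_co3 = c(25, NA, 27), d13C = c(NA, -17, NA))
  s2 <- summarize_groups(with_na, "d18O_co3")
  expect_equal(s2$n, 2L)
  expect_equal(s2$n_missing, 1L)
})

test_that("paired_tissue_offsets captures the incisor-over-bone pattern", {
  rep <- paired_tissue_offsets(table3(), "incisor", "bone", "d18O_co3")
  expect_equal(nrow(rep$pairs), 5L)
  expect_equal(rep$pairs$offset[rep$pairs$specimen_id == "AT01"], 0.7)
  expect_equal(rep$n_positive, 5L)          # all five incisors higher
  expect_equal(rep$proportion_positive, 1)
  expect_equal(unname(rep$offset_sd_by_species["Arvicola terrestris"]),
               sd(rep$pairs$offset))
  same <- paired_tissue_offsets(table3(), "bone", "bone", "d18O_co3")
  expect_true(all(same$pairs$offset == 0))
  expect_error(paired_tissue_offsets(table3(), "M2", "bone", "d18O_co3"),
               class = "rodiso_empty_selection")
})

test_that("intra_jaw_ranges computes overall and molar-only widths", {
  jaw <- make_records(rep("J1", 4), c("incisor", "M1", "M2", "M3"),
                      d18O_co3 = c(27.0, 26.2, 26.2, 26.2))
  r <- intra_jaw_ranges(jaw, "d18O_co3")
  expect_equal(r$overall_range, 0.8)
  expect_equal(r$molar_range, 0)
  two <- make_records(rep("J2", 2), c("incisor", "M1"),
                      d18O_co3 = c(26.6, 26.1))
  expect_equal(intra_jaw_ranges(two, "d18O_co3")$overall_range, 0.5)
  # molar-only range never exceeds the overall range
  set.seed(17)
  big <- make_records(rep(paste0("S", 1:8), each = 4),
                      rep(c("incisor", "M1", "M2", "M3"), 8),
                      d18O_co3 = runif(32, 24, 29))
  rb <- intra_jaw_ranges(big, "d18O_co3")
  expect_true(all(rb$molar_range <= rb$overall_range))
  lone <- make_records("L", "M1", d18O_co3 = 26)
  expect_message(expect_error(intra_jaw_ranges(lone, "d18O_co3"),
                              class = "rodiso_empty_selection"))
})

test_that("one_way_anova matches hand decomposition and the stats oracle", {
  # SSB = 1.5, MSW = 1 by hand
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$statistic, 1.5)
  expect_equal(c(a$df_between, a$df_within), c(1L, 4L))
  expect_equal(one_way_anova(list(c(1, 2, 3), c(2, 1, 3)))$statistic, 0)
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))),
               class = "rodiso_degenerate_variance")
  expect_error(one_way_anova(list(1, c(2, 3))),
               class = "rodiso_invalid_input")
  # cross-implementation oracle on seeded data, plus shift/scale invariance
  set.seed(101)
  g <- lapply(c(10, 7, 12), function(n) rnorm(n, sample(25:28, 1), 1.1))
  mine <- one_way_anova(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(seq_along(g), lengths(g))))
  ref <- anova(lm(y ~ grp, data = df))
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  shifted <- lapply(g, function(x) 3.2 * x + 7)
  expect_equal(one_way_anova(shifted)$statistic, mine$statistic,
               tolerance = 1e-9)
})

test_that("tukey_hsd matches TukeyHSD and behaves sanely", {
  set.seed(55)
  g <- list(a = rnorm(10, 27, 1), b = rnorm(10, 27.4, 1),
            c = rnorm(10, 29, 1))
  mine <- tukey_hsd(g)
  df <- data.frame(y = unlist(g), grp = factor(rep(names(g), lengths(g))))
  ref <- TukeyHSD(aov(y ~ grp, data = df))$grp
  # reference reports (later - earlier); align pairs by name
  key <- paste(mine$group_b, mine$group_a, sep = "-")
  expect_equal(unname(-mine$diff[match(rownames(ref), key)]),
               unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(unname(mine$p_adjusted[match(rownames(ref), key)]),
               unname(ref[, "p adj"]), tolerance = 1e-6)
  # adjusted p is conservative relative to the unadjusted pairwise t test
  # computed on the same pooled error variance and df
  df2 <- sum(lengths(g)) - length(g)
  msw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / df2
  for (i in seq_len(nrow(mine))) {
    na <- length(g[[mine$group_a[i]]]); nb <- length(g[[mine$group_b[i]]])
    t_stat <- abs(mine$diff[i]) / sqrt(msw * (1 / na + 1 / nb))
    p_unadj <- 2 * pt(t_stat, df2, lower.tail = FALSE)
    expect_gte(mine$p_adjusted[i], p_unadj - 1e-12)
  }
})

test_that("tukey_hsd degenerate orderings and unequal n", {
  set.seed(56)
  base <- rnorm(8, 0, 1)
  g <- list(p = base, q = base, r = base + 50)
  res <- tukey_hsd(g)
  expect_equal(res$p_adjusted[res$group_a == "p" & res$group_b == "q"], 1,
               tolerance = 1e-9)
  expect_true(all(res$significant[res$group_b == "r" | res$group_a == "r"]))
  # Tukey-Kramer harmonic-mean convention for unequal n matches stats
  g2 <- list(a = rnorm(5, 0), b = rnorm(9, 0.5), c = rnorm(7, 2))
  mine <- tukey_hsd(g2)
  df <- data.frame(y = unlist(g2), grp = factor(rep(names(g2),
                                                    lengths(g2))))
  ref <- TukeyHSD(aov(y ~ grp, data = df))$grp
  key <- paste(mine$group_b, mine$group_a, sep = "-")
  expect_equal(unname(mine$p_adjusted[match(rownames(ref), key)]),
               unname(ref[, "p adj"]), tolerance = 1e-6)
})

test_that("kruskal_wallis is tie-corrected, rank-based, matches oracle", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic, 2.4)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))),
               class = "rodiso_degenerate_variance")
  set.seed(77)
  g <- list(rnorm(9), rnorm(11, 0.8), round(rnorm(10, 0.3), 1))  # with ties
  mine <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # H depends on ranks only: strictly monotone transform leaves it fixed
  g_t <- lapply(g, function(x) exp(x / 2))
  expect_equal(kruskal_wallis(g_t)$statistic, mine$statistic,
               tolerance = 1e-10)
  # within-group reordering is irrelevant
  g_p <- lapply(g, sample)
  expect_equal(kruskal_wallis(g_p)$statistic, mine$statistic)
})

test_that("flag_outliers flags gross values only, never deletes", {
  # a 24.7-28.2 band plus one extreme value, as in the vole incisor case
  band <- c(24.7, 25.8, 26.3, 26.8, 27.0, 27.4, 27.7, 28.0, 28.2, 31.4)
  fl <- flag_outliers(band)
  expect_equal(which(fl), 10L)
  expect_length(fl, length(band))
  tight <- c(26.0, 26.1, 26.2, 26.3, 26.4)
  expect_false(any(flag_outliers(tight)))
  expect_false(any(flag_outliers(band, k = Inf)))
  expect_error(flag_outliers(c(1, 2)), class = "rodiso_invalid_input")
})
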