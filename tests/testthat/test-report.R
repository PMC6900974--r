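test_that("a single-class sample composes to fraction 1", {
  df <- data.frame(color_class = rep("mCFP", 100))
  ct <- compose_classes(df)
  comp <- ct$composition
  expect_equal(comp$fraction[comp$color_class == "mCFP"], 1)
  expect_equal(ct$summary$richness, 1)
  expect_equal(ct$summary$labeling_efficiency, 1)
})

test_that("hand-counted fractions, efficiency and conservation hold", {
  df <- data.frame(
    organ = c(rep("A", 6), rep("B", 6)),
    color_class = c("mCFP", "mCFP", "mCFP", "RFP", "RFP", "negative",
                    "eYFP", "eYFP", "eYFP", "eYFP", "unresolved", "mCFP"))
  ct <- compose_classes(df, "organ")
  comp <- ct$composition; summ <- ct$summary
  a <- comp[comp$organ == "A", ]
  expect_equal(a$count[a$color_class == "mCFP"], 3L)
  expect_equal(a$fraction[a$color_class == "mCFP"], 3 / 5)
  expect_equal(a$fraction[a$color_class == "RFP"], 2 / 5)
  b <- comp[comp$organ == "B", ]
  expect_equal(b$fraction[b$color_class == "eYFP"], 4 / 5)
  expect_equal(b$fraction[b$color_class == "mCFP"], 1 / 5)
  expect_equal(summ$labeling_efficiency, c(5 / 6, 1))  # B: unresolved counts
  expect_equal(summ$richness, c(2L, 2L))
  # conservation: classes + unresolved + negative = total, per group
  for (g in c("A", "B")) {
    rows <- comp[comp$organ == g, ]
    expect_equal(sum(rows$count), summ$total[summ$organ == g])
  }
  # labeled-class fractions sum to 1 per group
  lab <- comp[comp$color_class %in% color_class_levels(), ]
  expect_equal(as.numeric(tapply(lab$fraction, lab$organ, sum,
                                 na.rm = TRUE)), c(1, 1))
  expect_error(compose_classes(df, "tissue"), "missing group")
})

test_that("composition is invariant to row permutation", {
  df <- withr::with_seed(71, data.frame(
    organ = sample(c("A", "B"), 200, TRUE),
    color_class = sample(c(color_class_levels(), "negative"), 200, TRUE)))
  ct1 <- compose_classes(df, "organ")
  ct2 <- compose_classes(df[withr::with_seed(72, sample(200)), ], "organ")
  expect_equal(ct1$composition, ct2$composition, ignore_attr = TRUE)
})

test_that("group comparison measures shared classes and TVD", {
  df <- data.frame(
    organ = c(rep("A", 10), rep("B", 10), rep("C", 5), rep("D", 5)),
    color_class = c(rep("nGFP", 5), rep("eYFP", 3), rep("RFP", 2),
                    rep("nGFP", 2), rep("eYFP", 5), rep("RFP", 3),
                    rep("mCFP", 5), rep("RFP+mCFP", 5)))
  ct <- compose_classes(df, "organ")
  same <- compare_groups(ct, "A", "A")
  expect_equal(same$tvd, 0)
  expect_setequal(same$shared, c("nGFP", "eYFP", "RFP"))
  disjoint <- compare_groups(ct, "C", "D")
  expect_equal(disjoint$tvd, 1)
  expect_length(disjoint$shared, 0)
  # hand computation: 0.5 * (|.5-.2| + |.3-.5| + |.2-.3|) = 0.3
  ab <- compare_groups(ct, "A", "B")
  expect_equal(ab$tvd, 0.3)
  expect_setequal(ab$shared, c("nGFP", "eYFP", "RFP"))
})

test_that("reports round-trip and are byte-stable", {
  df <- data.frame(organ = rep(c("A", "B"), each = 20),
                   color_class = rep(c("mCFP", "RFP", "negative", "eYFP"), 10))
  ct <- compose_classes(df, "organ")
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p1 <- write_report(ct, d1, qc = list(threshold = 0.5))
  p2 <- write_report(ct, d2, qc = list(threshold = 0.5))
  expect_true(all(file.exists(p1)))
  for (f in c("composition.csv", "summary.csv", "report.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  back <- jsonlite::read_json(file.path(d1, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$composition$count,
               ct$composition$count)
  expect_equal(back$summary$labeling_efficiency,
               ct$summary$labeling_efficiency)
  # stacked-bar figure on demand
  p3 <- write_report(ct, d1, plot = TRUE)
  expect_true(file.exists(file.path(d1, "composition.png")))
})

test_that("organ subsampling recovers the generating class fractions", {
  pop <- simulate_population(50000, recombination_params(
    transduction_efficiency = 1, unrecombined_mass = 0, seed = 73))
  lv <- color_class_levels()
  w <- setNames(c(4, 3, 2, 1, rep(1, 6)), lv)
  n <- 5000
  cohort <- sample_organs(pop, list(organ1 = w), n_per_organ = n, seed = 74)
  ev <- simulate_events(cohort)
  ev$organ <- cohort$organ
  thr <- derive_thresholds(ev)
  out <- classify_table(ev[setdiff(names(ev), c("color_class", "gfp_hi"))],
                        thr)
  ct <- compose_classes(out, "organ")
  # expected fraction of class c among labeled draws: w_c n_c / sum w n
  counts <- table(factor(pop$color_class, levels = lv))
  expected <- (w * as.numeric(counts)) / sum(w * as.numeric(counts))
  comp <- ct$composition
  for (cls in lv) {
    p <- expected[[cls]]
    got <- comp$fraction[comp$color_class == cls]
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})
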