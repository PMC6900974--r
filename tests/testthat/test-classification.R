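events_from <- function(classes, signal = 1000, background = 100) {
  pop <- data.frame(cell_id = seq_along(classes), color_class = classes,
                    viral_marker = "none", gfp_hi = FALSE,
                    stringsAsFactors = FALSE)
  simulate_events(pop, signal = signal, background = background)
}

ten_class_events <- function(n_each = 10, ...) {
  events_from(rep(c(color_class_levels(), "negative"), n_each), ...)
}

test_that("well-separated channels get a gap threshold between the clusters", {
  ev <- withr::with_seed(61, {
    e <- ten_class_events(20)
    for (cn in c("CFP", "GREEN", "YFP", "RED"))
      e[[cn]] <- e[[cn]] * exp(rnorm(nrow(e), 0, 0.02))
    e
  })
  thr <- derive_thresholds(ev)
  for (cn in c("CFP", "GREEN", "YFP", "RED")) {
    expect_equal(thr$method[[cn]], "gap")
    neg <- max(ev[[cn]][ev[[cn]] < 500]); pos <- min(ev[[cn]][ev[[cn]] > 500])
    expect_gt(thr$cutoff[[cn]], neg); expect_lt(thr$cutoff[[cn]], pos)
  }
})

test_that("channels without a clear valley fall back to a variance split", {
  ev <- withr::with_seed(62, data.frame(
    CFP = exp(rnorm(200, 5, 0.4)), GREEN = c(rep(10, 100), rep(1000, 100)),
    YFP = c(rep(10, 100), rep(1000, 100)),
    RED = c(rep(10, 100), rep(1000, 100))))
  thr <- derive_thresholds(ev)
  expect_equal(thr$method[["CFP"]], "variance")
  expect_equal(thr$method[["GREEN"]], "gap")
  expect_error(derive_thresholds(transform(ev, RED = 5)), "RED")
  expect_error(derive_thresholds(ev[1:10, ]), "at least 20")
})

test_that("derived thresholds are near-optimal for a two-Gaussian mixture", {
  mu <- c(200, 2000); sdv <- c(20, 150)
  x <- withr::with_seed(63, c(rnorm(500, mu[1], sdv[1]),
                              rnorm(500, mu[2], sdv[2])))
  ev <- data.frame(CFP = x, GREEN = x, YFP = x, RED = x)
  thr <- derive_thresholds(ev)
  # analytic misclassification rate of a cutoff t, equal class weights
  err <- function(t) 0.5 * pnorm(t, mu[1], sdv[1], lower.tail = FALSE) +
    0.5 * pnorm(t, mu[2], sdv[2])
  opt <- optimize(err, c(mu[1], mu[2]))
  expect_lte(err(thr$cutoff[["CFP"]]), opt$objective + 1e-3)
})

test_that("events map to classes with exclusion-gating semantics", {
  ev <- ten_class_events(10)
  thr <- derive_thresholds(ev)
  # all channels below cutoffs: negative
  low <- c(CFP = 100, GREEN = 100, YFP = 100, RED = 100)
  expect_equal(classify_event(low, thr)$class, "negative")
  hi2 <- c(CFP = 1100, GREEN = 100, YFP = 1100, RED = 100)
  expect_equal(classify_event(hi2, thr)$class, "eYFP+mCFP")
  # more than two positive channels: explicit unresolved, never a class
  hi3 <- c(CFP = 1100, GREEN = 1100, YFP = 1100, RED = 100)
  expect_equal(classify_event(hi3, thr)$class, "unresolved")
  expect_error(classify_event(c(CFP = 1, GREEN = 1, YFP = 1), thr), "RED")
})

test_that("noise-free classification agrees exactly with the genotypes", {
  pop <- simulate_population(2000, recombination_params(
    transduction_efficiency = 1, unrecombined_mass = 0.2, seed = 64))
  ev <- simulate_events(pop)
  truth <- ev$color_class
  ev$color_class <- NULL; ev$gfp_hi <- NULL
  thr <- derive_thresholds(ev)
  out <- classify_table(ev, thr)
  expect_equal(mean(out$color_class == truth), 1)
  # row order does not matter
  perm <- withr::with_seed(65, sample(nrow(ev)))
  out2 <- classify_table(ev[perm, ], thr)
  expect_equal(out2$color_class, out$color_class[perm])
  # empty table passes through
  empty <- classify_table(ev[0, ], thr)
  expect_equal(nrow(empty), 0)
  expect_true("color_class" %in% names(empty))
})

test_that("thresholds are invariant to event order and table duplication", {
  ev <- withr::with_seed(66, {
    e <- ten_class_events(15)
    for (cn in c("CFP", "GREEN", "YFP", "RED"))
      e[[cn]] <- pmax(e[[cn]] + rnorm(nrow(e), 0, 50), 0)
    e
  })
  thr1 <- derive_thresholds(ev)
  thr2 <- derive_thresholds(ev[withr::with_seed(67, sample(nrow(ev))), ])
  thr3 <- derive_thresholds(rbind(ev, ev))
  expect_equal(thr1$cutoff, thr2$cutoff)
  expect_equal(thr1$cutoff, thr3$cutoff)
})

test_that("bright green events are attributed to the integrated provirus", {
  pop <- simulate_population(4000, recombination_params(
    transduction_efficiency = 1, integration_fraction = 0.05, seed = 68))
  ev <- simulate_events(pop, noise_sd = 50, gfp_hi_level = 30000, seed = 68)
  truth_hi <- ev$gfp_hi
  ev$color_class <- NULL; ev$gfp_hi <- NULL
  thr <- derive_thresholds(ev, gfp_hi = TRUE)
  expect_false(is.na(thr$gfp_hi_cutoff))
  expect_gt(thr$gfp_hi_cutoff, thr$cutoff[["GREEN"]])
  out <- classify_table(ev, thr)
  expect_equal(out$gfp_hi, truth_hi)
  # a GFP-hi-only event is Brainbow-negative, not nGFP
  solo <- classify_event(c(CFP = 100, GREEN = 30500, YFP = 100, RED = 100), thr)
  expect_true(solo$gfp_hi)
  expect_equal(solo$class, "negative")
})

test_that("no classified event carries more than two cassette colors", {
  ev <- withr::with_seed(69, data.frame(
    CFP = sample(c(10, 1000), 300, TRUE), GREEN = sample(c(10, 1000), 300, TRUE),
    YFP = sample(c(10, 1000), 300, TRUE), RED = sample(c(10, 1000), 300, TRUE)))
  thr <- derive_thresholds(ev)
  out <- classify_table(ev, thr)
  ncol_pos <- lengths(strsplit(out$color_class, "+", fixed = TRUE))
  expect_true(all(out$color_class %in%
                    c(color_class_levels(), "negative", "unresolved")))
  expect_true(all(ncol_pos[!out$color_class %in%
                             c("negative", "unresolved")] <= 2))
  expect_gt(sum(out$color_class == "unresolved"), 0)
})
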