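test_that("modal chromosome counts map to exact ploidy multiples", {
  for (k in 1:6) {
    call <- count_to_ploidy(list(plant_id = "p",
                                 cell_counts = rep(k * 11L, 10)))
    expect_equal(call$ploidy, k)
    expect_equal(call$chromosome_number, k * 11L)
  }
  # occasional miscounts do not move the modal call
  call <- count_to_ploidy(list(plant_id = "p",
                               cell_counts = c(rep(33, 8), 32, 34)))
  expect_equal(call$ploidy, 3)
  # tolerance admits a modal count one off a multiple
  expect_equal(count_to_ploidy(list(plant_id = "p",
                                    cell_counts = rep(32, 10)))$ploidy, 3)
  # a data frame slice of a cytology table works directly
  cy <- generate_chromosome_counts(c(pA = 2L), seed = 3)
  expect_equal(count_to_ploidy(cy$counts)$ploidy, 2)
})

test_that("tied modal counts resolve to the lower count", {
  call <- count_to_ploidy(list(plant_id = "p",
                               cell_counts = c(22, 22, 33, 33)))
  expect_equal(call$chromosome_number, 22L)
  expect_equal(call$ploidy, 2)
})

test_that("counts far from any ploidy multiple are refused, not rounded", {
  expect_error(count_to_ploidy(list(plant_id = "p",
                                    cell_counts = rep(27, 10))),
               class = "musadicho_aneuploid")
  expect_error(count_to_ploidy(list(plant_id = "p", cell_counts = rep(5, 10)),
                               basic_number = 11, tolerance = 1),
               class = "musadicho_aneuploid")
})

test_that("peak detection recovers constructed peak positions", {
  h <- generate_flow_histogram(3, control_channel = 75, seed = 12)
  pk <- detect_peaks(h)
  expect_length(pk, 1)
  expect_lt(abs(pk - 75), 3)

  h2 <- generate_flow_histogram(2, control_channel = 75, seed = 12)
  pk2 <- detect_peaks(h2)
  expect_length(pk2, 2)
  expect_true(all(diff(pk2) > 0)) # ascending
  expect_lt(abs(pk2[1] - 50), 3)
  expect_lt(abs(pk2[2] - 75), 3)
})

test_that("structureless histograms raise a no-peaks error", {
  zero <- flow_histogram("z", 1:64, rep(0L, 64))
  expect_error(detect_peaks(zero), class = "musadicho_no_peaks")
  set.seed(99)
  noise <- flow_histogram("n", 1:128, 100L + sample(-2:2, 128, replace = TRUE))
  expect_error(detect_peaks(noise), class = "musadicho_no_peaks")
})

test_that("flow calls convert peak ratios to ploidy against the control", {
  h2 <- generate_flow_histogram(2, control_channel = 75, seed = 22)
  c2 <- call_ploidy_flow(h2, control_channel = 75)
  expect_equal(c2$ploidy, 2)
  expect_lt(abs(c2$ratio_to_control - 2 / 3), 0.05)

  # only the control-band peak present -> the sample shares the control ploidy
  h3 <- generate_flow_histogram(3, control_channel = 75, seed = 22)
  expect_equal(call_ploidy_flow(h3, control_channel = 75)$ploidy, 3)

  h4 <- generate_flow_histogram(4, control_channel = 75, seed = 22)
  c4 <- call_ploidy_flow(h4, control_channel = 75)
  expect_equal(c4$ploidy, 4)
  expect_lt(abs(c4$ratio_to_control - 4 / 3), 0.05)
})

test_that("off-position peaks are refused as unresolved", {
  # a clean peak at channel 62 sits 24% off the nearest ploidy position
  counts <- round(2000 * stats::dnorm(1:128, mean = 62, sd = 2))
  h <- flow_histogram("odd", 1:128, counts)
  expect_error(call_ploidy_flow(h, control_channel = 75),
               class = "musadicho_unresolved_ploidy")
})

test_that("flow calls are invariant to a rescaling of the channel axis", {
  h <- generate_flow_histogram(4, control_channel = 75, seed = 33)
  call1 <- call_ploidy_flow(h, control_channel = 75)
  h2 <- flow_histogram(h$plant_id, h$channels * 3L, h$counts)
  call2 <- call_ploidy_flow(h2, control_channel = 75 * 3)
  expect_equal(call1$ploidy, call2$ploidy)
  expect_equal(call1$ratio_to_control, call2$ratio_to_control)
})

test_that("cohort calls recover the generated truth across seeds", {
  comp <- data.frame(ploidy = c(2, 3, 4), count = c(3, 2, 2))
  for (s in 1:20) {
    coh <- generate_cohort(comp, cv = 0.05, debris_fraction = 0.20,
                           n_nuclei = 2000, seed = s)
    calls <- call_cohort(coh$histograms, control_channel = 75)
    expect_true(all(vapply(calls, inherits, logical(1), "ploidy_call")))
    got <- vapply(calls, `[[`, integer(1), "ploidy")
    expect_identical(got, unname(coh$truth$ploidy_truth))
  }
})

test_that("cohort summaries tally calls and surface refusals", {
  coh <- generate_cohort(data.frame(ploidy = c(2, 4), count = c(9, 1)),
                         seed = 44)
  s <- summarize_cohort(call_cohort(coh$histograms, control_channel = 75))
  expect_equal(s$tally[["2"]], 9L)
  expect_equal(s$tally[["4"]], 1L)
  expect_length(s$refused, 0)

  empty <- summarize_cohort(list())
  expect_length(empty$tally, 0)

  refused <- tryCatch(detect_peaks(flow_histogram("z", 1:8, rep(0L, 8))),
                      error = function(e) e)
  mixed <- summarize_cohort(list(ploidy_call("a", "flow", 2,
                                             peak_channel = 50,
                                             ratio_to_control = 2 / 3),
                                 refused))
  expect_equal(mixed$tally[["2"]], 1L)
  expect_length(mixed$refused, 1)
})

test_that("side-by-side tables keep counting and flow calls distinct", {
  cc <- ploidy_call("p1", "counting", 2, chromosome_number = 22)
  fc <- ploidy_call("p1", "flow", 4, peak_channel = 100,
                    ratio_to_control = 4 / 3)
  tab <- ploidy_table(list(cc), list(fc))
  expect_equal(tab$display, "2x (4x)")
})
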