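table5_row <- c(6L, 97L, 85L, 38L, 91L, 40L, 42L, 75L, 92L, 40L, 42L, 89L,
                57L, 93L, 94L, 43L)
table2_row <- c(904L, 5L, 10L, 10L, 8L, 3L, 9L, 13L, 7L, 8L, 5L, 14L, 9L,
                5L, 7L, 7L)

record_from_counts <- function(counts, mark = "0000",
                               init = "00000000000", shots = sum(counts)) {
  qwalkmer:::new_run_record(init, mark, counts, shots)
}

test_that("accuracy is marked-state hits over shots", {
  rec <- record_from_counts(table2_row)
  expect_equal(accuracy(rec)$accuracy, 904 / 1024)

  all_on <- record_from_counts(c(1024L, rep(0L, 15)))
  expect_equal(accuracy(all_on)$accuracy, 1)
  none <- record_from_counts(c(0L, 1024L, rep(0L, 14)))
  expect_equal(accuracy(none)$accuracy, 0)

  # vectorized over records, indexing each row by its own mark
  two <- dplyr::bind_rows(
    record_from_counts(table2_row, mark = "0000"),
    record_from_counts(table5_row, mark = "0001")
  )
  expect_equal(accuracy(two)$accuracy, c(904, 97) / 1024)
})

test_that("hit_sigma is the sample standard deviation of the 16 counts", {
  flat <- record_from_counts(rep(64L, 16))
  expect_equal(hit_sigma(flat)$sigma, 0)

  # frozen from direct computation on the printed avoidance-pattern row
  expect_equal(hit_sigma(record_from_counts(table5_row))$sigma, 28.4956,
               tolerance = 1e-4)
  # the all-zeros headline row lands deep in the Strong band
  s2 <- hit_sigma(record_from_counts(table2_row))$sigma
  expect_equal(s2, 224.0187, tolerance = 1e-4)
  expect_identical(as.character(categorize(s2)), "Strong")
})

test_that("hit_sigma is invariant under permutation of the counts", {
  set.seed(31)
  for (i in 1:20) {
    counts <- as.integer(stats::rmultinom(1, 1024, runif(16)))
    s1 <- hit_sigma(record_from_counts(counts))$sigma
    s2 <- hit_sigma(record_from_counts(sample(counts)))$sigma
    expect_equal(s1, s2)
  }
})

test_that("string_sigma pools deviations over a string's 16 mark runs", {
  marks <- qwalkmer:::node_state_labels()
  recs <- dplyr::bind_rows(lapply(marks, function(m) {
    record_from_counts(rep(64L, 16), mark = m)
  }))
  out <- string_sigma(recs)
  expect_identical(nrow(out), 1L)
  expect_equal(out$sigma, 0)

  # identical counts in every run: pooled sigma equals the per-run
  # population standard deviation
  recs2 <- dplyr::bind_rows(lapply(marks, function(m) {
    record_from_counts(table5_row, mark = m)
  }))
  expect_equal(string_sigma(recs2)$sigma, sd(table5_row) * sqrt(15 / 16))

  expect_error(string_sigma(recs[1:5, ]), "one record per mark")
  dup <- recs
  dup$mark <- rep("0000", 16)
  expect_error(string_sigma(dup), "one record per mark")
})

test_that("categorize assigns the documented intervals, left-inclusive", {
  expect_identical(as.character(categorize(28.53)), "Weak")
  expect_identical(as.character(categorize(49.26)), "Complex")
  expect_identical(as.character(categorize(14.7)), "Emerging")
  expect_identical(
    as.character(categorize(c(0, 14.69, 21, 39.99, 40, 50, 79.9, 80, 300))),
    c("Random", "Random", "Weak", "Weak", "Complex", "Clear", "Clear",
      "Strong", "Strong")
  )
  expect_error(categorize(-1), "non-negative")
  expect_error(category_scheme(breaks = c(5, 4, 3, 2, 1)), "increasing")
})

test_that("doubling shots at fixed proportions scales sigma up, never demoting", {
  set.seed(13)
  for (i in 1:10) {
    counts <- as.integer(stats::rmultinom(1, 1024, runif(16)^3))
    s1 <- hit_sigma(record_from_counts(counts))$sigma
    s2 <- hit_sigma(record_from_counts(2L * counts, shots = 2048L))$sigma
    expect_equal(s2, 2 * s1)
    c1 <- as.integer(categorize(s1))
    c2 <- as.integer(categorize(s2))
    expect_gte(c2, c1)
  }
})

test_that("category_census on an exactly uniform synthetic sweep is all Random", {
  sw <- uniform_sweep()
  cen <- category_census(sw)
  expect_s3_class(cen, "category_census")
  expect_identical(sum(cen$census$n_strings), 2048L)
  expect_identical(
    cen$census$n_strings[cen$census$category == "Random"], 2048L
  )
  expect_true(all(cen$strings$sigma == 0))

  expect_error(category_census(sw[-(1:16), ]), "incomplete sweep")
})

test_that("aux_effect pairs records and summarizes absolute hit differences", {
  marks <- qwalkmer:::node_state_labels()
  rec0 <- dplyr::bind_rows(lapply(marks, function(m) {
    record_from_counts(table5_row, mark = m, init = "00000000001")
  }))
  rec1 <- rec0
  rec1$aux <- "1"
  eff <- aux_effect(dplyr::bind_rows(rec0, rec1))
  expect_true(all(eff$differences$diff == 0))
  expect_equal(eff$mode, 0.5)
  expect_equal(eff$histogram$cumulative[nrow(eff$histogram)], 1)

  # independent multinomial draws of the same circuit: right-skewed |diff|
  probs <- rep(1 / 16, 16)
  draws0 <- dplyr::bind_rows(lapply(seq_along(marks), function(i) {
    record_from_counts(sample_counts(probs, 1024L, seed = 100 + i),
                       mark = marks[i], init = "00000000000")
  }))
  draws1 <- dplyr::bind_rows(lapply(seq_along(marks), function(i) {
    record_from_counts(sample_counts(probs, 1024L, seed = 200 + i),
                       mark = marks[i], init = "00000000000")
  }))
  draws1$aux <- "1"
  eff2 <- aux_effect(dplyr::bind_rows(draws0, draws1))
  d <- eff2$differences$diff
  expect_gt(mean(d), stats::median(d) - 1e-9) # right skew
  expect_gt(max(d), 5)

  expect_error(aux_effect(rec0), "unpaired")
  mixed <- dplyr::bind_rows(rec0, rec1[1:5, ])
  expect_error(aux_effect(mixed), "unpaired")
})

test_that("exact probabilities make the marked state argmax (search) or argmin (avoidance)", {
  marks <- qwalkmer:::node_state_labels()
  for (m in marks[c(1, 4, 7, 14)]) {
    p <- exact_node_distribution("00000000000", m)
    expect_identical(names(which.max(p)), m)
    p2 <- exact_node_distribution("00000000001", m)
    expect_identical(names(which.min(p2)), m)
  }
})

test_that("plot builders return ggplot objects", {
  rec <- record_from_counts(table2_row)
  expect_s3_class(plot_hit_distribution(rec), "ggplot")
  cen <- category_census(uniform_sweep())
  expect_s3_class(plot_sigma_histogram(cen), "ggplot")
  marks <- qwalkmer:::node_state_labels()
  rec0 <- dplyr::bind_rows(lapply(marks, function(m) {
    record_from_counts(table5_row, mark = m)
  }))
  rec1 <- rec0
  rec1$aux <- "1"
  eff <- aux_effect(dplyr::bind_rows(rec0, rec1))
  expect_s3_class(autoplot(eff), "ggplot")
  expect_s3_class(autoplot(eff, cumulative = TRUE), "ggplot")
})
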