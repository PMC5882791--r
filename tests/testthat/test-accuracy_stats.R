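test_that("3x3 table construction validates its counts", {
  m <- rbind(c(15, 4, 1), c(6, 20, 1), c(2, 0, 0))
  tab <- contingency_3x3(m, labels = c("confrontation", "app"))
  expect_equal(sum(tab$counts), 49L)
  expect_error(contingency_3x3(m[1:2, 1:2]), "3x3")
  expect_error(contingency_3x3(m - 3), "non-negative")
  expect_error(contingency_3x3(matrix(0, 3, 3)), "at least 1")
})

test_that("complete-case reduction drops the unable margins", {
  tab <- published_table()
  cc <- complete_case_2x2(tab)
  expect_equal(cc$core, matrix(c(15L, 6L, 4L, 20L), 2,
                               dimnames = list(c("positive", "negative"),
                                               c("positive", "negative"))))
  expect_equal(cc$n_useable, 45L)
  # empty third margins leave the core unchanged
  tab0 <- contingency_3x3(rbind(c(5, 2, 0), c(1, 7, 0), c(0, 0, 0)))
  expect_equal(complete_case_2x2(tab0)$core[1, 1], 5L)
  all_unable <- contingency_3x3(rbind(c(0, 0, 3), c(0, 0, 2), c(4, 1, 5)))
  expect_error(complete_case_2x2(all_unable), "degenerate")
})

test_that("accuracy measures honour the reference-axis convention", {
  core <- rbind(c(15, 4), c(6, 20))
  est_c <- accuracy_measures(core, "columns")
  expect_equal(est_c$sensitivity$estimate, 15 / 21)
  expect_equal(est_c$specificity$estimate, 20 / 24)
  expect_equal(est_c$ppv$estimate, 15 / 19)
  expect_equal(est_c$npv$estimate, 20 / 26)

  est_r <- accuracy_measures(core, "rows")
  expect_equal(est_r$sensitivity$estimate, 15 / 19)
  expect_equal(est_r$specificity$estimate, 20 / 26)
  expect_equal(est_r$ppv$estimate, 15 / 21)
  expect_equal(est_r$npv$estimate, 20 / 24)

  perfect <- accuracy_measures(diag(c(10, 10)), "columns")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(perfect[[m]]$estimate, 1)
  }
})

test_that("transpose duality holds exactly", {
  set.seed(9)
  for (i in 1:25) {
    core <- matrix(rpois(4, 12), 2)
    a <- accuracy_measures(core, "rows")
    b <- accuracy_measures(t(core), "columns")
    for (m in c("sensitivity", "specificity", "ppv", "npv")) {
      expect_identical(a[[m]], b[[m]])
    }
  }
})

test_that("zero denominators report undefined, never zero", {
  est <- accuracy_measures(rbind(c(0, 5), c(0, 7)), "columns")
  expect_true(is.na(est$sensitivity$estimate))
  expect_equal(est$sensitivity$denominator, 0)
})

test_that("exact binomial interval matches the tail-inversion oracle", {
  expect_equal(exact_binomial_ci(0, 10)[1], 0)
  expect_equal(exact_binomial_ci(10, 10)[2], 1)
  expect_equal(exact_binomial_ci(15, 21), c(0.478, 0.887), tolerance = 1e-3)
  set.seed(2)
  for (i in 1:30) {
    n <- sample(1:30, 1); x <- sample(0:n, 1)
    expect_equal(exact_binomial_ci(x, n), cp_oracle(x, n), tolerance = 1e-6)
  }
  # width shrinks as n grows at fixed x/n
  w <- vapply(c(1, 2, 4, 8), function(k) diff(exact_binomial_ci(3 * k, 4 * k)),
              numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(exact_binomial_ci(5, 4), "0 <= x <= n")
})

test_that("intention-to-diagnose policies count untestable results correctly", {
  tab <- published_table()
  cc <- itd_measures(tab, "columns", "complete-case")
  expect_equal(cc$n_useable, 45L)
  expect_equal(round(cc$sensitivity$estimate, 2), 0.71)

  # reference = rows (confrontation): unable app results score as incorrect
  iti <- itd_measures(tab, "rows", "untestable-as-incorrect")
  expect_equal(iti$sensitivity$numerator, 15L)
  expect_equal(iti$sensitivity$denominator, 20L) # 15 + 4 + 1
  expect_equal(iti$specificity$denominator, 27L)

  # with empty unable margins the two policies agree exactly
  tab0 <- contingency_3x3(rbind(c(9, 3, 0), c(2, 11, 0), c(0, 0, 0)))
  a <- itd_measures(tab0, "columns", "complete-case")
  b <- itd_measures(tab0, "columns", "untestable-as-incorrect")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_identical(a[[m]], b[[m]])
  }
})

test_that("paired sample size behaves like a McNemar calculation", {
  n_small <- paired_sensitivity_sample_size(0.5, 0.9)
  n_big <- paired_sensitivity_sample_size(0.5, 0.7)
  expect_lt(n_small, n_big) # larger effect, smaller n
  expect_identical(paired_sensitivity_sample_size(0.7, 0.5), n_big) # symmetry
  expect_error(paired_sensitivity_sample_size(0.6, 0.6), "undefined")

  # exact-enumeration oracle: trinomial distribution of discordant pairs,
  # asymptotic McNemar rejection rule, at the returned n for a large effect
  exact_power <- function(n, p0, p1) {
    p10 <- p1 * (1 - p0); p01 <- p0 * (1 - p1)
    pow <- 0
    for (k in 0:n) { # k discordant pairs
      pk <- dbinom(k, n, p10 + p01)
      if (k == 0) next
      j <- 0:k   # j of them favour test 1
      rej <- abs(2 * j - k) / sqrt(k) > qnorm(0.975)
      pow <- pow + pk * sum(dbinom(j, k, p10 / (p10 + p01))[rej])
    }
    pow
  }
  n <- paired_sensitivity_sample_size(0.5, 0.9, alpha = 0.05, power = 0.8)
  expect_lt(abs(exact_power(n, 0.5, 0.9) - 0.8), 0.1)
})

test_that("contingency CSV dialect round-trips", {
  tab <- published_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_contingency_csv(tab, path)
  back <- read_contingency_csv(path, labels = tab$labels)
  expect_identical(back$counts, tab$counts)
})

test_that("the formatted accuracy row mirrors the published layout", {
  est <- itd_measures(published_table(), "columns", "complete-case")
  row <- format_accuracy_row(est, comparison = "App vs confrontation")
  expect_match(row, "45")
  expect_match(row, "0.71 \\(0.48-0.89\\)")
})
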