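test_that("Fisher two-tailed p matches hand enumeration on known tables", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
})

test_that("Fisher agrees with enumeration and R's reference on random
           tables", {
  set.seed(12)
  for (i in 1:200) {
    m <- matrix(rpois(4, sample(1:5, 1)), 2)
    if (sum(m) == 0) m[1, 1] <- 1
    p <- fisher_exact_2x2(m)$p_value
    expect_equal(p, fisher_oracle(m), tolerance = 1e-12)
    # simultaneous row and column swap leaves p unchanged
    expect_equal(fisher_exact_2x2(m[2:1, 2:1])$p_value, p,
                 tolerance = 1e-12)
  }
  # spot-check the stats reference implementation on a few mixed tables
  for (m in list(matrix(c(8, 2, 3, 9), 2), matrix(c(1, 7, 6, 2), 2),
                 matrix(c(12, 5, 7, 14), 2))) {
    expect_equal(fisher_exact_2x2(m)$p_value,
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher stays exact at questionnaire-scale margins", {
  m <- matrix(c(130, 80, 40, 50), 2)  # margins in the hundreds
  expect_equal(fisher_exact_2x2(m)$p_value,
               stats::fisher.test(m)$p.value, tolerance = 1e-9)
})

test_that("degenerate margins yield p = 1 with a flag", {
  r <- fisher_exact_2x2(matrix(c(0, 3, 0, 5), 2))
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "empty")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Kruskal-Wallis reproduces hand-derived statistics", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical rank sums
  r2 <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis is rank-based and matches R's reference", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    samples <- lapply(seq_len(k), function(j)
      sample(1:8, sample(3:9, 1), replace = TRUE))  # plenty of ties
    if (length(unique(unlist(samples))) == 1L) next
    r <- kruskal_wallis(samples)
    # monotone transform invariance (values positive, cube preserves order)
    r3 <- kruskal_wallis(lapply(samples, function(v) v^3))
    expect_equal(r3$statistic, r$statistic, tolerance = 1e-12)
    # independent reference with its own tie correction
    g <- factor(rep(seq_len(k), lengths(samples)))
    ref <- stats::kruskal.test(unlist(samples), g)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-group H equals the squared standardized rank-sum", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- sample(1:1000, n1 + n2)  # no ties
    g1 <- v[1:n1]; g2 <- v[-(1:n1)]
    N <- n1 + n2
    R1 <- sum(rank(v)[1:n1])
    z <- (R1 - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(kruskal_wallis(list(g1, g2))$statistic, z^2,
                 tolerance = 1e-10)
  }
})

test_that("chi-square p approaches the exact permutation p as groups grow", {
  # the permutation p is an exact tail probability: for {1,2,3} vs {4,5,6}
  # only the observed split and its mirror reach H = 27/7, so p = 2/20
  expect_equal(kw_perm_oracle(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # the permutation distribution is coarse for tiny groups; by 8 + 8
  # untied observations the chi-square approximation is within 0.05 and
  # its mean error is smaller than at 3 + 3
  set.seed(77)
  d8 <- replicate(10, {
    v <- sample(1:1000, 16)
    abs(kruskal_wallis(list(v[1:8], v[-(1:8)]))$p_value -
          kw_perm_oracle(v[1:8], v[-(1:8)]))
  })
  expect_lt(max(d8), 0.05)
  d3 <- replicate(10, {
    v <- sample(1:1000, 6)
    abs(kruskal_wallis(list(v[1:3], v[-(1:3)]))$p_value -
          kw_perm_oracle(v[1:3], v[-(1:3)]))
  })
  expect_lt(mean(d8), mean(d3))
})

test_that("respondent crosstabs are complete-case 2x2 tables", {
  r <- data.frame(gender = c("male", "male", "female", "female"),
                  education = c("formal", "nonformal", "formal",
                                "nonformal"))
  ct <- respondent_crosstab(r, "gender", "education")
  expect_equal(unname(ct), matrix(1, 2, 2))
  # swapping the variables transposes the table
  expect_equal(respondent_crosstab(r, "education", "gender"), t(ct))
  # missing values drop out of the total
  r$gender[1] <- NA
  expect_equal(sum(respondent_crosstab(r, "gender", "education")), 3)
  r$age <- c(20, 30, 40, 50)
  expect_error(respondent_crosstab(r, "age", "gender"), "not binary")
})

test_that("the questionnaire comparison table has the report shape", {
  resp <- simulate_respondents(respondent_sim_params(seed = 6))
  tab <- survey_test_table(resp)
  expect_true(all(c("variable", "comparison", "statistic", "df",
                    "p_value") %in% names(tab)))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  # age differs strongly by education under the default generator
  kw_edu <- tab[tab$variable == "age" &
                  tab$comparison == "formal vs nonformal", ]
  expect_equal(kw_edu$df, 1L)
  expect_lt(kw_edu$p_value, 0.01)
})
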