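# Exact questionnaire statistics, implemented from first principles:
# two-tailed Fisher's exact test for 2x2 tables by full hypergeometric
# enumeration, and the Kruskal-Wallis rank test with tie correction.

.as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  v <- as.vector(m)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("2x2 cells must be non-negative integers")
  if (sum(v) == 0) stop("empty 2x2 table")
  m
}

# log hypergeometric pmf via log-factorials: exact at large margins
.lhyper <- function(a, r1, c1, n) {
  lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and enumerates every table they allow. The
#' two-tailed p-value follows the sum-of-small-probabilities rule: the sum
#' of the hypergeometric probabilities of all tables no more probable than
#' the observed one (with relative tolerance 1e-7 for floating-point
#' ties), the convention used by `fisher.test` in R. Probabilities are
#' computed through log-factorials, so margins in the hundreds remain
#' exact.
#'
#' @param table a 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts; rows and columns are the two binary variables.
#' @return An object of class `survey_test` (printable like an `htest`):
#'   `p_value`, `method`, `df = NA`, `statistic = NA`, and `degenerate`
#'   (`TRUE`, with `p_value = 1`, when a row or column margin is zero).
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))   # p = 1/3
#' @export
fisher_exact_2x2 <- function(table) {
  m <- .as_2x2(table)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(structure(list(statistic = NA_real_, df = NA_integer_,
                          p_value = 1, degenerate = TRUE,
                          method = "Fisher's exact test (two-tailed)"),
                     class = "survey_test"))
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  logp <- .lhyper(support, r1, c1, n)
  p_obs <- exp(.lhyper(m[1, 1], r1, c1, n))
  p <- sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
  structure(list(statistic = NA_real_, df = NA_integer_,
                 p_value = min(p, 1), degenerate = FALSE,
                 method = "Fisher's exact test (two-tailed)"),
            class = "survey_test")
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Assigns mid-ranks (ties averaged) to the pooled observations, computes
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)` from the group
#' rank sums, divides by the tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`, and refers the result to the chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @param samples a list of two or more non-empty numeric vectors (one per
#'   group), or a single numeric vector together with `g`.
#' @param g optional grouping factor/vector parallel to `samples`.
#' @return A `survey_test` object with `statistic` (tie-corrected H),
#'   `df = k - 1` and the chi-square upper-tail `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 27/7
#' @export
kruskal_wallis <- function(samples, g = NULL) {
  if (!is.null(g)) samples <- split(as.numeric(samples), g)
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (any(lengths(samples) == 0L)) stop("every group must be non-empty")
  v <- unlist(samples, use.names = FALSE)
  N <- length(v)
  if (N < 3L) stop("need at least 3 observations in total")
  if (length(unique(v)) == 1L)
    stop("undefined statistic: all observations identical")
  rk <- rank(v)  # mid-ranks
  sizes <- lengths(samples)
  ends <- cumsum(sizes)
  Rj <- vapply(seq_along(samples), function(j)
    sum(rk[(ends[j] - sizes[j] + 1L):ends[j]]), numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  tie <- table(v)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H <- H / C
  df <- length(samples) - 1L
  structure(list(statistic = H, df = df,
                 p_value = stats::pchisq(H, df, lower.tail = FALSE),
                 degenerate = FALSE,
                 method = "Kruskal-Wallis rank sum test (tie-corrected)"),
            class = "survey_test")
}

#' @export
print.survey_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %.4f, df = %d, ", x$statistic, x$df))
  else cat("  ")
  cat(sprintf("p = %.4g%s\n", x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate table)" else ""))
  invisible(x)
}

#' Cross-tabulate two binary respondent variables
#'
#' @param table a `respondent_table` (see [simulate_respondents()]) or any
#'   data frame.
#' @param row_var,col_var names of binary-coded columns (exactly two
#'   observed levels each). Respondents missing either value are excluded.
#' @return A 2x2 integer matrix with level-labelled dimnames, rows sorted
#'   by level.
#' @export
respondent_crosstab <- function(table, row_var, col_var) {
  for (v in c(row_var, col_var)) {
    if (!v %in% names(table)) stop("no such column: ", v)
    lev <- sort(unique(stats::na.omit(as.character(table[[v]]))))
    if (length(lev) != 2L)
      stop("column '", v, "' is not binary: levels ",
           paste(lev, collapse = ", "))
  }
  keep <- !is.na(table[[row_var]]) & !is.na(table[[col_var]])
  out <- base::table(table[[row_var]][keep], table[[col_var]][keep])
  matrix(as.integer(out), 2L, 2L, dimnames = dimnames(out))
}

#' Standard questionnaire comparison table
#'
#' Runs the usual respondent comparisons — age by gender and by education
#' (Kruskal-Wallis), and each binary response by education (two-tailed
#' Fisher) — and returns them in the conventional report shape.
#'
#' @param respondents a `respondent_table`.
#' @param questions binary response columns to compare across education
#'   groups; default: every column beyond id/age/gender/education.
#' @return A data frame with columns `variable`, `comparison`, `test`,
#'   `statistic`, `df`, `p_value`.
#' @export
survey_test_table <- function(respondents, questions = NULL) {
  questions <- questions %||%
    setdiff(names(respondents),
            c("respondent_id", "age", "gender", "education"))
  row <- function(variable, comparison, test)
    data.frame(variable = variable, comparison = comparison,
               test = sub(" \\(.*", "", test$method),
               statistic = if (is.na(test$statistic)) NA_real_ else
                 test$statistic,
               df = if (is.na(test$df)) NA_integer_ else test$df,
               p_value = test$p_value, stringsAsFactors = FALSE)
  out <- list(
    row("age", "male vs female",
        kruskal_wallis(respondents$age, respondents$gender)),
    row("age", "formal vs nonformal",
        kruskal_wallis(respondents$age, respondents$education)),
    row("gender", "formal vs nonformal",
        fisher_exact_2x2(respondent_crosstab(respondents, "gender",
                                             "education"))))
  for (q in questions)
    out <- c(out, list(row(q, "formal vs nonformal",
                           fisher_exact_2x2(
                             respondent_crosstab(respondents, q,
                                                 "education")))))
  do.call(rbind, out)
}
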