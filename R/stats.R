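#' Mixed-model ANOVA for one strike variable
#'
#' Two-way mixed model with setup (open/walled) fixed and individual and
#' setup x individual random. For balanced designs the classical
#' expected-mean-squares F-tests are used: the setup and individual mean
#' squares are tested against the setup x individual mean square, and the
#' interaction against the residual. For unbalanced designs the model is
#' fitted by REML and the setup effect tested with a Satterthwaite
#' approximate denominator; the random terms are tested by likelihood
#' ratio.
#'
#' @param data Data frame with columns `individual`, `setup` and the
#'   response.
#' @param response Name of the response column (default `"value"`).
#' @return An object of class `strike_anova`: a table of terms with df,
#'   sums of squares / mean squares (balanced case), test statistics and
#'   p-values, plus the method used.
#' @export
mixed_anova <- function(data, response = "value") {
  for (col in c("individual", "setup", response))
    if (!col %in% names(data))
      stop("`data` must contain column '", col, "'", call. = FALSE)
  data$individual <- factor(data$individual)
  data$setup <- factor(data$setup)
  if (nlevels(data$individual) < 2L)
    stop("need at least 2 individuals", call. = FALSE)
  if (nlevels(data$setup) != 2L)
    stop("both setups must be present", call. = FALSE)
  counts <- table(data$individual, data$setup)
  if (any(counts < 2L)) {
    bad <- which(counts < 2L, arr.ind = TRUE)[1L, ]
    stop(sprintf("cell individual=%s, setup=%s has fewer than 2 trials",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  y <- data[[response]]
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  balanced <- length(unique(as.vector(counts))) == 1L

  if (balanced) {
    fit <- stats::aov(stats::reformulate("setup * individual", response),
                      data = data)
    ss <- summary(fit)[[1L]]
    rn <- trimws(rownames(ss))
    ms <- ss[["Mean Sq"]]; df <- ss[["Df"]]; sumsq <- ss[["Sum Sq"]]
    i_s <- match("setup", rn); i_i <- match("individual", rn)
    i_x <- match("setup:individual", rn); i_e <- match("Residuals", rn)
    Fv <- c(ms[i_s] / ms[i_x], ms[i_i] / ms[i_x], ms[i_x] / ms[i_e])
    den_df <- c(df[i_x], df[i_x], df[i_e])
    num_df <- c(df[i_s], df[i_i], df[i_x])
    p <- stats::pf(Fv, num_df, den_df, lower.tail = FALSE)
    tab <- data.frame(term = c("setup", "individual", "setup:individual"),
                      df = num_df, sum_sq = sumsq[c(i_s, i_i, i_x)],
                      mean_sq = ms[c(i_s, i_i, i_x)],
                      den_df = den_df, statistic = Fv, p = p,
                      stringsAsFactors = FALSE)
    out <- list(table = tab, residual = data.frame(df = df[i_e],
                                                   sum_sq = sumsq[i_e],
                                                   mean_sq = ms[i_e]),
                method = "EMS", balanced = TRUE)
  } else {
    data$.cell <- interaction(data$setup, data$individual)
    form <- stats::reformulate(c("setup", "(1 | individual)", "(1 | .cell)"),
                               response)
    fit <- suppressMessages(lmerTest::lmer(form, data = data))
    a <- stats::anova(fit)  # Satterthwaite ddf
    r <- suppressMessages(lmerTest::ranova(fit))
    rr <- as.data.frame(r)
    ind_row <- grep("individual", rownames(rr))[1L]
    int_row <- grep("\\.cell", rownames(rr))[1L]
    tab <- data.frame(
      term = c("setup", "individual", "setup:individual"),
      df = c(a[["NumDF"]][1L], 1, 1),
      sum_sq = NA_real_, mean_sq = NA_real_,
      den_df = c(a[["DenDF"]][1L], NA, NA),
      statistic = c(a[["F value"]][1L], rr$LRT[ind_row], rr$LRT[int_row]),
      p = c(a[["Pr(>F)"]][1L], rr[["Pr(>Chisq)"]][ind_row],
            rr[["Pr(>Chisq)"]][int_row]),
      stringsAsFactors = FALSE)
    out <- list(table = tab, residual = NULL,
                method = "REML-Satterthwaite", balanced = FALSE)
  }
  out$response <- response
  class(out) <- "strike_anova"
  out
}

#' @export
print.strike_anova <- function(x, ...) {
  cat(sprintf("Mixed-model ANOVA for '%s' (%s%s)\n", x$response, x$method,
              if (x$balanced) ", balanced" else ", unbalanced"))
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = 4)
  print(tab, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Brown--Forsythe test of variance homogeneity
#'
#' Levene's test on absolute deviations from the group medians,
#' `z_ij = |y_ij - median_j|`, followed by a one-way ANOVA F-test on z.
#'
#' @param values Numeric observations.
#' @param groups Grouping vector (>= 2 groups, each with >= 2
#'   observations).
#' @return A list with `statistic` (F), `df1`, `df2`, `p`.
#' @export
brown_forsythe <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- table(groups)
  if (any(n < 2L))
    stop(sprintf("group '%s' has fewer than 2 observations",
                 names(n)[which(n < 2L)[1L]]), call. = FALSE)
  lt <- car::leveneTest(values, groups, center = stats::median)
  list(statistic = lt[["F value"]][1L], df1 = lt[["Df"]][1L],
       df2 = lt[["Df"]][2L], p = lt[["Pr(>F)"]][1L])
}

#' Holm step-down multiplicity correction
#'
#' Step-down Bonferroni: sort p ascending and reject while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure. Adjusted
#' p-values are the running maxima of `(m - i + 1) p_(i)` capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error rate (default 0.05).
#' @return A list with `adjusted` (Holm-adjusted p, input order) and
#'   `reject` (logical flags at `alpha`).
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(p, method = "holm")
  list(adjusted = adjusted, reject = adjusted <= alpha, alpha = alpha)
}

#' Setup-variance comparisons per variable
#'
#' Brown--Forsythe comparisons of the two setups: pooled across
#' individuals, and within each individual (both readings of
#' "greater variation in one setup than the other" are reported).
#'
#' @param data Data frame with `individual`, `setup` and the response.
#' @param response Response column name.
#' @return Data frame with columns `scope`, `statistic`, `df1`, `df2`, `p`.
#' @export
setup_variance_tests <- function(data, response = "value") {
  y <- data[[response]]
  out <- list(c(scope = "pooled",
                brown_forsythe(y, data$setup)[c("statistic", "df1", "df2", "p")]))
  for (id in unique(data$individual)) {
    sel <- data$individual == id
    out[[length(out) + 1L]] <-
      c(scope = as.character(id),
        brown_forsythe(y[sel], data$setup[sel])[c("statistic", "df1", "df2", "p")])
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Statistical layer over a per-trial metric table
#'
#' Runs the per-variable mixed-model ANOVA and the pooled Brown--Forsythe
#' setup-variance test for each listed variable, then applies the Holm
#' step-down correction across variables within each family of tests
#' (the setup effects form one family, the variance tests another).
#'
#' @param metric_table Data frame with `individual`, `setup` and one
#'   column per variable (e.g. rows of [as.data.frame.strike_analysis()]
#'   or [generate_cohort()] output).
#' @param variables Character vector of variable columns to test (default:
#'   all numeric columns other than bookkeeping ones).
#' @param alpha Family-wise error rate (default 0.05).
#' @return An object of class `strike_stats`: a summary data frame
#'   (`$table`) plus the full per-variable `strike_anova` fits.
#' @export
strike_stats <- function(metric_table, variables = NULL, alpha = 0.05) {
  if (is.null(variables)) {
    skip <- c("individual", "setup", "trial", "theta")
    variables <- names(metric_table)[vapply(metric_table, is.numeric, TRUE)]
    variables <- setdiff(variables, skip)
  }
  fits <- lapply(variables, function(v) mixed_anova(metric_table, v))
  names(fits) <- variables
  get1 <- function(f, term, col)
    f$table[[col]][f$table$term == term]
  tab <- data.frame(
    variable = variables,
    setup_F = vapply(fits, get1, 0, term = "setup", col = "statistic"),
    setup_p = vapply(fits, get1, 0, term = "setup", col = "p"),
    individual_stat = vapply(fits, get1, 0, term = "individual", col = "statistic"),
    individual_p = vapply(fits, get1, 0, term = "individual", col = "p"),
    interaction_stat = vapply(fits, get1, 0, term = "setup:individual", col = "statistic"),
    interaction_p = vapply(fits, get1, 0, term = "setup:individual", col = "p"),
    stringsAsFactors = FALSE)
  bf <- lapply(variables, function(v) brown_forsythe(metric_table[[v]],
                                                     metric_table$setup))
  tab$bf_F <- vapply(bf, `[[`, 0, "statistic")
  tab$bf_p <- vapply(bf, `[[`, 0, "p")
  h_setup <- holm_adjust(tab$setup_p, alpha)
  h_bf <- holm_adjust(tab$bf_p, alpha)
  tab$setup_p_holm <- h_setup$adjusted
  tab$setup_significant <- h_setup$reject
  tab$bf_p_holm <- h_bf$adjusted
  tab$bf_significant <- h_bf$reject
  structure(list(table = tab, fits = fits, alpha = alpha),
            class = "strike_stats")
}

#' @export
print.strike_stats <- function(x, ...) {
  cat(sprintf("Per-variable setup comparisons (Holm-corrected at alpha = %.2f)\n",
              x$alpha))
  tab <- x$table
  for (col in grep("_p", names(tab))) tab[[col]] <- signif(tab[[col]], 4)
  print(tab[, c("variable", "setup_F", "setup_p", "setup_p_holm",
                "setup_significant", "bf_F", "bf_p", "bf_p_holm",
                "bf_significant")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
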