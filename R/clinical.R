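#' Two-group summary statistics
#'
#' A `mean +/- sd` summary of one measurement in one patient group, the
#' form in which baseline tables of two-arm clinical studies are printed.
#'
#' @param label group label.
#' @param n group size (at least 2).
#' @param mean sample mean.
#' @param sd sample standard deviation (non-negative).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (!is.finite(mean)) stop("`mean` must be finite", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  structure(list(label = as.character(label), n = n, mean = mean, sd = sd),
            class = "group_summary")
}

#' Two-sample t-test from group summaries
#'
#' The classic two-sample t-test computed from `(n, mean, sd)` summaries
#' rather than raw data.  `"pooled"` (the default) uses the pooled-variance
#' statistic with `n1 + n2 - 2` degrees of freedom; `"welch"` uses the
#' unequal-variance statistic with Welch-Satterthwaite degrees of freedom.
#' The p-value is two-sided.
#'
#' @param a,b [group_summary] objects.
#' @param variant `"pooled"` or `"welch"`.
#' @return An object of class `summary_ttest`: a list with `statistic`,
#'   `df`, `p_value`, `estimate` (mean difference a - b) and `variant`.
#' @examples
#' ctrl <- group_summary("control", 20, 74.09, 2.67)
#' obs  <- group_summary("observation", 20, 74.33, 2.16)
#' t_test_from_summaries(ctrl, obs)$p_value
#' @export
t_test_from_summaries <- function(a, b, variant = c("pooled", "welch")) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  variant <- match.arg(variant)
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    stop("undefined statistic: both groups have zero variance and equal means",
         call. = FALSE)
  }
  diff <- a$mean - b$mean
  if (variant == "pooled") {
    df <- a$n + b$n - 2L
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    v1 <- a$sd^2 / a$n
    v2 <- b$sd^2 / b$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  }
  if (se == 0) stop("undefined statistic: zero standard error", call. = FALSE)
  t <- diff / se
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 estimate = diff, variant = variant,
                 labels = c(a$label, b$label)),
            class = "summary_ttest")
}

#' @export
print.summary_ttest <- function(x, ...) {
  cat(sprintf("%s two-sample t-test (%s vs %s): t = %.4f, df = %.2f, p = %.4g\n",
              x$variant, x$labels[1], x$labels[2], x$statistic, x$df, x$p_value))
  invisible(x)
}

#' 2x2 contingency table of events by group
#'
#' Event counts (e.g. dyskinesia cases) out of `n` patients in each of two
#' groups, the "case (\%)" form in which incidence tables are printed.
#'
#' @param events integer vector of 2 event counts.
#' @param sizes integer vector of 2 group sizes.
#' @param labels character vector of 2 group labels.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(c(7, 1), c(20, 20), c("control", "observation"))
#' @export
contingency_2x2 <- function(events, sizes, labels = c("group1", "group2")) {
  events <- as.integer(events); sizes <- as.integer(sizes)
  if (length(events) != 2L || length(sizes) != 2L) {
    stop("`events` and `sizes` must each have 2 entries", call. = FALSE)
  }
  if (any(sizes < 1L)) stop("group sizes must be at least 1", call. = FALSE)
  if (any(events < 0L) || any(events > sizes)) {
    stop("each event count must lie in [0, n]", call. = FALSE)
  }
  structure(list(events = events, sizes = sizes,
                 labels = as.character(labels)),
            class = "contingency_2x2")
}

as_matrix_2x2 <- function(table) {
  m <- rbind(c(table$events[1], table$sizes[1] - table$events[1]),
             c(table$events[2], table$sizes[2] - table$events[2]))
  dimnames(m) <- list(table$labels, c("event", "no_event"))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' The chi-square test of equal event proportions, by default without
#' continuity correction; Yates' correction is selectable.  One degree of
#' freedom; two-sided p-value.  The result flags tables with any expected
#' count below 5, for which [fisher_exact_2x2()] is the safer choice.
#'
#' @param table a [contingency_2x2].
#' @param correction `"none"` (default) or `"yates"`.
#' @return An object of class `chisq_2x2`: a list with `statistic`, `df`,
#'   `p_value`, `expected`, `correction` and `small_expected`.
#' @examples
#' tab <- contingency_2x2(c(7, 1), c(20, 20))
#' chi_square_2x2(tab)$p_value
#' @export
chi_square_2x2 <- function(table, correction = c("none", "yates")) {
  stopifnot(inherits(table, "contingency_2x2"))
  correction <- match.arg(correction)
  m <- as_matrix_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a zero marginal leaves the statistic undefined",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correction == "yates"))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 expected = ht$expected,
                 correction = correction,
                 small_expected = any(ht$expected < 5)),
            class = "chisq_2x2")
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat(sprintf("chi-square (2x2, correction: %s): X2 = %.4f, df = %d, p = %.4g%s\n",
              x$correction, x$statistic, x$df, x$p_value,
              if (x$small_expected) "  [expected count < 5: consider Fisher]" else ""))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities no larger than that
#' of the observed table.  Preferable to the chi-square test when expected
#' counts are small (e.g. a 0-event arm).
#'
#' @param table a [contingency_2x2].
#' @return A list with `p_value` and `odds_ratio` (conditional MLE).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  ht <- stats::fisher.test(as_matrix_2x2(table))
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Incidence percentage for one group
#'
#' `100 * events / n` for the requested group of a [contingency_2x2].
#'
#' @param table a [contingency_2x2].
#' @param group group label or index (1 or 2).
#' @return The incidence in percent.
#' @examples
#' incidence_percent(contingency_2x2(c(7, 1), c(20, 20)), 1)   # 35
#' @export
incidence_percent <- function(table, group) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (is.character(group)) group <- match(group, table$labels)
  if (is.na(group) || !group %in% c(1L, 2L)) {
    stop("`group` must name or index one of the two groups", call. = FALSE)
  }
  100 * table$events[group] / table$sizes[group]
}

#' Clinical rating-scale specification
#'
#' Direction metadata for the rating scales used to follow Parkinson's
#' disease patients: UPDRS (higher scores mean worse motor condition),
#' MoCA (cognition, 30 points, scores above 26 considered normal) and
#' MMSE (mental state, lower scores mean worse).
#'
#' @param name `"UPDRS"`, `"MoCA"` or `"MMSE"`.
#' @return An object of class `scale_spec`: a list with `name`,
#'   `direction` (`"higher_is_worse"` or `"higher_is_better"`),
#'   `max_score` and `normal_cutoff` (either may be `NA`).
#' @export
scale_spec <- function(name = c("UPDRS", "MoCA", "MMSE")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown scale", call. = FALSE))
  spec <- switch(name,
    UPDRS = list(direction = "higher_is_worse", max_score = NA_integer_,
                 normal_cutoff = NA_integer_),
    MoCA  = list(direction = "higher_is_better", max_score = 30L,
                 normal_cutoff = 26L),
    MMSE  = list(direction = "higher_is_better", max_score = 30L,
                 normal_cutoff = NA_integer_)
  )
  structure(c(list(name = name), spec), class = "scale_spec")
}

#' Interpret a before/after change on a clinical scale
#'
#' Classifies a score change as improvement, worsening or no change,
#' respecting the direction of the scale: a UPDRS decrease is an
#' improvement, while MoCA and MMSE increases are improvements.  When the
#' scale has a normality cutoff (MoCA: above 26 is normal), an improving
#' change that crosses it sets `crossed_normal`.
#'
#' @param scale a [scale_spec] (or a scale name).
#' @param before,after scores before and after treatment.
#' @return A list with `assessment` (`"improved"`, `"worsened"` or
#'   `"unchanged"`) and `crossed_normal` (logical).
#' @examples
#' interpret_score_change(scale_spec("UPDRS"), 40, 30)$assessment   # improved
#' @export
interpret_score_change <- function(scale, before, after) {
  if (is.character(scale)) scale <- scale_spec(scale)
  stopifnot(inherits(scale, "scale_spec"))
  if (!is.finite(before) || !is.finite(after)) {
    stop("scores must be finite", call. = FALSE)
  }
  delta <- after - before
  assessment <- if (delta == 0) "unchanged"
    else if ((scale$direction == "higher_is_better") == (delta > 0)) "improved"
    else "worsened"
  crossed <- !is.na(scale$normal_cutoff) && assessment == "improved" &&
    before <= scale$normal_cutoff && after > scale$normal_cutoff
  list(assessment = assessment, crossed_normal = crossed)
}

#' Read group summaries from a delimited file
#'
#' Expects columns `group`, `n`, `mean`, `sd`, and optionally `measure`
#' for files holding several measurements.
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension).
#' @param measure optional measure name to filter on.
#' @return A list of [group_summary] objects, one per row.
#' @export
read_group_summaries <- function(path, measure = NULL) {
  df <- read_delimited(path, c("group", "n", "mean", "sd"))
  if (!is.null(measure)) {
    if (!"measure" %in% names(df)) stop("file has no `measure` column", call. = FALSE)
    df <- df[df$measure == measure, , drop = FALSE]
    if (nrow(df) == 0L) stop("no rows for measure '", measure, "'", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    group_summary(df$group[i], df$n[i], df$mean[i], df$sd[i])
  })
}

#' Read a 2x2 contingency table from a delimited file
#'
#' Expects columns `group`, `n`, `events`, and optionally `outcome` for
#' files holding several outcomes; exactly two rows must remain after
#' filtering.
#'
#' @param path CSV/TSV file path.
#' @param outcome optional outcome name to filter on.
#' @return A [contingency_2x2].
#' @export
read_contingency_2x2 <- function(path, outcome = NULL) {
  df <- read_delimited(path, c("group", "n", "events"))
  if (!is.null(outcome)) {
    if (!"outcome" %in% names(df)) stop("file has no `outcome` column", call. = FALSE)
    df <- df[df$outcome == outcome, , drop = FALSE]
  }
  if (nrow(df) != 2L) stop("expected exactly 2 group rows, got ", nrow(df),
                           call. = FALSE)
  contingency_2x2(df$events, df$n, df$group)
}

read_delimited <- function(path, required) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
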