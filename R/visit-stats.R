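#' Grouping scheme for visit-time analysis
#'
#' Age bands are half-open intervals partitioning `[0, Inf)`; the default
#' follows paediatric convention (infancy, early childhood, pre-school,
#' school age) then decades, with age 12 belonging to the adolescent band.
#' Diagnosis counts group as 1 / 2 / 3+.
#'
#' @param age_breaks increasing break points starting at 0; bands are
#'   `[b[i], b[i+1])` with a final `[b[last], Inf)` band.
#' @param t1_milestone which milestone anchors the post-diagnosis duration
#'   T1: the dispensing time with payment as fallback (default), or the
#'   payment time with dispensing as fallback.
#' @return A `group_scheme` object.
#' @export
group_scheme <- function(age_breaks = c(0, 1, 3, 6, 12, 20, 30, 40, 50, 60),
                         t1_milestone = c("dispense", "payment")) {
  if (age_breaks[1] != 0 || is.unsorted(age_breaks, strictly = TRUE)) {
    stop_invalid("`age_breaks` must strictly increase from 0")
  }
  structure(list(age_breaks = age_breaks,
                 t1_milestone = match.arg(t1_milestone)),
            class = "group_scheme")
}

age_band_labels <- function(breaks) {
  upper <- c(breaks[-1], Inf)
  sprintf("[%s,%s)", breaks, ifelse(is.infinite(upper), "Inf", upper))
}

#' Assign ages to bands
#'
#' @param age non-negative ages in years.
#' @param scheme a [group_scheme()].
#' @return Factor with one level per band; every age maps to exactly one.
#' @export
assign_age_band <- function(age, scheme = group_scheme()) {
  if (any(age < 0)) stop_invalid("ages must be non-negative")
  labs <- age_band_labels(scheme$age_breaks)
  cut(age, breaks = c(scheme$age_breaks, Inf), labels = labs,
      right = FALSE)
}

#' Visit durations T1 and T2 from milestone timestamps
#'
#' T2, the diagnosis time, is the earliest diagnosis time minus the
#' receipt (pickup) time. T1, the visit time after diagnosis measure, is
#' the dispensing time (or, when absent, the payment time) minus the
#' receipt time - both anchored at receipt, so T1 includes the diagnosis
#' interval; the difference `t1_post = T1 - T2` is also returned. A record
#' is unusable when a needed timestamp is missing or a duration is
#' negative; missingness is a state, not an error.
#'
#' @param records a `visit_records` data frame (see
#'   [generate_visit_records()] / [read_visit_records()]).
#' @param scheme a [group_scheme()] (controls the T1 milestone
#'   preference).
#' @return The records with added columns `T1`, `T2`, `t1_post` (minutes)
#'   and `usable`.
#' @examples
#' rec <- generate_visit_records(synthetic_visit_config(n_records = 50))
#' head(compute_durations(rec)[, c("T1", "T2", "usable")])
#' @export
compute_durations <- function(records, scheme = group_scheme()) {
  minutes <- function(a, b) as.numeric(difftime(a, b, units = "mins"))
  t2 <- minutes(records$t_diagnosis, records$t_receipt)
  t1 <- if (scheme$t1_milestone == "dispense") {
    ifelse(!is.na(records$t_dispense),
           minutes(records$t_dispense, records$t_receipt),
           minutes(records$t_payment, records$t_receipt))
  } else {
    ifelse(!is.na(records$t_payment),
           minutes(records$t_payment, records$t_receipt),
           minutes(records$t_dispense, records$t_receipt))
  }
  records$T1 <- t1
  records$T2 <- t2
  records$t1_post <- t1 - t2
  records$usable <- !is.na(t1) & !is.na(t2) & t1 >= 0 & t2 >= 0
  records
}

#' Usable-record count and fraction
#'
#' @param records records with durations (see [compute_durations()]).
#' @return List with `n_usable`, `n_total`, `fraction`.
#' @export
usable_fraction <- function(records) {
  if (nrow(records) == 0L) stop_invalid("no records")
  if (is.null(records$usable)) records <- compute_durations(records)
  n <- sum(records$usable)
  list(n_usable = n, n_total = nrow(records), fraction = n / nrow(records))
}

primary_diagnosis <- function(records) {
  vapply(strsplit(records$diagnoses, ";", fixed = TRUE), `[[`, character(1), 1L)
}

record_factors <- function(records, scheme) {
  cats <- disease_categories()
  prim <- primary_diagnosis(records)
  bad <- setdiff(unique(unlist(strsplit(records$diagnoses, ";", fixed = TRUE))),
                 cats)
  if (length(bad)) {
    stop_invalid("unknown disease category: ", paste(bad, collapse = ", "))
  }
  list(sex = factor(records$sex, levels = c("Male", "Female")),
       age_band = assign_age_band(records$age, scheme),
       n_diagnoses = factor(pmin(records$n_diagnoses, 3L), levels = 1:3,
                            labels = c("1", "2", "3+")),
       disease_type = factor(prim, levels = cats))
}

#' Per-factor frequency and percentage table
#'
#' Counts and percentages of the usable records for each level of sex,
#' age band, number of diagnoses and (primary) disease type; percentages
#' are computed within each factor's own denominator.
#'
#' @inheritParams compute_durations
#' @return Data frame: `factor`, `level`, `n`, `percent`.
#' @export
group_summary <- function(records, scheme = group_scheme()) {
  if (is.null(records$usable)) records <- compute_durations(records, scheme)
  records <- records[records$usable, , drop = FALSE]
  if (nrow(records) == 0L) stop_invalid("no usable records")
  f <- record_factors(records, scheme)
  do.call(rbind, lapply(names(f), function(nm) {
    tab <- table(f[[nm]])
    data.frame(factor = nm, level = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
}

shapiro_p <- function(x) {
  if (length(x) < 3L) return(0)      # cannot verify normality
  if (length(x) > 5000L) x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  if (diff(range(x)) == 0) return(0)
  shapiro.test(x)$p.value
}

#' Compare visit durations across groups with automatic test selection
#'
#' Two groups are compared with a two-sample t-test. More than two groups
#' use one-way ANOVA when each group passes Shapiro-Wilk normality
#' (alpha 0.05) and Levene's test finds homogeneous variances
#' (alpha 0.05); otherwise the Kruskal-Wallis H test is used. Significance
#' is declared at P < 0.05. The selection is a pure function of the data's
#' normality and homoscedasticity flags.
#'
#' @param values numeric durations.
#' @param labels group memberships (coerced to factor); every group must
#'   have at least 2 observations.
#' @param alpha significance level for the assumption gates and the
#'   reported `significant` flag.
#' @return A `group_comparison`: `test` ("t-test", "anova" or
#'   "kruskal-wallis"), `statistic`, `p.value`, `significant`, plus the
#'   gate p-values (`normality_p`, `levene_p`).
#' @examples
#' compare_groups(c(rnorm(30), rnorm(30, 2)), rep(c("a", "b"), each = 30))
#' @export
compare_groups <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- droplevels(factor(labels[keep]))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop_invalid("need at least 2 non-empty groups")
  if (any(sizes < 2L)) {
    stop_invalid("group(s) with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  norm_p <- min(vapply(split(values, labels), shapiro_p, numeric(1)))
  lev <- car::leveneTest(values ~ labels, center = "mean")
  lev_p <- lev[["Pr(>F)"]][1L]
  if (nlevels(labels) == 2L) {
    ht <- t.test(values ~ labels, var.equal = lev_p >= alpha)
    res <- list(test = "t-test", statistic = unname(ht$statistic),
                p.value = ht$p.value)
  } else if (norm_p >= alpha && lev_p >= alpha) {
    fit <- aov(values ~ labels)
    tab <- summary(fit)[[1L]]
    res <- list(test = "anova", statistic = tab[["F value"]][1L],
                p.value = tab[["Pr(>F)"]][1L])
  } else {
    ht <- kruskal.test(values, labels)
    res <- list(test = "kruskal-wallis", statistic = unname(ht$statistic),
                p.value = ht$p.value)
  }
  structure(c(res, list(significant = res$p.value < alpha,
                        normality_p = norm_p, levene_p = lev_p,
                        n_groups = nlevels(labels))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, p %s (%d groups)%s\n", x$test,
              x$statistic, format.pval(x$p.value, digits = 3), x$n_groups,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Influence-factor report for T1 and T2
#'
#' Runs [compare_groups()] for each factor (sex, age band, number of
#' diagnoses, disease type) against both durations and returns a table
#' with one row per factor level (matching [group_summary()]), the
#' factor-level p-values repeated within each factor. Raw p-values are
#' reported by default; set `adjust = "bonferroni"` (or any
#' [stats::p.adjust()] method) to correct across factors.
#'
#' @inheritParams compute_durations
#' @param adjust multiple-testing correction across factors
#'   (default `"none"`).
#' @param min_group_n factor levels with fewer usable records than this
#'   are dropped from testing (they cannot support a comparison).
#' @return Data frame: `factor`, `level`, `n`, `percent`, `test_T1`,
#'   `p_T1`, `test_T2`, `p_T2`.
#' @export
influence_report <- function(records, scheme = group_scheme(),
                             adjust = "none", min_group_n = 2L) {
  if (is.null(records$usable)) records <- compute_durations(records, scheme)
  usable <- records[records$usable, , drop = FALSE]
  if (nrow(usable) == 0L) stop_invalid("no usable records")
  f <- record_factors(usable, scheme)
  summary_tab <- group_summary(usable, scheme)
  tests <- lapply(names(f), function(nm) {
    lab <- droplevels(f[[nm]])
    keep_levels <- names(table(lab))[table(lab) >= min_group_n]
    keep <- lab %in% keep_levels
    run <- function(v) {
      if (length(keep_levels) < 2L) return(list(test = NA, p.value = NA))
      compare_groups(v[keep], droplevels(lab[keep]))
    }
    list(factor = nm, T1 = run(usable$T1), T2 = run(usable$T2))
  })
  p1 <- stats::p.adjust(vapply(tests, function(t) t$T1$p.value, numeric(1)),
                        method = adjust)
  p2 <- stats::p.adjust(vapply(tests, function(t) t$T2$p.value, numeric(1)),
                        method = adjust)
  for (i in seq_along(tests)) {
    rows <- summary_tab$factor == tests[[i]]$factor
    summary_tab$test_T1[rows] <- tests[[i]]$T1$test
    summary_tab$p_T1[rows] <- p1[i]
    summary_tab$test_T2[rows] <- tests[[i]]$T2$test
    summary_tab$p_T2[rows] <- p2[i]
  }
  summary_tab
}
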