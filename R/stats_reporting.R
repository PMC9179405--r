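# Descriptive and survival reporting: summary tables with the correct
# denominators, small-stratum suppression, the critical-bandwidth
# multimodality test with kernel mode location, and Kaplan-Meier /
# reverse Kaplan-Meier / log-rank analyses.

summary_block <- function(variable, values, denominator_name,
                          denominator = length(values),
                          levels = sort(unique(values))) {
  counts <- unname(vapply(levels, function(l) sum(values == l, na.rm = TRUE),
                          1L))
  tibble::tibble(
    variable = variable, class = as.character(levels), count = counts,
    percent = percent_of(counts, denominator),
    denominator_name = denominator_name, denominator = denominator)
}

#' Chemotherapy-setting denominator
#'
#' The regimen block of the summary table is displayed per chemotherapy
#' *setting*, so a patient treated in both the neoadjuvant and the
#' adjuvant setting contributes twice:
#' `n_neoadjuvant + n_adjuvant + 2 * n_both`.
#'
#' @param n_neoadjuvant,n_adjuvant,n_both patient counts per setting.
#' @return integer count of chemotherapy settings.
#' @export
#' @examples
#' ct_setting_denominator(15627, 72939, 1686)  # 91938
ct_setting_denominator <- function(n_neoadjuvant, n_adjuvant, n_both) {
  n_neoadjuvant + n_adjuvant + 2L * n_both
}

#' Summarise a cohort
#'
#' Emits every summary block with its correct denominator: whole cohort
#' for age classes, subtype (undefined included), nodal status and
#' treatment yes/no; the treated subset for each modality's settings and
#' regimens; the defined-subtype subset for subtype shares excluding
#' `undefined`; and the chemotherapy-*setting* denominator (both-setting
#' patients counted once per setting) for chemotherapy regimens.
#' Percentages are rounded half-up to one decimal.
#'
#' @param records cohort tibble from [build_cohort()] (`$cohort`).
#' @param treatments tidy course table from [build_cohort()]
#'   (`$treatments`).
#' @return a tibble of class `cohort_summary` with columns `variable`,
#'   `class`, `count`, `percent`, `denominator_name`, `denominator`.
#' @export
summarize_cohort <- function(records, treatments) {
  n <- nrow(records)
  if (n == 0) {
    out <- tibble::tibble(variable = character(), class = character(),
                          count = integer(), percent = double(),
                          denominator_name = character(),
                          denominator = integer())
    return(structure(out, class = c("cohort_summary", class(out))))
  }
  tr <- function(mod) treatments[treatments$modality == mod, ]
  received_of <- function(mod) {
    t <- tr(mod)
    t$patient_id[t$received]
  }
  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1]] <<- b

  add(summary_block("age_class", records$age_class, "cohort", n,
                    levels = AGE_CLASS_LABELS))
  add(summary_block("subtype", records$subtype, "cohort", n,
                    levels = SUBTYPES))
  defined <- records$subtype[records$subtype != "undefined"]
  add(summary_block("subtype_defined", defined, "defined_subtypes",
                    length(defined),
                    levels = setdiff(SUBTYPES, "undefined")))
  add(summary_block("nodal_status",
                    ifelse(records$node_positive, "node_positive",
                           "node_negative"), "cohort", n,
                    levels = c("node_negative", "node_positive")))
  add(summary_block("surgery_type", records$surgery_breast_type,
                    "cohort", n, levels = c("partial", "mastectomy")))
  add(summary_block("axillary_surgery",
                    ifelse(records$surgery_axillary, "yes", "no"),
                    "cohort", n, levels = c("no", "yes")))

  for (mod in c("RT", "CT", "ET", "TT")) {
    t <- tr(mod)
    add(summary_block(paste0(mod, "_received"),
                      ifelse(t$received, "yes", "no"), "cohort", n,
                      levels = c("no", "yes")))
    tt_ <- t[t$received, ]
    if (nrow(tt_) == 0) next
    add(summary_block(paste0(mod, "_setting"), tt_$setting,
                      paste0(mod, "_treated"), nrow(tt_)))
    if (mod == "CT") {
      n_settings <- ct_setting_denominator(
        sum(tt_$setting == "neoadjuvant"), sum(tt_$setting == "adjuvant"),
        sum(tt_$setting == "both"))
      counts <- unname(vapply(CT_REGIMENS, function(r) {
        sum((tt_$regimen == r) * ifelse(tt_$setting == "both", 2L, 1L))
      }, 1L))
      add(tibble::tibble(
        variable = "CT_regimen", class = CT_REGIMENS, count = counts,
        percent = percent_of(counts, n_settings),
        denominator_name = "CT_settings", denominator = n_settings))
    } else if (mod == "ET") {
      add(summary_block("ET_regimen", tt_$regimen, "ET_treated",
                        nrow(tt_), levels = ET_REGIMENS))
    } else if (mod == "TT") {
      add(summary_block("TT_regimen", tt_$regimen, "TT_treated",
                        nrow(tt_),
                        levels = c("trastuzumab",
                                   "pertuzumab+/-trastuzumab")))
      add(summary_block("TT_combination", tt_$combination, "TT_treated",
                        nrow(tt_), levels = TT_COMBINATIONS))
    }
  }
  add(summary_block("main_pathway", records$main_pathway, "cohort", n,
                    levels = PATHWAYS))
  out <- dplyr::bind_rows(blocks)
  structure(out, class = c("cohort_summary", class(out)))
}

#' Suppress small strata
#'
#' Removes strata containing fewer than `min_n` patients from a
#' stratified count table (an edge-effect guard for trend displays); the
#' removed strata are recorded in the `suppressed` attribute and a warning
#' is raised when nothing survives.
#'
#' @param data data frame of stratified counts.
#' @param n_col name of the count column (default `"n"`).
#' @param min_n suppression threshold (default 50).
#' @return the filtered data frame, with attribute `suppressed`.
#' @export
#' @examples
#' suppress_small_strata(data.frame(stratum = 1:3, n = c(49, 50, 200)))
suppress_small_strata <- function(data, n_col = "n", min_n = 50L) {
  keep <- data[[n_col]] >= min_n
  out <- data[keep, , drop = FALSE]
  attr(out, "suppressed") <- data[!keep, , drop = FALSE]
  if (nrow(out) == 0 && nrow(data) > 0) {
    warning("all strata fall below the suppression threshold (",
            min_n, ")")
  }
  out
}

# ---- critical-bandwidth multimodality test ----------------------------

count_kde_modes <- function(x, bw, n_grid = 512L) {
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = n_grid)
  y <- d$y
  sum(diff(sign(diff(y))) < 0)
}

# smallest Gaussian-kernel bandwidth whose KDE has at most k modes,
# located by bisection on a scale-equivariant bracket
critical_bandwidth <- function(x, k = 1L, tol_rel = 1e-4) {
  s <- stats::sd(x)
  hi <- s
  while (count_kde_modes(x, hi) > k) hi <- hi * 2
  lo <- hi / 2
  while (count_kde_modes(x, lo) <= k) {
    hi <- lo
    lo <- lo / 2
    if (lo < s * 1e-6) break  # effectively k modes at any bandwidth
  }
  while ((hi - lo) / hi > tol_rel) {
    mid <- (hi + lo) / 2
    if (count_kde_modes(x, mid) <= k) hi <- mid else lo <- mid
  }
  hi
}

#' Locate density modes
#'
#' Positions of the local maxima of the Gaussian KDE evaluated at the
#' largest bandwidth yielding `n_modes` modes (the critical bandwidth for
#' `n_modes`).
#'
#' @param values numeric sample.
#' @param n_modes requested number of modes.
#' @return sorted numeric vector of mode locations (length `n_modes`).
#' @export
locate_modes <- function(values, n_modes = 1L) {
  x <- values[is.finite(values)]
  if (stats::sd(x) == 0) return(x[1])
  h <- critical_bandwidth(x, n_modes)
  d <- stats::density(x, bw = h, kernel = "gaussian", n = 2048L)
  i <- which(diff(sign(diff(d$y))) < 0) + 1L
  if (length(i) > n_modes) {
    i <- i[order(d$y[i], decreasing = TRUE)[seq_len(n_modes)]]
  }
  sort(d$x[i])
}

#' Critical-bandwidth test of multimodality
#'
#' Silverman-type bootstrap test. The critical bandwidth `h*` is the
#' smallest Gaussian-kernel bandwidth whose KDE has at most `null_modes`
#' modes (found by bisection). The p-value is the fraction of smoothed
#' bootstrap resamples (drawn from the KDE at `h*`, variance-rescaled)
#' whose KDE at `h*` has more than `null_modes` modes. If the null is
#' rejected at 0.05, the mode count is taken as `alt_modes` (a parameter,
#' standing in for the graphical assessment of the mode count) and mode
#' locations are read off the KDE at the critical bandwidth for that
#' count. P-values are invariant under affine rescaling of the input.
#'
#' @param values numeric sample (n >= 20).
#' @param null_modes number of modes under the null (default 1:
#'   unimodality).
#' @param reps bootstrap replicates (default 500; fewer than 100 warns).
#' @param seed integer seed for the bootstrap.
#' @param alt_modes mode count reported upon rejection (default
#'   `null_modes + 1`).
#' @return object of class `modality_test`: `p_value`, `n_modes`,
#'   `mode_locations`, `bandwidth` (critical), `reps`, `seed`, `n`.
#' @export
#' @examples
#' x <- c(rnorm(200, 50, 5), rnorm(200, 65, 5))
#' mt <- modality_test(x, reps = 100, seed = 1)
#' glance(mt)
modality_test <- function(values, null_modes = 1L, reps = 500L,
                          seed = NULL, alt_modes = null_modes + 1L) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 20) abort_ctx("modality_test needs at least 20 values",
                        "input_error")
  if (reps < 100) warning("fewer than 100 bootstrap replicates")
  if (stats::sd(x) == 0) {
    # degenerate point mass: unimodal by convention
    out <- list(p_value = 1, n_modes = 1L, mode_locations = x[1],
                bandwidth = 0, reps = as.integer(reps), seed = seed, n = n)
    return(structure(out, class = "modality_test"))
  }
  h <- critical_bandwidth(x, null_modes)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(seed)
  }
  v <- stats::var(x)
  rescale <- 1 / sqrt(1 + h^2 / v)
  exceed <- vapply(seq_len(reps), function(r) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    z <- mean(xb) + (xb - mean(xb) + h * stats::rnorm(n)) * rescale
    count_kde_modes(z, h) > null_modes
  }, TRUE)
  p <- mean(exceed)
  if (p < 0.05) {
    k <- alt_modes
    modes <- locate_modes(x, k)
  } else {
    k <- null_modes
    modes <- locate_modes(x, null_modes)
  }
  structure(list(p_value = p, n_modes = as.integer(k),
                 mode_locations = modes, bandwidth = h,
                 reps = as.integer(reps), seed = seed, n = n),
            class = "modality_test")
}

#' @export
print.modality_test <- function(x, ...) {
  cat("Critical-bandwidth multimodality test\n")
  cat("  n = ", x$n, ", critical bandwidth = ",
      signif(x$bandwidth, 4), ", bootstrap reps = ", x$reps, "\n",
      sep = "")
  cat("  p-value = ", format.pval(x$p_value), "; modes (", x$n_modes,
      "): ", paste(signif(x$mode_locations, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.modality_test <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$mode_locations),
                 location = x$mode_locations)
}

#' @export
glance.modality_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, n_modes = x$n_modes,
                 bandwidth = x$bandwidth, reps = x$reps, n = x$n)
}

#' @export
autoplot.modality_test <- function(object, ...) {
  stopifnot(object$bandwidth > 0)
  df <- tibble::tibble(location = object$mode_locations)
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$location)) +
    ggplot2::geom_vline(data = df,
                        ggplot2::aes(xintercept = .data$location),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "value", y = "density",
                  title = sprintf("KDE modes (p = %.3g)", object$p_value))
}

# ---- survival ---------------------------------------------------------

#' Kaplan-Meier survival analysis of a cohort
#'
#' Overall survival runs from the index surgery to death or the
#' administrative cutoff, in months (30.4375 days). Estimates the overall
#' product-limit curve, the median follow-up and its IQR by reverse
#' Kaplan-Meier (censoring treated as the event), and log-rank tests per
#' grouping variable.
#'
#' @param records cohort tibble with `survival_time_months` and `event`.
#' @param groupings character vector of grouping columns for log-rank
#'   comparisons (defaults to age class, subtype, nodal status).
#' @return object of class `km_analysis`: `fit` (the `survfit` object),
#'   `curve` (tidy step-curve tibble), `median_followup_months`,
#'   `followup_iqr`, `logrank` (tibble: grouping, chisq, df, p_value),
#'   `n`, `n_events`.
#' @export
km_analysis <- function(records,
                        groupings = c("age_class", "subtype",
                                      "node_positive")) {
  stopifnot(all(c("survival_time_months", "event") %in% names(records)))
  time <- records$survival_time_months
  event <- as.integer(records$event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- tibble::tibble(time = fit$time, estimate = fit$surv,
                          n_risk = fit$n.risk, n_event = fit$n.event,
                          n_censor = fit$n.censor)
  # reverse KM: censoring is the event
  rfit <- survival::survfit(survival::Surv(time, 1L - event) ~ 1)
  rq <- stats::quantile(rfit, probs = c(0.25, 0.5, 0.75))$quantile
  logrank <- NULL
  if (sum(event) == 0) {
    logrank <- tibble::tibble(grouping = groupings, chisq = NA_real_,
                              df = NA_integer_, p_value = NA_real_,
                              note = "no events: log-rank not applicable")
  } else {
    rows <- lapply(groupings, function(g) {
      grp <- records[[g]]
      if (length(unique(grp)) < 2) {
        return(tibble::tibble(grouping = g, chisq = NA_real_,
                              df = NA_integer_, p_value = NA_real_,
                              note = "single group"))
      }
      sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
      df <- length(sd$n) - 1L
      tibble::tibble(grouping = g, chisq = sd$chisq, df = df,
                     p_value = stats::pchisq(sd$chisq, df,
                                             lower.tail = FALSE),
                     note = NA_character_)
    })
    logrank <- dplyr::bind_rows(rows)
  }
  structure(list(fit = fit, curve = curve,
                 median_followup_months = unname(rq[2]),
                 followup_iqr = unname(rq[c(1, 3)]),
                 logrank = logrank, n = length(time),
                 n_events = sum(event)),
            class = "km_analysis")
}

#' @export
print.km_analysis <- function(x, ...) {
  cat("Kaplan-Meier analysis: ", x$n, " patients, ", x$n_events,
      " deaths\n", sep = "")
  cat("  median follow-up (reverse KM): ",
      round(x$median_followup_months, 1), " months (IQR ",
      round(x$followup_iqr[1], 1), "; ", round(x$followup_iqr[2], 1),
      ")\n", sep = "")
  if (!is.null(x$logrank)) {
    for (i in seq_len(nrow(x$logrank))) {
      cat("  log-rank [", x$logrank$grouping[i], "]: p = ",
          format.pval(x$logrank$p_value[i]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
tidy.km_analysis <- function(x, ...) x$curve

#' @export
glance.km_analysis <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 median_followup_months = x$median_followup_months,
                 followup_iqr_low = x$followup_iqr[1],
                 followup_iqr_high = x$followup_iqr[2])
}

#' @export
autoplot.km_analysis <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, estimate = 1),
    object$curve[, c("time", "estimate")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since index surgery",
                  y = "overall survival")
}

#' Plot filter attrition
#'
#' @param attrition the filter report tibble from [apply_filters()].
#' @return a ggplot bar chart of exclusions per filter.
#' @export
plot_attrition <- function(attrition) {
  attrition$filter_name <- factor(attrition$filter_name,
                                  levels = rev(attrition$filter_name))
  ggplot2::ggplot(attrition,
                  ggplot2::aes(x = .data$n_excluded,
                               y = .data$filter_name)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "patients excluded", y = NULL)
}
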