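#' Longitudinal tumor-burden and survival analysis
#'
#' The efficacy layer for 4-arm therapy experiments: whole-body radiance
#' (bioluminescence) summarised per arm and week with a minimum-survivor
#' masking rule, per-mouse fold change relative to the treatment week,
#' cross-sectional one-way ANOVA with Bonferroni-adjusted pairwise contrasts,
#' and Kaplan-Meier / log-rank (Mantel-Cox) survival analysis built on the
#' `survival` package.
#'
#' BLI data are long data.frames with columns `mouse_id, arm, week, radiance`;
#' survival records have `mouse_id, arm, time, event` (1 = death/euthanasia,
#' 0 = censored), times in weeks.
#'
#' @name efficacy
NULL

validate_bli <- function(bli) {
  needed <- c("mouse_id", "arm", "week", "radiance")
  if (!all(needed %in% names(bli))) {
    stop("BLI table missing columns: ", paste(setdiff(needed, names(bli)), collapse = ", "))
  }
  if (any(bli$radiance <= 0)) stop("radiance must be > 0")
  invisible(bli)
}

validate_survival <- function(records) {
  needed <- c("mouse_id", "arm", "time", "event")
  if (!all(needed %in% names(records))) {
    stop("survival table missing columns: ",
         paste(setdiff(needed, names(records)), collapse = ", "))
  }
  if (any(records$time <= 0)) stop("survival times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(records)
}

#' Per-mouse fold change in radiance
#'
#' Radiance divided by the same mouse's radiance at the baseline (treatment)
#' week; the baseline week is exactly 1. A mouse without a baseline
#' measurement is an error.
#'
#' @param bli long BLI data.frame (`mouse_id, arm, week, radiance`).
#' @param baseline_week week index of treatment.
#' @return `bli` with a `fold_change` column.
#' @export
fold_change <- function(bli, baseline_week) {
  validate_bli(bli)
  out <- do.call(rbind, lapply(split(bli, bli$mouse_id), function(m) {
    base <- m$radiance[m$week == baseline_week]
    if (length(base) != 1) {
      stop("mouse ", m$mouse_id[1], ": missing (or duplicated) baseline measurement at week ",
           baseline_week)
    }
    m$fold_change <- m$radiance / base
    m
  }))
  rownames(out) <- NULL
  out
}

#' Arm-level radiance summary with survivor masking
#'
#' Mean +/- SD of the chosen value per arm and week, on the linear scale.
#' Weeks where an arm has fewer than `min_alive` contributing mice are masked
#' (`NA` mean/SD, `masked = TRUE`) rather than reported from a shrinking
#' group -- the "time points with 5 or more remaining mice" plotting rule.
#'
#' @param bli long BLI data.frame; pass the output of [fold_change()] and
#'   `value = "fold_change"` to summarise fold changes.
#' @param min_alive minimum contributing mice per cell (>= 1).
#' @param value column to summarise (`"radiance"` or `"fold_change"`).
#' @return data.frame `arm, week, n, mean, sd, masked`.
#' @export
group_radiance_summary <- function(bli, min_alive = 5, value = "radiance") {
  validate_bli(bli)
  stopifnot(min_alive >= 1, value %in% names(bli))
  cells <- split(bli, list(bli$arm, bli$week), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(cell) {
    v <- cell[[value]]
    masked <- length(v) < min_alive
    data.frame(arm = cell$arm[1], week = cell$week[1], n = length(v),
               mean = if (masked) NA_real_ else mean(v),
               sd = if (masked) NA_real_ else if (length(v) > 1) sd(v) else 0,
               masked = masked, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$arm, out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Bonferroni-adjusted pairwise contrasts
#'
#' Cross-sectional comparison of arms at a fixed week: overall one-way ANOVA
#' F test, then pairwise contrasts using the pooled within-group mean square
#' (t on the error df), each raw p multiplied by the number of contrasts and
#' clipped at 1. Fully degenerate input (zero variance everywhere, equal
#' means) returns p = 1 by convention.
#'
#' @param values_by_arm named list of numeric vectors (>= 2 arms, >= 2 values
#'   each).
#' @param contrasts list of length-2 character vectors naming arm pairs;
#'   default all pairs.
#' @return list with `f_statistic`, `df`, `p_overall` and a data.frame
#'   `contrasts` (`arm1, arm2, statistic, p_raw, p_adjusted`).
#' @export
anova_bonferroni <- function(values_by_arm, contrasts = NULL) {
  stopifnot(length(values_by_arm) >= 2,
            all(vapply(values_by_arm, length, integer(1)) >= 2))
  arms <- names(values_by_arm)
  if (is.null(arms) || any(!nzchar(arms))) stop("values_by_arm must be named by arm")
  ns <- vapply(values_by_arm, length, integer(1))
  means <- vapply(values_by_arm, mean, numeric(1))
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(values_by_arm, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(arms) - 1
  df2 <- sum(ns) - length(arms)
  degenerate <- ssw == 0
  if (degenerate && ssb == 0) {
    f <- 0; p_overall <- 1
  } else if (degenerate) {
    f <- Inf; p_overall <- 0
  } else {
    mse <- ssw / df2
    f <- (ssb / df1) / mse
    p_overall <- pf(f, df1, df2, lower.tail = FALSE)
  }
  if (is.null(contrasts)) {
    idx <- utils::combn(arms, 2, simplify = FALSE)
    contrasts <- idx
  }
  m <- length(contrasts)
  rows <- lapply(contrasts, function(cc) {
    stopifnot(length(cc) == 2, all(cc %in% arms))
    d <- means[cc[1]] - means[cc[2]]
    if (degenerate) {
      tstat <- if (d == 0) 0 else Inf * sign(d)
      p_raw <- if (d == 0) 1 else 0
    } else {
      se <- sqrt((ssw / df2) * (1 / ns[cc[1]] + 1 / ns[cc[2]]))
      tstat <- d / se
      p_raw <- 2 * pt(-abs(tstat), df2)
    }
    data.frame(arm1 = cc[1], arm2 = cc[2], statistic = tstat,
               p_raw = p_raw, p_adjusted = min(1, m * p_raw),
               stringsAsFactors = FALSE)
  })
  list(f_statistic = f, df = c(df1, df2), p_overall = p_overall,
       method = "anova_bonferroni",
       contrasts = do.call(rbind, rows))
}

#' Kaplan-Meier estimate and median survival per arm
#'
#' Product-limit survival curves (via `survival::survfit`) and the median
#' survival per arm, defined as the earliest time at which the estimated
#' survival drops to 0.5 or below; arms whose curve never reaches 0.5 report
#' `NA` (median not reached).
#'
#' @param records survival data.frame (`mouse_id, arm, time, event`).
#' @return list with the `survfit` object (`fit`), a `medians` data.frame
#'   (`arm, n, events, median`), and the input.
#' @export
km_estimate <- function(records) {
  validate_survival(records)
  if (sum(records$event) < 1) stop("need at least one event")
  records$arm <- as.character(records$arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = records)
  arms <- sort(unique(records$arm))
  med_one <- function(arm) {
    r <- records[records$arm == arm, ]
    f <- survival::survfit(survival::Surv(time, event) ~ 1, data = r)
    s <- summary(f, censored = TRUE)
    hit <- which(s$surv <= 0.5)
    data.frame(arm = arm, n = nrow(r), events = sum(r$event),
               median = if (length(hit)) s$time[min(hit)] else NA_real_,
               stringsAsFactors = FALSE)
  }
  medians <- do.call(rbind, lapply(arms, med_one))
  rownames(medians) <- NULL
  list(fit = fit, medians = medians, records = records)
}

#' Log-rank (Mantel-Cox) test between two arms
#'
#' Chi-square statistic with 1 df and two-sided p-value via
#' `survival::survdiff`, with the standard tie handling (all deaths at a time
#' processed together).
#'
#' @param records survival data.frame.
#' @param contrast length-2 character vector of arm labels.
#' @return list `contrast, statistic, df, p, method`.
#' @export
logrank <- function(records, contrast) {
  validate_survival(records)
  stopifnot(length(contrast) == 2)
  sub <- records[records$arm %in% contrast, ]
  counts <- table(factor(sub$arm, levels = contrast))
  if (any(counts == 0)) {
    stop("empty arm in contrast: ", paste(contrast[counts == 0], collapse = ", "))
  }
  if (sum(sub$event) == 0 || length(unique(sub$time[sub$event == 1])) == 0) {
    return(list(contrast = contrast, statistic = 0, df = 1, p = 1,
                method = "logrank"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm, data = sub)
  chisq <- unname(sd_$chisq)
  list(contrast = contrast, statistic = chisq, df = 1,
       p = pchisq(chisq, df = 1, lower.tail = FALSE), method = "logrank")
}
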