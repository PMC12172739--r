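#' Cochlear symmetry deviation of an aligned landmark set
#'
#' Skull-base alignment metric: the absolute anterior-posterior (y) and
#' craniocaudal (z) differences between the two cochlear points, in mm.
#' Perfect alignment is a deviation of 0 on both axes.
#'
#' @param landmarks a [landmark_set] (typically after alignment).
#' @param subject_id optional identifier carried into reports.
#' @return A list with `y_dev_mm`, `z_dev_mm` and `subject_id`.
#' @export
cochlear_deviation <- function(landmarks, subject_id = NA_character_) {
  list(
    y_dev_mm = abs(landmarks$left_cochlea[2] - landmarks$right_cochlea[2]),
    z_dev_mm = abs(landmarks$left_cochlea[3] - landmarks$right_cochlea[3]),
    subject_id = subject_id
  )
}

#' Residual per-plane angular deviation from ground truth
#'
#' Whole-head alignment metric on phantoms: composes the recovered
#' alignment rotation with the known applied misalignment and decomposes
#' the residual into axial (yaw), sagittal (pitch) and coronal (roll)
#' angles under the same z -> x -> y convention as the alignment itself.
#' A perfect recovery (recovered = inverse of applied) gives (0, 0, 0).
#'
#' Signs follow the reporting convention that clockwise misalignment, as
#' seen in standard radiological display of each plane, is positive; this
#' is the sign of the rotation angle in the package's right-handed LPS
#' axis convention.
#'
#' @param applied the applied misalignment: a [misalignment_spec], a
#'   [rigid_transform], or a 3x3 rotation matrix.
#' @param recovered the recovered alignment: a [rigid_transform] or 3x3
#'   rotation matrix. Defaults to the identity (i.e. report the applied
#'   misalignment itself).
#' @param rounded round to whole signed degrees (half away from zero)?
#'   Default `FALSE`.
#' @return Named numeric: `axial_deg`, `sagittal_deg`, `coronal_deg`.
#' @export
plane_deviation_from_truth <- function(applied, recovered = NULL,
                                       rounded = FALSE) {
  as_rot <- function(x) {
    if (inherits(x, "misalignment_spec"))
      euler_to_matrix(x$yaw_deg, x$pitch_deg, x$roll_deg)
    else if (inherits(x, "rigid_transform")) x$rotation
    else matrix(as.numeric(x), 3, 3)
  }
  A <- as_rot(applied)
  Rr <- if (is.null(recovered)) diag(3) else as_rot(recovered)
  resid <- Rr %*% A
  e <- matrix_to_euler(resid)
  out <- c(axial_deg = unname(e["yaw_deg"]),
           sagittal_deg = unname(e["pitch_deg"]),
           coronal_deg = unname(e["roll_deg"]))
  if (rounded) out <- round_half_away(out)
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Signed whole-degree misalignment value
#'
#' Reporting convention for manual whole-head alignment measurements: a
#' clockwise angulation of magnitude `angle_deg` is reported as a positive
#' whole number of degrees, counter-clockwise as negative; rounding is
#' half away from zero. E.g. 4.64 clockwise -> +5; 25.3 clockwise -> +25;
#' 5.26 counter-clockwise -> -5.
#'
#' @param angle_deg non-negative angulation magnitude in degrees.
#' @param direction `"clockwise"` or `"counter-clockwise"`.
#' @return Signed integer degrees.
#' @export
signed_rounded_degrees <- function(angle_deg,
                                   direction = c("clockwise", "counter-clockwise")) {
  direction <- match.arg(direction)
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0))
    stop("`angle_deg` must be a non-negative magnitude", call. = FALSE)
  s <- if (direction == "clockwise") 1 else -1
  as.integer(s * floor(angle_deg + 0.5))
}

#' Paired Wilcoxon signed-rank test on absolute deviations
#'
#' Two-sided signed-rank test comparing |before| with |after| as paired
#' samples. Absolute values are used because signed clockwise/
#' counter-clockwise deviations tend to cancel and understate
#' misalignment. Zero differences are dropped (the standard Wilcoxon
#' convention). With at most 14 informative pairs the exact two-sided
#' p-value is computed by full enumeration of the 2^n sign assignments
#' (correct under ties as well); larger samples use the signed-rank test
#' from the stats package.
#'
#' @param before,after equal-length numeric vectors of paired deviations
#'   (n >= 5).
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_effective` (pairs after dropping zero differences) and `exact`.
#' @export
paired_wilcoxon_abs <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must be paired (equal length)", call. = FALSE)
  if (length(before) < 5)
    stop("need at least 5 pairs", call. = FALSE)
  d <- abs(before) - abs(after)
  d <- d[d != 0]
  if (!length(d))
    stop("degenerate test: all paired absolute deviations are identical",
         call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 14L) {
    # exact null: every sign assignment equally likely
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
    exact <- TRUE
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(abs(before), abs(after), paired = TRUE,
                         alternative = "two.sided")
    )
    p <- res$p.value
    exact <- FALSE
  }
  list(statistic = w_obs, p_value = p, n_effective = n, exact = exact)
}

#' Shapiro-Wilk normality gate
#'
#' Tests the sample for normality at level `alpha`; a non-normal result
#' steers downstream analysis to the nonparametric signed-rank test.
#'
#' @param x numeric sample, n >= 3 and not all identical.
#' @param alpha significance level (default 0.05).
#' @return A list with `normal` (logical), `p_value` and `alpha`.
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3)
    stop("Shapiro-Wilk test needs at least 3 observations", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate sample: all values identical; normality is undefined",
         call. = FALSE)
  res <- stats::shapiro.test(x)
  list(normal = res$p.value >= alpha, p_value = res$p.value, alpha = alpha)
}

#' ICC(1,k): one-way random effects, average-measures, absolute agreement
#'
#' Interrater reliability of the average of k raters under the one-way
#' random-effects model. From the one-way ANOVA across subjects,
#' `ICC(1,k) = (MS_between - MS_within) / MS_between`; the confidence
#' interval follows the standard F construction with
#' `F = MS_between / MS_within` on (n-1, n(k-1)) degrees of freedom:
#' lower = 1 - 1/(F / qf(1-a/2, n-1, n(k-1))), upper analogous.
#'
#' @param ratings numeric matrix, subjects in rows (n >= 2), raters in
#'   columns (k >= 2), no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return A list with `icc`, `ci` (length-2), `ms_between`, `ms_within`,
#'   `n`, `k`.
#' @export
icc_1k <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings)))
    stop("`ratings` must have no missing cells", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("`ratings` needs at least 2 subjects and 2 raters", call. = FALSE)
  df <- data.frame(value = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)))
  ms <- summary(stats::aov(value ~ subject, data = df))[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  if (msb <= 1e-12 * (msb + msw))
    stop("undefined ICC: between-subject mean square is zero", call. = FALSE)
  icc <- (msb - msw) / msb
  alpha <- 1 - conf_level
  f <- msb / msw
  df1 <- n - 1; df2 <- n * (k - 1)
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  list(icc = icc, ci = c(1 - 1 / fl, 1 - 1 / fu),
       ms_between = msb, ms_within = msw, n = n, k = k)
}

#' Cohort summary of paired alignment deviations
#'
#' Builds a summary in the layout used to report alignment cohorts: for
#' each metric and condition the mean, median, sample SD and range of the
#' *absolute* deviations, plus the paired Wilcoxon signed-rank p-value
#' between the two conditions.
#'
#' @param deviations a data.frame with columns `subject_id`, `condition`,
#'   `metric` and `value`. Exactly two conditions; every (subject, metric)
#'   pair must appear in both.
#' @return A list with `table` (one row per metric x condition:
#'   mean/median/sd/min/max of |value| and n) and `tests` (one row per
#'   metric with the paired Wilcoxon p-value).
#' @export
summarize_deviations <- function(deviations) {
  req <- c("subject_id", "condition", "metric", "value")
  if (!all(req %in% names(deviations)))
    stop("`deviations` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  conds <- sort(unique(as.character(deviations$condition)))
  if (length(conds) != 2)
    stop("expected exactly two conditions, got ", length(conds), call. = FALSE)
  if (length(unique(deviations$subject_id)) < 2)
    stop("need at least 2 subjects", call. = FALSE)

  rows <- list(); tests <- list()
  for (m in unique(as.character(deviations$metric))) {
    sub <- deviations[deviations$metric == m, ]
    wide <- merge(
      sub[sub$condition == conds[1], c("subject_id", "value")],
      sub[sub$condition == conds[2], c("subject_id", "value")],
      by = "subject_id", suffixes = c("_1", "_2")
    )
    n1 <- sum(sub$condition == conds[1]); n2 <- sum(sub$condition == conds[2])
    if (nrow(wide) != n1 || nrow(wide) != n2) {
      missing_ids <- setdiff(unique(sub$subject_id), wide$subject_id)
      stop("unpaired subjects for metric '", m, "': ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    for (cond in conds) {
      v <- abs(sub$value[sub$condition == cond])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, condition = cond, n = length(v),
        mean = mean(v), median = stats::median(v),
        sd = stats::sd(v), min = min(v), max = max(v),
        stringsAsFactors = FALSE
      )
    }
    p <- tryCatch(paired_wilcoxon_abs(wide$value_1, wide$value_2)$p_value,
                  error = function(e) NA_real_)
    tests[[length(tests) + 1L]] <- data.frame(
      metric = m, condition_1 = conds[1], condition_2 = conds[2],
      p_wilcoxon = p, stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, rows), tests = do.call(rbind, tests))
}

#' Render a deviation summary as text
#'
#' @param summary result of [summarize_deviations()].
#' @return A character vector of report lines, invisibly printed with
#'   `cat` when called interactively via `print`.
#' @export
format_summary <- function(summary) {
  tab <- summary$table
  lines <- character(0)
  for (m in unique(tab$metric)) {
    lines <- c(lines, sprintf("== %s ==", m))
    sub <- tab[tab$metric == m, ]
    for (i in seq_len(nrow(sub)))
      lines <- c(lines, sprintf(
        "  %-12s n=%3d  mean=%.3f  median=%.3f  sd=%.3f  range=%.3f-%.3f",
        sub$condition[i], sub$n[i], sub$mean[i], sub$median[i],
        sub$sd[i], sub$min[i], sub$max[i]))
    p <- summary$tests$p_wilcoxon[summary$tests$metric == m]
    lines <- c(lines, sprintf("  paired Wilcoxon p = %s",
                              ifelse(is.na(p), "NA", format.pval(p, digits = 3))))
  }
  lines
}
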