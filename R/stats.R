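#' Unpaired Student's t-test between two groups
#'
#' Classical pooled-variance two-sample t-test (`df = n_a + n_b - 2`),
#' two-sided. Welch's unequal-variance form is available behind a flag.
#'
#' @param sample_a,sample_b Numeric vectors with at least two values each.
#' @param metric Optional name of the compared quantity.
#' @param group_a,group_b Group labels.
#' @param welch Use Welch's t instead of the pooled-variance form.
#' @return A `group_comparison` tibble with one row: labels, per-group
#'   mean/SD/n, `t_statistic`, `df` and `p_value`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))$p_value
#' @export
unpaired_t_test <- function(sample_a, sample_b, metric = NA_character_,
                            group_a = "A", group_b = "B", welch = FALSE) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort_zfecg("Each sample needs at least two non-missing values.", "zfecg_insufficient")
  }
  if (stats::var(sample_a) + stats::var(sample_b) == 0) {
    abort_zfecg("Degenerate samples: pooled variance is zero.", "zfecg_degenerate")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  out <- tibble::tibble(
    metric = metric,
    group_a = group_a, group_b = group_b,
    mean_a = mean(sample_a), mean_b = mean(sample_b),
    sd_a = stats::sd(sample_a), sd_b = stats::sd(sample_b),
    n_a = length(sample_a), n_b = length(sample_b),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
tidy.group_comparison <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, t_statistic = x$t_statistic,
                 df = x$df, p_value = x$p_value)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Per sample, `dCt = ct_target - ct_reference`; the condition contrast is
#' `ddCt = mean dCt(treatment) - mean dCt(control)`, the fold change is
#' `2^(-ddCt)` and, when expression falls, the percent reduction is
#' `100 * (1 - fold)`.
#'
#' @param samples A tibble with columns `ct_target`, `ct_reference`
#'   (positive, finite cycle thresholds) and `condition` (`"control"` or
#'   `"treatment"`), at least one sample per condition.
#' @return A one-row tibble: `delta_delta_ct`, `fold`,
#'   `percent_reduction` (0 when expression does not fall).
#' @examples
#' s <- tibble::tibble(ct_target = c(20, 21), ct_reference = c(15, 15),
#'                     condition = c("control", "treatment"))
#' relative_expression(s)$fold
#' @export
relative_expression <- function(samples) {
  need <- c("ct_target", "ct_reference", "condition")
  if (!all(need %in% names(samples))) {
    abort_zfecg("`samples` needs columns ct_target, ct_reference, condition.", "zfecg_input")
  }
  ct <- c(samples$ct_target, samples$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    abort_zfecg("Ct values must be positive and finite.", "zfecg_domain")
  }
  conds <- c("control", "treatment")
  if (!all(conds %in% samples$condition)) {
    abort_zfecg("Both control and treatment samples are required.", "zfecg_input")
  }
  dct <- samples$ct_target - samples$ct_reference
  ddct <- mean(dct[samples$condition == "treatment"]) -
    mean(dct[samples$condition == "control"])
  fold <- 2^(-ddct)
  tibble::tibble(
    delta_delta_ct = ddct,
    fold = fold,
    percent_reduction = if (fold < 1) 100 * (1 - fold) else 0
  )
}

#' Baseline-normalized fluorescence change
#'
#' `(f - f0) / f0`, the standard normalization for indicator-dye
#' time series.
#'
#' @param f Fluorescence series.
#' @param f0 Positive baseline fluorescence (scalar).
#' @return Numeric series of the same length as `f`.
#' @examples
#' delta_f_over_f(c(10, 20), 10)
#' @export
delta_f_over_f <- function(f, f0) {
  if (length(f0) != 1 || !is.finite(f0) || f0 <= 0) {
    abort_zfecg("`f0` must be a single positive number.", "zfecg_domain")
  }
  (f - f0) / f0
}

#' Ventricular-to-atrial surface area ratio
#'
#' @param vsa Ventricular surface area (positive).
#' @param asa Atrial surface area (positive), same units.
#' @return `vsa / asa` (unitless), vectorized.
#' @examples
#' chamber_area_ratio(1.865, 1)
#' @export
chamber_area_ratio <- function(vsa, asa) {
  if (any(vsa <= 0) || any(asa <= 0)) {
    abort_zfecg("Surface areas must be positive.", "zfecg_domain")
  }
  vsa / asa
}
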