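#' Average absolute relative deviation (AARD, %)
#'
#' `AARD = 100 / NDP * sum(|calc - exp| / exp)`, the headline error metric
#' for diffusivity models: a relative deviation, so models are compared
#' fairly across the decades spanned by liquid-phase D12 values.
#'
#' @param calc Calculated values.
#' @param exp Experimental (reference) values; must be nonzero.
#' @return AARD in percent.
#' @export
#' @examples
#' aard(c(1, 2), c(2, 2)) # 25
aard <- function(calc, exp) {
  if (length(calc) != length(exp) || length(exp) < 1L) {
    .stop_domain("'calc' and 'exp' must be equal-length, non-empty")
  }
  if (any(exp == 0)) .stop_domain("'exp' must not contain zeros")
  100 * mean(abs((calc - exp) / exp))
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((calc - exp)^2))`, in the units of the inputs
#' (cm2 s-1 for diffusivities).
#'
#' @inheritParams aard
#' @return RMSE.
#' @export
rmse <- function(calc, exp) {
  if (length(calc) != length(exp) || length(exp) < 1L) {
    .stop_domain("'calc' and 'exp' must be equal-length, non-empty")
  }
  sqrt(mean((calc - exp)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the evaluated observations. Used as R2 on training data and as Q2
#' (external validation) on test data. The best possible score is 1; a
#' constant model predicting the mean of the response scores 0; arbitrarily
#' worse models score negative.
#'
#' @param pred Predicted values.
#' @param obs Observed values (at least 2, with nonzero variance).
#' @return Coefficient of determination (dimensionless).
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2L) {
    .stop_domain("'pred' and 'obs' must be equal-length with >= 2 values")
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) .stop_domain("zero variance in 'obs'")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Per-system evaluation report
#'
#' Aggregates predictions against observations in the layout used to report
#' diffusivity models: AARD per system, the point-pooled ("global", i.e.
#' NDP-weighted) AARD over all points, the unweighted arithmetic mean of the
#' per-system AARDs, the minimum and maximum system AARD, pooled RMSE and the
#' coefficient of determination of the evaluated set.
#'
#' @param calc Predicted D12, cm2 s-1.
#' @param exp Observed D12, cm2 s-1.
#' @param system Character vector of system keys (see [system_key()]), one
#'   per point.
#' @return Object of class `eval_report`: `per_system` (data.frame with
#'   system, `ndp`, `aard`), `n_sys`, `ndp_total`, `global_aard`,
#'   `aard_arith`, `aard_min`, `aard_max`, `rmse`, `r2`.
#' @export
#' @examples
#' evaluate(c(1.1, 2, 2, 2), c(1, 2, 2, 2), c("a/b", "a/c", "a/c", "a/c"))
evaluate <- function(calc, exp, system) {
  if (length(calc) != length(exp) || length(calc) != length(system)) {
    .stop_domain("'calc', 'exp' and 'system' must have equal lengths")
  }
  if (any(is.na(calc)) || any(is.na(exp)) || any(is.na(system))) {
    .stop_domain("unmatched records: NA in predictions, observations or keys")
  }
  keys <- unique(system)
  per <- do.call(rbind, lapply(keys, function(k) {
    i <- system == k
    data.frame(system = k, ndp = sum(i),
               aard = aard(calc[i], exp[i]), stringsAsFactors = FALSE)
  }))
  structure(list(
    per_system = per,
    n_sys = length(keys),
    ndp_total = length(exp),
    global_aard = aard(calc, exp),
    aard_arith = mean(per$aard),
    aard_min = min(per$aard),
    aard_max = max(per$aard),
    rmse = rmse(calc, exp),
    r2 = if (length(exp) >= 2L && stats::var(exp) > 0) r_squared(calc, exp) else NA_real_
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("D12 evaluation report\n")
  cat(sprintf("  NSys %d | NDP %d | Global AARD %.2f%% | AARD_arith %.2f%% | min %.2f%% | max %.2f%%\n",
              x$n_sys, x$ndp_total, x$global_aard, x$aard_arith,
              x$aard_min, x$aard_max))
  cat(sprintf("  RMSE %.3e cm2 s-1 | R2 %.4f\n", x$rmse, x$r2))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Renders the summary row (NSys, NDP, Global AARD, AARD_arith, AARD_min,
#' AARD_max, RMSE, R2) followed by the per-system table to a CSV file.
#'
#' @param report An [evaluate()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("section,system,ndp,aard_pct,global_aard_pct,aard_arith_pct,aard_min_pct,aard_max_pct,rmse_cm2_s,r2", con)
  writeLines(sprintf("summary,all,%d,,%0.6g,%0.6g,%0.6g,%0.6g,%0.6g,%0.6g",
                     report$ndp_total, report$global_aard, report$aard_arith,
                     report$aard_min, report$aard_max, report$rmse, report$r2),
             con)
  for (i in seq_len(nrow(report$per_system))) {
    writeLines(sprintf("system,%s,%d,%0.6g,,,,,,",
                       report$per_system$system[i], report$per_system$ndp[i],
                       report$per_system$aard[i]), con)
  }
  invisible(path)
}
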