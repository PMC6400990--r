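#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  labels <- c(wald = "Wald ratio", ivw = "Inverse-variance weighted",
              egger = "MR-Egger", wmedian = "Weighted median",
              pwmedian = "Penalized weighted median",
              mvmr = "Multivariable MR")
  cat(sprintf("Two-sample MR: %s (%d instrument%s)\n",
              labels[[x$method]], x$k, if (x$k == 1) "" else "s"))
  if (length(x$theta) == 1) {
    cat(sprintf("  theta = %s (SE %s), 95%% CI [%s, %s], p = %s\n",
                signif(x$theta, digits), signif(x$se, digits),
                signif(x$ci_low, digits), signif(x$ci_high, digits),
                format(x$p, digits = 3)))
  } else {
    tab <- data.frame(theta = x$theta, se = x$se, ci_low = x$ci_low,
                      ci_high = x$ci_high, p = x$p)
    print(signif(tab, digits))
  }
  if (!is.null(x$or))
    cat(sprintf("  OR per exposure SD = %.2f [%.2f, %.2f]\n",
                x$or, x$or_ci_low, x$or_ci_high))
  if (!is.null(x$q) && !is.na(x$q))
    cat(sprintf("  Cochran's Q = %s on %d df, p = %s\n",
                signif(x$q, digits), x$q_df, format(x$q_p, digits = 3)))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %s (SE %s), p = %s\n",
                signif(x$egger_intercept, digits),
                signif(x$egger_intercept_se, digits),
                format(x$egger_intercept_p, digits = 3)))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (object$method == "egger")
    c(intercept = object$egger_intercept, slope = object$theta)
  else object$theta
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  crit <- if (is.finite(object$df)) stats::qt((1 + level) / 2, object$df)
          else stats::qnorm((1 + level) / 2)
  cbind(lower = object$theta - crit * object$se,
        upper = object$theta + crit * object$se)
}

#' Scatter plot of instrument effects with the fitted causal slope
#'
#' Plots per-instrument outcome effects against exposure effects with
#' +/- 1 SE error bars and the fitted line (through the origin for
#' IVW-type fits, with intercept for MR-Egger).
#'
#' @param x an `mr_fit`.
#' @param instruments the [mr_instruments] the model was fitted to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, instruments, ...) {
  ins <- if (x$method == "egger") orient_instruments(instruments)
         else instruments
  graphics::plot(ins$gamma_x, ins$Gamma_y,
                 xlab = "SNP effect on exposure (SD/allele)",
                 ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(ins$gamma_x, ins$Gamma_y - ins$se_y,
                     ins$gamma_x, ins$Gamma_y + ins$se_y)
  graphics::segments(ins$gamma_x - ins$se_x, ins$Gamma_y,
                     ins$gamma_x + ins$se_x, ins$Gamma_y)
  intercept <- x$egger_intercept %||% 0
  graphics::abline(intercept, x$theta[1], col = "darkorange", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
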