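# Base-graphics diagnostic plots for the bias analyses.

#' Diagnostic plots for codon-usage bias
#'
#' `plot_neutrality()` draws the GC12-on-GC3 scatter with the OLS fit and the
#' diagonal; `plot_enc_curve()` draws observed ENC against GC3 with the
#' expected-ENC standard curve; `plot_pr2()` draws the PR2 square with the
#' parity center lines; `plot_pi_profile()` draws the sliding-window
#' diversity track.
#'
#' @param profiles Profile data frame from [codon_profiles()].
#' @param ... Passed to the underlying base-graphics call.
#' @return Invisibly, `NULL`; called for the side effect.
#' @export
plot_neutrality <- function(profiles, ...) {
  fit <- neutrality_analysis(profiles)
  plot(profiles$gc3, profiles$gc12, xlab = "GC3 (%)", ylab = "GC12 (%)",
       pch = 19, col = "grey30", ...)
  graphics::abline(fit$intercept, fit$slope, col = "firebrick", lwd = 2)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  graphics::mtext(sprintf("slope = %.4f, r = %.3f, p = %.4f",
                          fit$slope, fit$r, fit$p_value), side = 3, cex = 0.8)
  invisible(NULL)
}

#' @rdname plot_neutrality
#' @export
plot_enc_curve <- function(profiles, ...) {
  plot(profiles$gc3, profiles$enc, xlab = "GC3 (%)", ylab = "ENC",
       pch = 19, col = "grey30", xlim = c(0, 100), ylim = c(20, 61), ...)
  x <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(100 * x, expected_enc(x), col = "firebrick", lwd = 2)
  invisible(NULL)
}

#' @rdname plot_neutrality
#' @export
plot_pr2 <- function(profiles, ...) {
  plot(profiles$pr2_x, profiles$pr2_y, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)", pch = 19, col = "grey30", ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey60")
  invisible(NULL)
}

#' @rdname plot_neutrality
#' @param profile A `diversity_profile` from [sliding_window_pi()].
#' @export
plot_pi_profile <- function(profile, ...) {
  w <- profile$windows
  plot(w$midpoint, w$pi, type = "l", xlab = "alignment position (bp)",
       ylab = expression(pi), col = "grey20", ...)
  invisible(NULL)
}
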