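#' @export
plot.ap_trace <- function(x, ...) {
  graphics::plot(x$time, x$v, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", ...)
  invisible(x)
}

#' @export
plot.bifurcation_scan <- function(x, ...) {
  s <- x$scan
  graphics::plot(rep(s$cl, 2), c(s$apd_prev, s$apd_last), pch = 16,
                 cex = 0.5, xlab = "cycle length (ms)", ylab = "APD90 (ms)",
                 xlim = rev(range(s$cl)), ...)
  if (!is.na(x$onset_cl))
    graphics::abline(v = x$onset_cl, lty = 2, col = "red")
  invisible(x)
}

#' @export
plot.restitution_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(p$di, p$ari, pch = 16, cex = 0.6, xlab = "DI (ms)",
                 ylab = "ARI (ms)", ...)
  di <- seq(min(p$di), max(p$di), length.out = 200)
  graphics::lines(di, x$alpha + x$beta * log(di), col = "red")
  invisible(x)
}

#' @export
plot.inducibility_map <- function(x, ...) {
  graphics::image(x$sigmas, x$cis, x$sustained * 1,
                  col = c("grey90", "firebrick"),
                  xlab = "conductivity (S/m)",
                  ylab = "S1S2 coupling interval (ms)", ...)
  invisible(x)
}

#' @export
plot.linkage_tree <- function(x, ...) {
  graphics::plot(x$hclust, labels = FALSE, main = "", sub = "",
                 xlab = "", ylab = "height", ...)
  invisible(x)
}
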