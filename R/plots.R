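# Base-graphics displays for the main result objects.

#' @export
plot.fpt_density <- function(x, ...) {
  graphics::plot(x$time, x$density, type = "l", xlab = "time",
                 ylab = "first-passage density", ...)
  if (x$atom_mass > 0)
    graphics::segments(x$atom_time, 0, x$atom_time, x$atom_mass,
                       lwd = 3, col = "red")
  invisible(x)
}

#' @export
plot.forage_trajectory <- function(x, ...) {
  n <- ncol(x$states)
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = "belief x_i", ...)
  invisible(x)
}

#' @export
plot.strategy_sweep <- function(x, ...) {
  s <- x$surface[is.finite(x$surface$kappa), ]
  th <- sort(unique(s$theta))
  ka <- sort(unique(s$kappa))
  z <- matrix(NA_real_, length(th), length(ka))
  for (i in seq_len(nrow(s)))
    z[match(s$theta[i], th), match(s$kappa[i], ka)] <- s$rr[i]
  graphics::image(th, seq_along(ka), z, xlab = "threshold theta",
                  ylab = "coupling strength kappa (index)", axes = FALSE,
                  main = sprintf("reward rate (%s)", x$mode), ...)
  graphics::axis(1)
  graphics::axis(2, at = seq_along(ka), labels = signif(ka, 3))
  graphics::lines(x$optimal_theta$theta_opt_smooth,
                  match(x$optimal_theta$kappa, ka), lwd = 2, col = "grey20")
  invisible(x)
}

#' @export
plot.departure_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h", xlab = "group departure time",
                 ylab = "density", ...)
  graphics::abline(v = x$mean_time, lty = 2)
  invisible(x)
}
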