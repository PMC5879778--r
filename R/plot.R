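## Base-graphics plot methods.

#' @export
plot.cc_trajectory <- function(x, species = c("e2f", "myc", "cycD", "cycE",
                                              "pp", "rb"),
                               threshold = TRUE, ...) {
  species <- match.arg(species, .species, several.ok = TRUE)
  cols <- grDevices::hcl.colors(length(species), "Dark 3")
  graphics::matplot(x$time_h, as.matrix(as.data.frame(x)[, species]),
                    type = "l", lty = 1, col = cols,
                    xlab = "time (h)", ylab = "concentration (uM)", ...)
  if (threshold)
    graphics::abline(h = 1, lty = 3, col = "darkgreen")
  graphics::legend("topleft", legend = species, col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.cc_curve <- function(x, ...) {
  graphics::plot(100 * x$o2, x$ct, type = "b", pch = 16, cex = 0.6,
                 xlab = "oxygen (%)", ylab = "commitment time (h)", ...)
  if (!is.na(x$o2_optimal))
    graphics::points(100 * x$o2_optimal, x$ct_min, col = "red", pch = 17)
  if (!is.na(x$ct_norm))
    graphics::abline(h = x$ct_norm, lty = 3, col = "grey40")
  invisible(x)
}

#' @export
plot.cc_dgsm <- function(x, ...) {
  lv <- sort(unique(x$o2_fraction))
  syms <- unique(x$symbol)
  m <- t(vapply(lv, function(o)
    x$G_score[x$o2_fraction == o][match(syms,
                                        x$symbol[x$o2_fraction == o])],
    numeric(length(syms))))
  graphics::barplot(t(m), beside = TRUE, names.arg = sprintf("%g%%",
                                                             100 * lv),
                    legend.text = syms,
                    xlab = "oxygen tension", ylab = "G-score", ...)
  invisible(x)
}
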