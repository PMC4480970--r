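#' Plot a fitted expression-class mixture over the data density
#'
#' Kernel density estimate of the log2-FPKM values (bandwidth set to twice
#' the default, smoothing the plotted curve only — classification never uses
#' it) overlaid with the two weighted Gaussian components and the LE/HE
#' class boundaries.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param values the log2-FPKM values the fit was computed from.
#' @param boundaries optional \linkS4class{ClassBoundaries} to draw.
#' @param main plot title.
#' @return invisibly, the kernel density estimate.
#' @export
plotMixtureFit <- function(fit, values, boundaries = NULL,
                           main = "log2 FPKM expression classes") {
    values <- values[is.finite(values)]
    d0 <- stats::density(values)
    d <- stats::density(values, bw = 2 * d0$bw)
    plot(d, main = main, xlab = "log2 FPKM", lwd = 2)
    xs <- seq(min(values), max(values), length.out = 400)
    graphics::lines(xs, fit@piLE * stats::dnorm(xs, fit@muLE, fit@sigmaLE),
                    col = "orange", lwd = 2)
    graphics::lines(xs, fit@piHE * stats::dnorm(xs, fit@muHE, fit@sigmaHE),
                    col = "purple", lwd = 2)
    if (!is.null(boundaries)) {
        graphics::abline(v = boundaries@tLE, col = "red", lty = 2)
        graphics::abline(v = boundaries@tHE, col = "red", lty = 3)
    }
    invisible(d)
}
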