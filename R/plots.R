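## Minimal figures: presence/absence heat grid and allele-balance
## histogram (base graphics; the analysis scripts write them as PNG).

#' Plot a presence/absence matrix as a heat grid
#'
#' Families on rows, taxa on columns; dark cells are present, light
#' gray genome-only detections, white absences.
#'
#' @param pm A `presence_matrix`.
#' @param ... Passed to `graphics::image()`.
#' @export
plot_presence_matrix <- function(pm, ...) {
  stopifnot(inherits(pm, "presence_matrix"))
  code <- matrix(match(pm$state, PRESENCE_STATES),
                 nrow = length(pm$families))
  z <- t(code[rev(seq_len(nrow(code))), , drop = FALSE])
  graphics::image(seq_along(pm$taxa), seq_along(pm$families), z,
                  col = c("#2c3e70", "#9fb2d8", "#ffffff"),
                  breaks = c(0.5, 1.5, 2.5, 3.5),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_along(pm$taxa), pm$taxa, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(pm$families), rev(pm$families), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(pm)
}

#' Plot the minor-allele-fraction histogram of a ploidy report
#'
#' @param report A `ploidy_report`.
#' @param ... Passed to `graphics::barplot()`.
#' @export
plot_allele_balance <- function(report, ...) {
  stopifnot(inherits(report, "ploidy_report"))
  graphics::barplot(report$histogram,
                    xlab = "minor-allele fraction",
                    ylab = "heterozygous sites", las = 2,
                    main = sprintf("verdict: %s", report$verdict), ...)
  invisible(report)
}
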