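#' Render an identifiability report to files
#'
#' Writes, deterministically given the report: a CI summary table
#' (`ci_table.csv`), one `(theta, chi2_pl)` CSV per parameter profile, a
#' `summary.txt` whose last line prints the design criterion exactly as
#' `mCI = <value>` (or `mCI = inf`), and a multi-panel profile plot
#' (`profiles.pdf`) with the profile as a line, the chi-square threshold
#' as a horizontal line and the true parameter value as a vertical line.
#'
#' @param report an [assess_model()] result.
#' @param out_dir output directory (created on demand).
#' @param plot also draw the multi-panel profile figure (default TRUE).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, out_dir, plot = TRUE) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)

  ci_path <- file.path(out_dir, "ci_table.csv")
  write.table(report$cis, ci_path, sep = ",", row.names = FALSE, quote = TRUE)
  files <- c(files, ci_path)

  for (pr in report$profiles) {
    p <- file.path(out_dir, sprintf("profile_%02d_%s.csv", pr$param_index,
                                    gsub("[^A-Za-z0-9]+", "_", pr$label)))
    write.table(data.frame(theta = pr$theta_grid, chi2_pl = pr$chi2_pl,
                           capped = pr$capped),
                p, sep = ",", row.names = FALSE, quote = FALSE)
    files <- c(files, p)
  }

  sm <- file.path(out_dir, "summary.txt")
  lines <- c(
    sprintf("design: TR %g s, %d slices, %d volumes (session %.4g min)",
            report$design$tr, report$design$n_slices,
            report$design$n_volumes, report$design$session / 60),
    sprintf("snr: %s   seed: %d", format(report$snr), report$seed),
    sprintf("fit: chi2 = %.6g, converged = %s", report$fit$chi2_min,
            report$fit$converged),
    sprintf("identifiable parameters: %d / %d",
            sum(report$cis$status == "identifiable"), nrow(report$cis)),
    sprintf("mCI = %s", if (is.na(report$mci)) "NA"
            else if (is.finite(report$mci)) format(report$mci)
            else "inf"))
  writeLines(lines, sm)
  files <- c(files, sm)

  if (plot && length(report$profiles)) {
    pdf_path <- file.path(out_dir, "profiles.pdf")
    grDevices::pdf(pdf_path, width = 10, height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
    np <- length(report$profiles)
    nc <- ceiling(sqrt(np)); nr <- ceiling(np / nc)
    graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
    for (i in seq_along(report$profiles))
      plot_profile(report$profiles[[i]], truth = report$cis$truth[i])
    files <- c(files, pdf_path)
  }
  invisible(files)
}

#' Plot one profile-likelihood curve
#'
#' @param curve a [profile_parameter()] result.
#' @param truth optional true parameter value (vertical line).
#' @param ... passed to [graphics::plot()].
#' @export
plot_profile <- function(curve, truth = NULL, ...) {
  keep <- !curve$capped
  thr <- curve$chi2_hat + curve$delta
  ylim <- range(c(curve$chi2_pl[keep], thr), finite = TRUE)
  graphics::plot(curve$theta_grid[keep], curve$chi2_pl[keep], type = "l",
                 col = "blue", xlab = curve$label,
                 ylab = expression(chi^2), ylim = ylim, ...)
  graphics::abline(h = thr, col = "red")
  if (!is.null(truth) && is.finite(truth))
    graphics::abline(v = truth, col = "darkgreen")
  graphics::points(curve$theta_hat_i, curve$chi2_hat, pch = 19, cex = 0.6)
  invisible(curve)
}
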