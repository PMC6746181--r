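#' Number of distinct UMIs of a given length
#'
#' The UMI capacity bounds the number of template molecules that can be
#' counted before identical tags become unavoidable: a 7-base UMI gives
#' `4^7 = 16384` possible tags, the theoretical single-locus limit of
#' detection for molecule counting.
#'
#' @param umi_length UMI length in bases (>= 0).
#' @return `4^umi_length` as a double.
#' @examples
#' umi_capacity(7) # 16384
#' @export
umi_capacity <- function(umi_length) {
  if (!is.numeric(umi_length) || any(umi_length < 0)) {
    abort("`umi_length` must be >= 0")
  }
  4^umi_length
}

#' Expected number of distinct UMIs after random tagging
#'
#' Collision correction for the capacity bound: tagging `n_molecules`
#' templates uniformly from `capacity` tags yields on average
#' `capacity * (1 - (1 - 1/capacity)^n)` distinct tags.
#'
#' @param n_molecules number of tagged molecules (>= 0).
#' @param capacity number of possible tags (>= 1), e.g. [umi_capacity()].
#' @return expected distinct tag count.
#' @examples
#' expected_distinct(16384, umi_capacity(7))
#' @export
expected_distinct <- function(n_molecules, capacity) {
  if (any(n_molecules < 0)) abort("`n_molecules` must be >= 0")
  if (any(capacity < 1)) abort("`capacity` must be >= 1")
  capacity * (1 - (1 - 1 / capacity)^n_molecules)
}

#' Fit a spike-in calibration curve
#'
#' Builds the monotone log-log mapping from input template molecules to
#' observed unique mutant families over a spike-in benchmark. Observations
#' are pooled across loci and grouped by their true input amount; each
#' level's support point is the mean `log10` observed mutant-family count
#' over the replicates that observed at least one family. Levels where every
#' replicate observed zero families are excluded with a warning. The fitted
#' curve is made non-decreasing by isotonic regression; its top end is the
#' saturation level (observed plateau).
#'
#' @param reports locus call reports with `library_id`, `locus_id` and
#'   `mutant_families` (for example from [call_libraries()]).
#' @param truth truth manifest with `library_id`, `locus_id`,
#'   `true_template_molecules`.
#' @param min_levels minimum usable spike levels (default 3).
#' @return object of class `spikein_curve`: list with `support` (tibble of
#'   `log10_molecules`, `log10_families`, `n_obs`, `sd_log10_families`),
#'   `saturation_level` (families, natural scale) and `n_levels`.
#' @export
fit_spikein_curve <- function(reports, truth, min_levels = 3L) {
  obs <- dplyr::inner_join(reports, truth, by = c("library_id", "locus_id"))
  obs <- obs[obs$true_template_molecules > 0, , drop = FALSE]
  lev <- dplyr::summarise(
    dplyr::group_by(obs, molecules = .data$true_template_molecules),
    n_obs = sum(.data$mutant_families >= 1),
    n_zero = sum(.data$mutant_families < 1),
    log10_families = mean(log10(.data$mutant_families[
      .data$mutant_families >= 1])),
    sd_log10_families = stats::sd(log10(.data$mutant_families[
      .data$mutant_families >= 1])),
    .groups = "drop"
  )
  dropped <- lev$molecules[lev$n_obs == 0]
  if (length(dropped) > 0) {
    warn(sprintf(
      "spike level(s) %s had zero observed mutant families everywhere; excluded",
      paste(dropped, collapse = ", ")))
    lev <- lev[lev$n_obs > 0, , drop = FALSE]
  }
  if (nrow(lev) < min_levels) {
    abort(sprintf("need >= %d usable spike levels, got %d", min_levels,
                  nrow(lev)))
  }
  lev <- dplyr::arrange(lev, .data$molecules)
  iso <- stats::isoreg(log10(lev$molecules), lev$log10_families)
  support <- tibble(
    log10_molecules = log10(lev$molecules),
    log10_families = iso$yf,
    n_obs = lev$n_obs,
    sd_log10_families = lev$sd_log10_families
  )
  structure(
    list(
      support = support,
      saturation_level = 10^support$log10_families[nrow(support)],
      n_levels = nrow(support)
    ),
    class = "spikein_curve"
  )
}

#' @export
print.spikein_curve <- function(x, ...) {
  cat(sprintf(
    "<spikein_curve> %d levels, saturation %.1f mutant families\n",
    x$n_levels, x$saturation_level))
  print(x$support, ...)
  invisible(x)
}

#' Evaluate a spike-in curve at given input molecule counts
#'
#' Piecewise-linear interpolation in log-log space; inputs outside the
#' calibrated range are extrapolated linearly from the terminal segments.
#'
#' @param object a `spikein_curve`.
#' @param molecules input molecule counts (> 0).
#' @param ... unused.
#' @return expected observed mutant families (natural scale).
#' @export
predict.spikein_curve <- function(object, molecules, ...) {
  s <- object$support
  x <- log10(molecules)
  y <- stats::approx(s$log10_molecules, s$log10_families, xout = x,
                     rule = 2)$y
  # linear extrapolation beyond the support
  n <- nrow(s)
  if (n >= 2) {
    lo <- x < s$log10_molecules[1]
    hi <- x > s$log10_molecules[n]
    slope1 <- (s$log10_families[2] - s$log10_families[1]) /
      (s$log10_molecules[2] - s$log10_molecules[1])
    slopen <- (s$log10_families[n] - s$log10_families[n - 1]) /
      (s$log10_molecules[n] - s$log10_molecules[n - 1])
    y[lo] <- s$log10_families[1] + slope1 * (x[lo] - s$log10_molecules[1])
    y[hi] <- s$log10_families[n] + slopen * (x[hi] - s$log10_molecules[n])
  }
  10^y
}

#' Back-calculate input molecules from observed mutant families
#'
#' Inverts the monotone spike-in curve by piecewise-linear inversion in
#' log-log space. Observations at or above the curve's plateau cannot be
#' resolved and are clamped to the largest calibrated input with an
#' `at_or_above_saturation` flag; zero observed families map to zero
#' molecules; observations below the calibrated range are extrapolated and
#' flagged.
#'
#' @param observed_families observed unique mutant family counts (>= 0).
#' @param curve a fitted `spikein_curve`.
#' @return tibble with `observed_families`, `estimated_molecules`, `flag`
#'   (`"ok"`, `"zero"`, `"below_range"`, `"at_or_above_saturation"`).
#' @examples
#' \dontrun{
#' interpolate_molecules(c(0, 5, 50), curve)
#' }
#' @export
interpolate_molecules <- function(observed_families, curve) {
  if (!inherits(curve, "spikein_curve")) {
    abort("`curve` must be a fitted spikein_curve")
  }
  if (any(observed_families < 0)) abort("`observed_families` must be >= 0")
  s <- curve$support
  # collapse plateau levels (equal fitted y) keeping the smallest input, so
  # the inversion is well defined; everything at/above the top is clamped
  keep <- !duplicated(s$log10_families)
  si <- s[keep, , drop = FALSE]
  y_top <- s$log10_families[nrow(s)]
  x_top <- s$log10_molecules[nrow(s)]
  out <- purrr::map(observed_families, function(f) {
    if (f == 0) {
      return(list(est = 0, flag = "zero"))
    }
    yf <- log10(f)
    if (yf >= y_top) {
      return(list(est = 10^x_top, flag = "at_or_above_saturation"))
    }
    if (yf < si$log10_families[1]) {
      if (nrow(si) >= 2) {
        slope <- (si$log10_molecules[2] - si$log10_molecules[1]) /
          (si$log10_families[2] - si$log10_families[1])
        est <- 10^(si$log10_molecules[1] +
                     slope * (yf - si$log10_families[1]))
      } else {
        est <- 10^si$log10_molecules[1]
      }
      return(list(est = est, flag = "below_range"))
    }
    est <- 10^stats::approx(si$log10_families, si$log10_molecules,
                            xout = yf, ties = "ordered")$y
    list(est = est, flag = "ok")
  })
  tibble(
    observed_families = observed_families,
    estimated_molecules = vapply(out, function(o) o$est, numeric(1)),
    flag = vapply(out, function(o) o$flag, character(1))
  )
}

#' Attach interpolated molecule estimates to a locus call report
#'
#' @param report locus call report (with `dedup_mutant_count`).
#' @param curve a fitted `spikein_curve`.
#' @return the report with `interpolated_molecules` and
#'   `interpolation_flag` columns.
#' @export
quantify_report <- function(report, curve) {
  est <- interpolate_molecules(report$dedup_mutant_count, curve)
  dplyr::mutate(report,
                interpolated_molecules = est$estimated_molecules,
                interpolation_flag = est$flag)
}

#' Serialise a spike-in curve to JSON
#'
#' @param curve a `spikein_curve`.
#' @param path JSON file path.
#' @export
write_curve_json <- function(curve, path) {
  jsonlite::write_json(
    list(support = curve$support,
         saturation_level = curve$saturation_level,
         n_levels = curve$n_levels),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(support = as_tibble(x$support),
         saturation_level = x$saturation_level,
         n_levels = x$n_levels),
    class = "spikein_curve"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_spikein_curve
#' @param x,object a `spikein_curve`.
#' @param ... unused.
#' @method tidy spikein_curve
#' @export
tidy.spikein_curve <- function(x, ...) x$support

#' @rdname fit_spikein_curve
#' @method glance spikein_curve
#' @export
glance.spikein_curve <- function(x, ...) {
  tibble(n_levels = x$n_levels,
         saturation_level = x$saturation_level,
         min_log10_molecules = x$support$log10_molecules[1],
         max_log10_molecules = x$support$log10_molecules[x$n_levels])
}

#' Plot a spike-in calibration curve
#'
#' @param object a `spikein_curve`.
#' @param ... unused.
#' @return a ggplot: observed mutant families against input molecules on
#'   log-log axes, with the fitted monotone curve and the saturation level.
#' @method autoplot spikein_curve
#' @export
autoplot.spikein_curve <- function(object, ...) {
  s <- object$support
  grid <- tibble(molecules = 10^seq(min(s$log10_molecules),
                                    max(s$log10_molecules),
                                    length.out = 200))
  grid$families <- predict(object, grid$molecules)
  ggplot2::ggplot(s, ggplot2::aes(x = 10^.data$log10_molecules,
                                  y = 10^.data$log10_families)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$molecules,
                                    y = .data$families),
                       colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$saturation_level,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input template molecules",
                  y = "observed unique mutant families",
                  title = "Spike-in calibration curve") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
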