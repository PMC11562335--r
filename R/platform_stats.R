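# Platform-agreement statistics for matched berries measured by two
# platforms: per-trait mean differences, the range-normalised mean
# difference (rmd), Pearson correlations and paired t-tests.

#' Range-normalised mean difference
#'
#' Effect size for paired measurements from two platforms:
#' `rmd = mean(x - y) / min(max(x) - min(x), max(y) - min(y))` - the mean
#' paired difference divided by the smaller within-platform range. The
#' normalisation places traits of different scales on a comparable footing
#' and emphasises that measurements within one platform vary more than the
#' shift between platforms. Antisymmetric in its arguments and invariant to
#' multiplying both platforms by a positive constant.
#'
#' @param x,y paired numeric vectors of equal length (>= 2); `x` is the
#'   platform under evaluation, `y` the reference.
#' @return Dimensionless scalar.
#' @export
rmd <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  rx <- max(x) - min(x)
  ry <- max(y) - min(y)
  if (rx <= 0 || ry <= 0) {
    stop("rmd is undefined when a platform has zero range", call. = FALSE)
  }
  mean(x - y) / min(rx, ry)
}

#' Compare traits between two platforms on matched berries
#'
#' For every trait, computes platform means with t-based 95% confidence
#' intervals, pooled population minima/maxima, the mean difference `x - y`,
#' [rmd()], the Pearson correlation, and a paired t-test on the per-berry
#' differences. No multiple-testing correction is applied (p-values on
#' large samples are reported with that caveat in mind).
#'
#' @param matched tibble of matched berries, one row per pair, containing
#'   `<trait><suffix[1]>` and `<trait><suffix[2]>` columns for every trait.
#' @param traits character vector of trait base names.
#' @param suffix length-2 suffixes of the two platforms' columns.
#' @param platforms display names of the two platforms.
#' @param conf confidence level for the interval of each platform mean.
#' @return A `trait_comparison` tibble, one row per trait: `trait`, `n`,
#'   `mean_x`, `mean_y`, `min_x`, `max_x`, `min_y`, `max_y`, `lci_x`,
#'   `uci_x`, `lci_y`, `uci_y`, `md`, `rmd`, `r`, `t`, `p`.
#' @export
compare_traits <- function(matched, traits, suffix = c("_x", "_y"),
                           platforms = c("x", "y"), conf = 0.95) {
  rows <- purrr::map_dfr(traits, function(tr) {
    cx <- paste0(tr, suffix[1]); cy <- paste0(tr, suffix[2])
    if (!cx %in% names(matched) || !cy %in% names(matched)) {
      stop("columns for trait '", tr, "' not found", call. = FALSE)
    }
    x <- matched[[cx]]; y <- matched[[cy]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    stopifnot(n >= 2)
    ci <- function(v) {
      se <- stats::sd(v) / sqrt(n)
      q <- stats::qt(1 - (1 - conf) / 2, n - 1)
      c(mean(v) - q * se, mean(v) + q * se)
    }
    cix <- ci(x); ciy <- ci(y)
    d <- x - y
    if (stats::sd(d) > 0) {
      tt <- stats::t.test(x, y, paired = TRUE)
      t_stat <- unname(tt$statistic); p_val <- tt$p.value
    } else {
      # constant differences: t.test() refuses; the limit is well defined
      t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p_val <- if (mean(d) == 0) 1 else 0
    }
    rng_ok <- (max(x) > min(x)) && (max(y) > min(y))
    tibble::tibble(
      trait = tr, n = n,
      mean_x = mean(x), mean_y = mean(y),
      min_x = min(x), max_x = max(x), min_y = min(y), max_y = max(y),
      lci_x = cix[1], uci_x = cix[2], lci_y = ciy[1], uci_y = ciy[2],
      md = mean(x - y),
      rmd = if (rng_ok) rmd(x, y) else NA_real_,
      r = if (stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y) else NA_real_,
      t = t_stat, p = p_val)
  })
  structure(rows, platforms = platforms,
            class = c("trait_comparison", class(rows)))
}

#' @export
print.trait_comparison <- function(x, ...) {
  pl <- attr(x, "platforms")
  cat(sprintf("<trait_comparison> %s vs %s, %d trait(s)\n",
              pl[1], pl[2], nrow(x)))
  NextMethod()
}

#' Write a platform-comparison report CSV
#'
#' Long-format table with one row per trait and platform: `trait`,
#' `platform`, `mean`, `min`, `max`, `lci`, `uci` and, on the first
#' platform's row, the agreement statistics `md`, `rmd`, `r`. Zero
#' comparisons give a header-only file.
#'
#' @param comparisons a [compare_traits()] result.
#' @param path output CSV.
#' @return The long-format tibble, invisibly.
#' @export
comparison_report <- function(comparisons, path) {
  pl <- attr(comparisons, "platforms") %||% c("x", "y")
  rows <- purrr::map_dfr(seq_len(nrow(comparisons)), function(i) {
    cc <- comparisons[i, ]
    tibble::tibble(
      trait = rep(cc$trait, 2), platform = pl,
      mean = c(cc$mean_x, cc$mean_y),
      min = c(cc$min_x, cc$min_y), max = c(cc$max_x, cc$max_y),
      lci = c(cc$lci_x, cc$lci_y), uci = c(cc$uci_x, cc$uci_y),
      md = c(cc$md, NA_real_), rmd = c(cc$rmd, NA_real_),
      r = c(cc$r, NA_real_))
  })
  if (!nrow(comparisons)) {
    rows <- tibble::tibble(trait = character(), platform = character(),
                           mean = numeric(), min = numeric(),
                           max = numeric(), lci = numeric(), uci = numeric(),
                           md = numeric(), rmd = numeric(), r = numeric())
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(rows)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trait comparison
#'
#' One row per trait with the agreement statistics, ready for further
#' dplyr/ggplot work.
#'
#' @param x a `trait_comparison`.
#' @param ... unused.
#' @return A tibble with columns `trait`, `n`, `md`, `rmd`, `r`, `t`, `p`.
#' @export
tidy.trait_comparison <- function(x, ...) {
  tibble::as_tibble(x)[, c("trait", "n", "md", "rmd", "r", "t", "p")]
}

#' One-line summary of a trait comparison
#'
#' @param x a `trait_comparison`.
#' @param ... unused.
#' @return A one-row tibble: number of traits, median absolute `rmd`,
#'   minimum correlation, number of traits with p below 0.05.
#' @export
glance.trait_comparison <- function(x, ...) {
  tibble::tibble(n_traits = nrow(x),
                 median_abs_rmd = stats::median(abs(x$rmd), na.rm = TRUE),
                 min_r = if (all(is.na(x$r))) NA_real_ else
                   min(x$r, na.rm = TRUE),
                 n_signif = sum(x$p < 0.05, na.rm = TRUE))
}
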