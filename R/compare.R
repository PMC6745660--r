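#' Median test for two samples (Fisher exact probability)
#'
#' Dichotomises the pooled values at their grand median, cross-classifies each
#' group as strictly above versus at-or-below the grand median, and evaluates
#' the resulting 2x2 table with Fisher's exact probability. The two-tailed p is
#' the sum of the probabilities of all tables with the observed margins whose
#' point (hypergeometric) probability does not exceed that of the observed
#' table (`two_tailed = "prob"`, the common "Fisher exact probability"
#' convention); `two_tailed = "double"` instead doubles the smaller one-sided
#' tail (capped at 1). Ties with the grand median fall in the at-or-below cell.
#'
#' @param data data frame with one row per individual/journey.
#' @param value column of values to compare (e.g. furthest-east longitude,
#'   unwrapped degrees), given as a bare column name.
#' @param group column defining the two groups (bare column name); must have
#'   exactly two levels.
#' @param two_tailed `"prob"` or `"double"`, see above.
#' @return An object of class `median_test`: list with `table` (2x2 counts,
#'   groups x above/at-or-below), `grand_median`, `p_value`, `method`,
#'   `groups`. If all pooled values are identical, `p_value = 1` with a
#'   warning. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' df <- data.frame(
#'   lon = c(152, 158, 167, 122, 89, 158, 207, 122, 157, 153, 101, 101,
#'           27, 20, 15, 30, 45, 60, 12, 80, 109, 33, 25),
#'   pop = rep(c("baltic", "greenland-like"), c(12, 11))
#' )
#' median_test(df, lon, pop)
#' @export
median_test <- function(data, value, group, two_tailed = c("prob", "double")) {
  two_tailed <- match.arg(two_tailed)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  stopifnot(all(is.finite(v)))
  lv <- unique(g)
  if (length(lv) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  if (length(v) < 4) stop("need a combined n of at least 4", call. = FALSE)
  med <- stats::median(v)
  if (all(v == v[1])) {
    warning("all pooled values identical; median test is degenerate")
    tab <- rbind(c(0, sum(g == lv[1])), c(0, sum(g == lv[2])))
    dimnames(tab) <- list(lv, c("above", "at_or_below"))
    return(structure(
      list(
        table = tab, grand_median = med, p_value = 1,
        method = two_tailed, groups = lv
      ),
      class = "median_test"
    ))
  }
  above <- v > med
  tab <- rbind(
    c(sum(above & g == lv[1]), sum(!above & g == lv[1])),
    c(sum(above & g == lv[2]), sum(!above & g == lv[2]))
  )
  dimnames(tab) <- list(lv, c("above", "at_or_below"))
  p <- fisher_p_2x2(tab, two_tailed)
  structure(
    list(
      table = tab, grand_median = med, p_value = p,
      method = two_tailed, groups = lv
    ),
    class = "median_test"
  )
}

# two-tailed Fisher exact p for a 2x2 table via the hypergeometric distribution
fisher_p_2x2 <- function(tab, two_tailed = "prob") {
  n1 <- sum(tab[1, ])
  n2 <- sum(tab[2, ])
  m <- sum(tab[, 1]) # total "above"
  a_obs <- tab[1, 1]
  a_min <- max(0, m - n2)
  a_max <- min(m, n1)
  a <- a_min:a_max
  probs <- stats::dhyper(a, n1, n2, m)
  p_obs <- stats::dhyper(a_obs, n1, n2, m)
  if (two_tailed == "prob") {
    # sum of all tables no more probable than the observed one
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  } else {
    lower <- sum(probs[a <= a_obs])
    upper <- sum(probs[a >= a_obs])
    min(1, 2 * min(lower, upper))
  }
}

#' @export
print.median_test <- function(x, ...) {
  cat("Median test (Fisher exact probability, two-tailed)\n")
  cat(sprintf("grand median = %g\n", x$grand_median))
  print(x$table)
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.median_test <- function(x, ...) {
  tibble::tibble(
    group = rownames(x$table),
    above = x$table[, "above"],
    at_or_below = x$table[, "at_or_below"]
  )
}

#' @export
glance.median_test <- function(x, ...) {
  tibble::tibble(
    grand_median = x$grand_median,
    p_value = x$p_value,
    n = sum(x$table),
    method = paste0("median test / Fisher exact (", x$method, ")")
  )
}

#' Summarise furthest-east longitudes per population
#'
#' @param data data frame with one row per journey.
#' @param value furthest-east longitude column (unwrapped degrees; bare name).
#' @param group population column (bare name).
#' @return A tibble per group: `n`, `mean_lon` (nearest degree), `median_lon`,
#'   `min_lon`, `max_lon`.
#' @export
summarize_furthest_east <- function(data, value, group) {
  data |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_lon = round(mean({{ value }})),
      median_lon = stats::median({{ value }}),
      min_lon = min({{ value }}),
      max_lon = max({{ value }}),
      .groups = "drop"
    )
}
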