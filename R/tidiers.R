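#' Tidy a single exact CMH test
#'
#' @param x A [exact_cmh()] result.
#' @param ... Unused.
#' @return A one-row tibble with estimate, confidence bounds, statistic and
#'   p-value.
#' @method tidy cmh_test
#' @export
tidy.cmh_test <- function(x, ...) {
  tibble(
    estimate = unname(x$estimate),
    conf.low = x$conf.int[1],
    conf.high = x$conf.int[2],
    statistic = unname(x$statistic),
    p.value = x$p.value,
    method = x$method,
    alternative = x$alternative
  )
}

#' @rdname tidy.cmh_test
#' @method glance cmh_test
#' @export
glance.cmh_test <- function(x, ...) {
  tibble(
    n_strata = x$n_strata,
    untestable = x$untestable,
    p.value = x$p.value,
    estimate = unname(x$estimate)
  )
}

#' @method tidy rc_ztest
#' @export
tidy.rc_ztest <- function(x, ...) {
  tibble(
    estimate1 = unname(x$estimate[1]),
    estimate2 = unname(x$estimate[2]),
    statistic = unname(x$statistic),
    p.value = x$p.value,
    method = x$method,
    alternative = x$alternative
  )
}

#' @method tidy rc_qq
#' @export
tidy.rc_qq <- function(x, ...) {
  x$data
}

#' @method glance rc_qq
#' @export
glance.rc_qq <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    n_units = nrow(x$data),
    n_permutations = x$n_permutations
  )
}
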