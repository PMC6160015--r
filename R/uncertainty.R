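#' Specify a probabilistic sensitivity analysis
#'
#' Declares the sampled inputs and Monte Carlo settings. Each parameter row
#' gives a distribution family and its two parameters: `normal` (mean, sd)
#' for trial percent changes (SE taken as CI half-width / 1.96), `lognormal`
#' (meanlog = log(mean), sdlog = sd) for relative risks, `gamma`
#' (mean, sd, re-parameterised to shape/rate) for costs, and `fixed`
#' (degenerate at mean).
#'
#' @param params Tibble with columns `parameter`, `dist`, `mean`, `sd`.
#' @param n_iterations Monte Carlo iterations; default 2000.
#' @param seed Integer seed.
#' @return A `psa_spec` object.
#' @export
psa_spec <- function(params, n_iterations = 2000, seed = 1) {
  stopifnot(n_iterations >= 1)
  required <- c("parameter", "dist", "mean", "sd")
  if (!all(required %in% names(params))) {
    abort("`params` needs columns parameter, dist, mean, sd.")
  }
  ok <- c("normal", "lognormal", "gamma", "fixed")
  if (!all(params$dist %in% ok)) {
    abort(paste0("Unknown distribution family: ",
                 paste(setdiff(params$dist, ok), collapse = ", ")))
  }
  if (any(params$sd < 0 | (params$dist != "fixed" & !is.finite(params$sd)))) {
    abort("Distribution SDs must be finite and non-negative.")
  }
  if (anyDuplicated(params$parameter) > 0) abort("Parameter names must be unique.")
  structure(list(params = params, n_iterations = as.integer(n_iterations),
                 seed = seed),
            class = "psa_spec")
}

draw_parameters <- function(spec) {
  n <- spec$n_iterations
  cols <- purrr::pmap(spec$params, function(parameter, dist, mean, sd, ...) {
    switch(dist,
      fixed = rep(mean, n),
      normal = if (sd == 0) rep(mean, n) else rnorm(n, mean, sd),
      lognormal = if (sd == 0) rep(mean, n) else rlnorm(n, log(mean), sd),
      gamma = if (sd == 0) rep(mean, n) else {
        rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
      }
    )
  })
  names(cols) <- spec$params$parameter
  tibble::as_tibble(cols) |>
    dplyr::mutate(iteration = dplyr::row_number(), .before = 1)
}

#' Monte Carlo uncertainty propagation
#'
#' Draws each sampled input from its declared distribution, evaluates the
#' model pipeline on every draw, and summarises outputs as the mean and the
#' empirical 2.5th/97.5th percentiles (linear-interpolation quantiles, the
#' non-parametric interval choice). Draws whose model evaluation errors are
#' recorded as failed and excluded from summaries; more than 1% failures
#' aborts with the first error messages. When the outputs include
#' `dalys_averted` and `net_cost`, draws are also classified into
#' cost-effectiveness-plane quadrants.
#'
#' @param model A function taking one named list of parameter values and
#'   returning a named list/one-row tibble of numeric outputs. Must be
#'   deterministic given a draw.
#' @param spec A [psa_spec()].
#' @return A `psa_result`: list with `draws` (tibble of per-iteration
#'   outputs), `summary` (per output: mean, lo, hi), `quadrants`
#'   (fractions summing to 1, or NULL), `n_failed`, and the spec.
#' @export
run_psa <- function(model, spec) {
  stopifnot(inherits(spec, "psa_spec"))
  withr::with_seed(spec$seed, {
    par_draws <- draw_parameters(spec)
    errors <- character(0)
    rows <- purrr::map(seq_len(nrow(par_draws)), function(i) {
      draw <- as.list(par_draws[i, setdiff(names(par_draws), "iteration")])
      tryCatch(
        {
          out <- model(draw)
          tibble::as_tibble(as.list(out)) |>
            dplyr::mutate(iteration = i, .before = 1)
        },
        error = function(e) {
          errors[[length(errors) + 1]] <<- conditionMessage(e)
          NULL
        }
      )
    })
  })
  n_failed <- sum(vapply(rows, is.null, logical(1)))
  if (n_failed > 0.01 * spec$n_iterations) {
    abort(paste0(
      n_failed, " of ", spec$n_iterations, " iterations failed (> 1%). ",
      "First errors: ", paste(head(unique(errors), 3), collapse = " | ")
    ))
  }
  draws <- dplyr::bind_rows(rows)
  out_cols <- setdiff(names(draws), "iteration")
  summary <- purrr::map_dfr(out_cols, function(v) {
    x <- draws[[v]]
    tibble::tibble(
      output = v, mean = mean(x),
      lo = unname(quantile(x, 0.025, type = 7)),
      hi = unname(quantile(x, 0.975, type = 7))
    )
  })
  bad <- summary$mean < summary$lo | summary$mean > summary$hi
  if (any(bad)) {
    warn(paste0("Mean outside the 95% interval for: ",
                paste(summary$output[bad], collapse = ", "),
                " (heavily skewed or multimodal draws)."))
  }
  quadrants <- NULL
  if (all(c("dalys_averted", "net_cost") %in% out_cols)) {
    quadrants <- draws |>
      dplyr::count(
        quadrant = dplyr::case_when(
          .data$net_cost > 0 & .data$dalys_averted < 0 ~ "upper_left",
          .data$net_cost > 0 & .data$dalys_averted >= 0 ~ "upper_right",
          .data$net_cost <= 0 & .data$dalys_averted < 0 ~ "lower_left",
          TRUE ~ "lower_right"
        )
      ) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n))
  }
  structure(
    list(draws = draws, summary = summary, quadrants = quadrants,
         n_failed = n_failed, failures = errors, spec = spec),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", nrow(x$draws), " successful draws (",
      x$n_failed, " failed), seed ", x$spec$seed, "\n", sep = "")
  print(x$summary)
  if (!is.null(x$quadrants)) {
    cat("cost-effectiveness plane quadrants:\n")
    print(x$quadrants)
  }
  invisible(x)
}

#' @rdname run_psa
#' @param x A `psa_result`.
#' @param ... Unused.
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @rdname run_psa
#' @export
glance.psa_result <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "output",
                       values_from = c("mean", "lo", "hi")) |>
    dplyr::mutate(n_iterations = x$spec$n_iterations, n_failed = x$n_failed)
}

#' Cost-effectiveness plane
#'
#' Scatter of per-draw (DALYs averted, net cost) pairs. Health losses at
#' extra cost fall in the upper-left quadrant, where an intervention is
#' dominated by current practice.
#'
#' @param object A `psa_result` whose outputs include `dalys_averted` and
#'   `net_cost`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, ...) {
  if (!all(c("dalys_averted", "net_cost") %in% names(object$draws))) {
    abort("Draws must include `dalys_averted` and `net_cost` for a CE plane.")
  }
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$dalys_averted, y = .data$net_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "DALYs averted (negative = health loss)",
      y = "Net cost (AUD2011)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
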