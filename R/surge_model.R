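#' Construct a surge model object
#'
#' Wraps a model variant and its parameters into a single object with the
#' usual modelling verbs: \code{predict} evaluates the closed-form
#' trajectory, \code{simulate} integrates the governing ODEs numerically
#' (the independent cross-check), and \code{print}/\code{summary}/
#' \code{plot} report the key timescales.
#'
#' @param variant One of \code{"simple"}, \code{"delayed"},
#'   \code{"capacity"}, \code{"ptc"}, \code{"mortality"}.
#' @param rates The matching rate-set object.
#' @param deaths A [death_rate_set()] (mortality variant only).
#' @param n0 Initial cohort size in persons; trajectories are fractions
#'   and are multiplied by \code{n0} only for presentation.
#' @param threshold Discharged fraction defining the completion time.
#' @return An object of class \code{"surge_model"}.
#' @examples
#' m <- surge_model("capacity", rate_set(0.158, 1.151, 0.122))
#' predict(m, times = c(2, 8, 10))
#' @export
surge_model <- function(variant = c("simple", "delayed", "capacity", "ptc",
                                    "mortality"),
                        rates, deaths = NULL, n0 = 1, threshold = 0.99) {
  variant <- match.arg(variant)
  needed <- switch(variant,
                   simple = "rate_set", delayed = "delayed_rate_set",
                   capacity = "rate_set", ptc = "ptc_rate_set",
                   mortality = "ptc_rate_set")
  if (!inherits(rates, needed)) {
    stop("variant '", variant, "' needs rates of class '", needed, "'")
  }
  if (variant == "mortality" && !inherits(deaths, "death_rate_set")) {
    stop("the mortality variant needs a death_rate_set")
  }
  if (variant == "capacity") check_kprime(rates)
  structure(list(variant = variant, rates = rates, deaths = deaths,
                 n0 = n0, threshold = threshold),
            class = "surge_model")
}

#' @export
predict.surge_model <- function(object, times = NULL, ...) {
  times <- default_times(object, times)
  tr <- switch(object$variant,
               simple = simple_model_at(times, object$rates),
               delayed = delayed_model_at(times, object$rates),
               capacity = capacity_model_at(times, object$rates),
               ptc = ptc_model_at(times, object$rates),
               mortality = mortality_model_at(times, object$rates,
                                              object$deaths))
  scale_counts(tr, object$n0)
}

#' Numerically integrated trajectory of a surge model
#'
#' \code{simulate} deliberately bypasses the closed forms: it integrates
#' the model's governing ODEs with the fixed-step Runge-Kutta oracle, so a
#' side-by-side comparison with \code{predict} verifies the implementation.
#'
#' @param object A [surge_model()].
#' @param nsim,seed Ignored (the model is deterministic); present for
#'   compatibility with the generic.
#' @param times Times (days) at which to report the state.
#' @param step Integration step (days).
#' @param ... Unused.
#' @export
simulate.surge_model <- function(object, nsim = 1, seed = NULL,
                                 times = NULL, step = 1e-3, ...) {
  times <- default_times(object, times)
  variant <- object$variant
  tr <- oracle_trajectory(variant, object$rates, t_grid = times,
                          step = step, deaths = object$deaths)
  scale_counts(tr, object$n0)
}

#' Key timescales of a surge model
#'
#' @param model A [surge_model()].
#' @return A named vector of the model's breakpoints and completion time
#'   (days), as applicable to the variant.
#' @export
surge_timescales <- function(model) {
  stopifnot(inherits(model, "surge_model"))
  switch(model$variant,
    simple = c(t_peak = time_of_max_admitted(model$rates)),
    delayed = c(t_surge_peak = time_of_max_surge_delayed(model$rates)),
    capacity = {
      bp <- capacity_breakpoints(model$rates)
      c(t1 = bp$t1, t2 = bp$t2,
        t99 = capacity_t99(model$rates, model$threshold))
    },
    ptc = {
      bd <- ptc_boundaries(model$rates)
      c(t1a = bd$t1a, t1p = bd$t1p, t2 = bd$t2,
        t99 = ptc_t99(model$rates, model$threshold))
    },
    mortality = {
      bd <- mortality_boundaries(model$rates, model$deaths)
      c(t1a = bd$t1a, t1p = bd$t1p, t2 = bd$t2)
    })
}

#' @export
print.surge_model <- function(x, ...) {
  cat("Surge kinetics model, variant '", x$variant, "' (N0 = ", x$n0, ")\n",
      sep = "")
  print(x$rates)
  if (!is.null(x$deaths)) print(x$deaths)
  ts <- surge_timescales(x)
  cat("  timescales (days): ",
      paste(sprintf("%s = %.3f", names(ts), ts), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.surge_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.surge_model <- function(x, times = NULL, ...) {
  tr <- predict(x, times)
  labels <- switch(x$variant,
    simple = c(Ns = "Surge", Na = "Admitted", Nd = "Discharged"),
    capacity = c(Ns = "Surge", Na = "Admitted", Nd = "Discharged"),
    delayed = c(Ne = "Exposed", Ns = "Surge", Na = "Admitted",
                Nd = "Discharged"),
    ptc = c(Ps = "Surge", Paa = "Adult center", Pap = "PTC",
            Pd = "Discharged"),
    mortality = c(Ps = "Surge", Paa = "Adult center", Pap = "PTC",
                  Pd = "Discharged", PD = "Deceased"))
  plot_trajectory(tr, labels,
                  main = paste0("Surge model ('", x$variant, "')"), ...)
  invisible(tr)
}

default_times <- function(object, times) {
  if (!is.null(times)) return(times)
  horizon <- switch(object$variant,
    simple = 5 / object$rates$ka,
    delayed = 5 / min(object$rates$ks, object$rates$ka),
    capacity = 1.2 * capacity_t99(object$rates, object$threshold),
    ptc = 1.2 * ptc_t99(object$rates, object$threshold),
    mortality = 1.5 * mortality_boundaries(object$rates, object$deaths)$t2)
  seq(0, horizon, length.out = 201)
}

scale_counts <- function(tr, n0) {
  if (n0 != 1) {
    num <- setdiff(names(tr), c("t", "region"))
    tr[num] <- tr[num] * n0
  }
  tr
}

plot_trajectory <- function(tr, labels, main = "", ...) {
  cols <- c("steelblue", "firebrick", "darkorange", "forestgreen", "black")
  nm <- intersect(names(labels), names(tr))
  graphics::matplot(tr$t, as.matrix(tr[nm]), type = "l", lty = 1,
                    col = cols[seq_along(nm)], xlab = "time (days)",
                    ylab = "population", main = main, ...)
  graphics::legend("right", legend = labels[nm], col = cols[seq_along(nm)],
                   lty = 1, bty = "n")
  invisible(tr)
}
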