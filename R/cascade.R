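#' Three-step residualization cascade of service correlations
#'
#' Computes pairwise Pearson correlations between ecosystem services at
#' three stages: (1) the (standardized) services themselves, (2) their
#' residuals from linear models on the environmental factors, and
#' (3) their residuals from models on environment plus all forest
#' attributes.  The ordering encodes a hierarchy of controls in which
#' the environment partially determines the attributes (e.g. via
#' management), so any variance shared between the two blocks is
#' credited to the environment: a conservative reading of attribute
#' effects.
#'
#' Correlations use pairwise-complete observations and the per-pair
#' sample size is recorded; a pair with fewer than 10 shared
#' observations is set to `NA` with a warning.  The residual service
#' matrices are kept because the pairwise tests of [compare_pairs()]
#' need the realized variables at each step.
#'
#' @param data a [plot_data] object, typically standardized via
#'   [apply_transforms()].
#' @return object of class `es_cascade`: list with `cor` (list of three
#'   S x S correlation matrices `step1`, `step2`, `step3`), `n` (S x S
#'   pairwise sample sizes), `Y` (list of the three P x S service
#'   matrices: standardized, environment-residualized, fully
#'   residualized), and `services`.
#' @examples
#' d <- apply_transforms(generate_dataset(preset_scenario("env_only",
#'   P = 120))$data)
#' cc <- correlation_cascade(d)
#' cc
#' @export
correlation_cascade <- function(data) {
  stopifnot(inherits(data, "plot_data"))
  E <- env_design(data)
  Y1 <- data$services
  resid_safe <- function(Y, X) {
    out <- Y
    for (j in seq_len(ncol(Y)))
      out[, j] <- tryCatch(fit_lm(Y[, j], X)$residuals, error = function(e) {
        warning("service '", colnames(Y)[j],
                "' could not be residualized (", conditionMessage(e),
                "); set to missing")
        rep(NA_real_, nrow(Y))
      })
    out
  }
  Y2 <- resid_safe(Y1, E)
  Y3 <- resid_safe(Y1, cbind(E, data$attributes))
  npair <- crossprod(!is.na(Y1))
  cors <- lapply(list(step1 = Y1, step2 = Y2, step3 = Y3), function(Y) {
    r <- suppressWarnings(stats::cor(Y, use = "pairwise.complete.obs"))
    if (any(npair < 10 & upper.tri(npair))) {
      warning("setting correlation(s) with fewer than 10 shared ",
              "observations to NA")
      r[npair < 10] <- NA_real_
      diag(r) <- 1
    }
    r
  })
  structure(list(cor = cors, n = npair,
                 Y = list(step1 = Y1, step2 = Y2, step3 = Y3),
                 services = colnames(Y1)),
            class = "es_cascade")
}

#' Mean synergy and trade-off strength per cascade step
#'
#' @param cascade an [correlation_cascade()] object.
#' @return data frame with, per step, the mean positive (synergy) and
#'   mean negative (trade-off) off-diagonal correlation and the mean
#'   absolute correlation.
#' @export
cascade_summary <- function(cascade) {
  stopifnot(inherits(cascade, "es_cascade"))
  rows <- lapply(names(cascade$cor), function(st) {
    r <- cascade$cor[[st]][upper.tri(cascade$cor[[st]])]
    r <- r[!is.na(r)]
    data.frame(step = st,
               mean_positive = if (any(r > 0)) mean(r[r > 0]) else NA_real_,
               mean_negative = if (any(r < 0)) mean(r[r < 0]) else NA_real_,
               mean_abs = mean(abs(r)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.es_cascade <- function(x, digits = 2, ...) {
  S <- length(x$services)
  cat("Correlation cascade:", S, "services,", S * (S - 1) / 2, "pairs\n")
  cat("steps: all factors -> environment removed -> environment + attributes removed\n\n")
  s <- cascade_summary(x)
  s[-1] <- lapply(s[-1], round, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Restrict a cascade's input data to a subset of services
#'
#' @param data a [plot_data] object.
#' @param keep service names to keep.
#' @return a [plot_data] with only those service columns.
#' @keywords internal
subset_services <- function(data, keep) {
  stopifnot(inherits(data, "plot_data"))
  data$services <- data$services[, keep, drop = FALSE]
  data$miss <- is.na(data$services)
  data
}
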