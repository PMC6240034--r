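#' Partition the explained variance of one service
#'
#' Decomposes the variance in an ecosystem service explained jointly by
#' the environmental factors and the forest attributes into four
#' components, by subtraction of R-squared values from three nested
#' linear models fitted on the identical complete-case rows:
#'
#' * `unique_env  = r2_full - r2_attr`
#' * `unique_attr = r2_full - r2_env`
#' * `shared      = r2_env + r2_attr - r2_full`
#' * `unexplained = 1 - r2_full`
#'
#' The four components sum to one exactly.  The unique components are
#' non-negative because the single-group models are nested in the full
#' model on the same rows; the shared component can be negative
#' (suppression), in which case a warning is raised and the value is
#' reported as computed.  Adjusted-R-squared analogues are computed the
#' same way (with `adj_unexplained = 1 - adj_r2_full`, so the identity
#' is preserved by construction), together with the AICc of the full
#' model and of the intercept-only null.
#'
#' @param data a [plot_data] object.
#' @param service service column name (or index).
#' @return a one-row data frame with columns `service`, `n`, `r2_env`,
#'   `r2_attr`, `r2_full`, `unique_env`, `unique_attr`, `shared`,
#'   `unexplained`, the `adj_*` analogues, `aicc_model`, `aicc_null`,
#'   `delta_aicc`.
#' @seealso [varpart()] for all services at once.
#' @export
partition_variance <- function(data, service) {
  stopifnot(inherits(data, "plot_data"))
  if (is.numeric(service)) service <- colnames(data$services)[service]
  if (!service %in% colnames(data$services))
    stop("unknown service: ", service)
  y <- data$services[, service]
  E <- env_design(data)
  A <- data$attributes
  rows <- !is.na(y)
  yr <- ifelse(rows, y, NA_real_)
  f_env <- fit_lm(yr, E)
  f_attr <- fit_lm(yr, A)
  f_full <- fit_lm(yr, cbind(E, A))
  stopifnot(f_env$n == f_full$n, f_attr$n == f_full$n)
  nc <- null_comparison(f_full, yr)
  comp <- function(re, ra, rf) {
    c(unique_env = rf - ra, unique_attr = rf - re,
      shared = re + ra - rf, unexplained = 1 - rf)
  }
  cr <- comp(f_env$r2, f_attr$r2, f_full$r2)
  ca <- comp(f_env$adj_r2, f_attr$adj_r2, f_full$adj_r2)
  if (cr[["shared"]] < 0)
    warning("negative shared variance (", signif(cr[["shared"]], 3),
            ") for service '", service, "'; reported as computed")
  data.frame(service = service, n = f_full$n,
             r2_env = f_env$r2, r2_attr = f_attr$r2, r2_full = f_full$r2,
             unique_env = cr[["unique_env"]], unique_attr = cr[["unique_attr"]],
             shared = cr[["shared"]], unexplained = cr[["unexplained"]],
             adj_r2_env = f_env$adj_r2, adj_r2_attr = f_attr$adj_r2,
             adj_r2_full = f_full$adj_r2,
             adj_unique_env = ca[["unique_env"]],
             adj_unique_attr = ca[["unique_attr"]],
             adj_shared = ca[["shared"]],
             adj_unexplained = ca[["unexplained"]],
             aicc_model = nc$aicc_model, aicc_null = nc$aicc_null,
             delta_aicc = nc$delta_aicc,
             stringsAsFactors = FALSE)
}

#' Variance partitioning across all services
#'
#' Applies [partition_variance()] to every service and summarises the
#' components across services as mean and range.  A service whose
#' models cannot be fitted (e.g. too few complete cases) is skipped with
#' a warning rather than failing the whole analysis.
#'
#' @param data a [plot_data] object.
#' @return object of class `es_varpart`: a data frame (one row per
#'   service) with a `summary` attribute holding the across-service mean
#'   and min/max of each component.
#' @examples
#' d <- generate_dataset(preset_scenario("paper_like", P = 100))$data
#' d <- apply_transforms(d)
#' vp <- varpart(d)
#' vp
#' @export
varpart <- function(data) {
  stopifnot(inherits(data, "plot_data"))
  rows <- lapply(colnames(data$services), function(s) {
    tryCatch(partition_variance(data, s), error = function(e) {
      warning("skipping service '", s, "': ", conditionMessage(e))
      NULL
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no service could be partitioned")
  comp_cols <- c("r2_full", "unique_env", "unique_attr", "shared",
                 "unexplained")
  summ <- t(vapply(comp_cols, function(cn)
    c(mean = mean(out[[cn]]), min = min(out[[cn]]), max = max(out[[cn]])),
    numeric(3)))
  structure(out, summary = summ, class = c("es_varpart", "data.frame"))
}

#' @export
print.es_varpart <- function(x, digits = 3, ...) {
  cat("Variance partitioning:", nrow(x), "ecosystem services\n\n")
  cols <- c("service", "n", "r2_full", "unique_env", "unique_attr",
            "shared", "unexplained")
  df <- as.data.frame(x)[, cols]
  df[-(1:2)] <- lapply(df[-(1:2)], round, digits)
  print(df, row.names = FALSE)
  s <- attr(x, "summary")
  cat("\nAcross services, mean [min-max]:\n")
  for (cn in rownames(s))
    cat(sprintf("  %-12s %3.0f%% [%.0f-%.0f%%]\n", cn,
                100 * s[cn, "mean"], 100 * s[cn, "min"], 100 * s[cn, "max"]))
  invisible(x)
}

#' @export
plot.es_varpart <- function(x, ...) {
  m <- t(as.matrix(as.data.frame(x)[, c("unique_attr", "shared",
                                        "unique_env", "unexplained")]))
  colnames(m) <- x$service
  op <- graphics::par(mar = c(8, 4, 2, 8), xpd = TRUE)
  on.exit(graphics::par(op))
  cols <- c("#1b9e77", "#7570b3", "#d95f02", "grey85")
  graphics::barplot(m, col = cols, las = 2, ylab = "proportion of variance",
                    ...)
  graphics::legend("topright", inset = c(-0.25, 0),
                   legend = c("attributes only", "shared",
                              "environment only", "unexplained"),
                   fill = cols, bty = "n", cex = 0.8)
  invisible(x)
}

#' @rdname varpart
#' @export
partition_all <- varpart
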