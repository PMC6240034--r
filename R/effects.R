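#' Residualize services and attributes on the environment
#'
#' Preparation step shared by the attribute-effect analyses: services
#' and attributes are replaced by their residuals from linear models on
#' the environmental design (so only attribute effects not shared with
#' the environment remain -- a conservative choice), and each service
#' residual column is re-standardized so effects are comparable across
#' services.
#'
#' @param data a [plot_data] object.
#' @return list with `services` (residualized, z-scored, `NA` kept) and
#'   `attributes` (residualized).
#' @export
residualize_on_env <- function(data) {
  stopifnot(inherits(data, "plot_data"))
  E <- env_design(data)
  srv <- apply(residualize(data$services, E), 2, zscore)
  attr <- residualize(data$attributes, E)
  list(services = srv, attributes = attr)
}

stack_long <- function(data, res) {
  P <- length(data$plot_id)
  S <- ncol(res$services)
  long <- data.frame(
    y = as.vector(res$services),
    plot = factor(rep(data$plot_id, S)),
    service = factor(rep(colnames(res$services), each = P)),
    res$attributes[rep(seq_len(P), S), , drop = FALSE],
    check.names = FALSE)
  long[!is.na(long$y), , drop = FALSE]
}

# Backward elimination for the stacked mixed model using lme4's modular
# interface: the random-effect structure is built once and only the
# fixed-effect columns change between refits.  Drop decisions use
# large-sample normal p-values; with thousands of stacked observations
# these agree with Satterthwaite p-values to well past the decision
# point (see the methods vignette).
backward_eliminate_lmm <- function(lf, terms, alpha) {
  Xfull <- lf$X
  fit_sub <- function(keep) {
    X <- Xfull[, c("(Intercept)", keep), drop = FALSE]
    devfun <- do.call(lme4::mkLmerDevfun,
                      list(fr = lf$fr, X = X, reTrms = lf$reTrms,
                           REML = TRUE))
    opt <- lme4::optimizeLmer(devfun, optimizer = "bobyqa")
    lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
  }
  keep <- terms
  fit <- fit_sub(keep)
  repeat {
    if (!length(keep)) break
    cc <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    z <- cc / se
    p <- 2 * stats::pnorm(-abs(z))[keep]
    if (max(p) <= alpha) break
    keep <- setdiff(keep, names(which.max(p)))
    fit <- fit_sub(keep)
  }
  list(retained = keep, fit = fit)
}

#' Net effects of forest attributes across all services
#'
#' Estimates, for each forest attribute, its average standardized effect
#' across every ecosystem service, from one linear mixed model on the
#' stacked data: services and attributes are first residualized on the
#' environment ([residualize_on_env()]), services are stacked long-form
#' (one row per plot x service, missing values dropped), and the model
#' has all attributes as fixed effects with random intercepts for
#' service identity and for plot.  Backward simplification removes the
#' least significant fixed effect until all retained effects satisfy
#' `p <= alpha`; both the full and the simplified fit are reported.
#'
#' Degrees of freedom use the Satterthwaite approximation
#' (`df_method = "satterthwaite"`, via lmerTest); `"normal"` substitutes
#' a large-sample normal approximation (`DF = Inf`), flagged in the
#' output.  Elimination decisions always use the fast large-sample
#' p-values (see the methods vignette).  Singular random-effect
#' variances are reported, not fatal.  If a grouping factor is
#' degenerate (fewer than two levels, or as many levels as
#' observations) it is dropped, and with no random effects left the
#' model reduces to OLS.
#'
#' @param data a [plot_data] object (standardized).
#' @param alpha retention threshold for the backward simplification.
#' @param df_method `"satterthwaite"` (default) or `"normal"`.
#' @return object of class `es_net_effects`: list with `table`
#'   (simplified-model coefficient table: Estimate, Std.error, DF, t, p,
#'   significance), `full_table` (same for the unsimplified model),
#'   `retained`, `varcor` (random-intercept and residual variances),
#'   `n_obs`, `df_method`, `singular`.
#' @examples
#' \donttest{
#' d <- apply_transforms(generate_dataset(preset_scenario("paper_like"))$data)
#' ne <- fit_net_effects(d)
#' ne
#' }
#' @export
fit_net_effects <- function(data, alpha = 0.05,
                            df_method = c("satterthwaite", "normal")) {
  stopifnot(inherits(data, "plot_data"))
  df_method <- match.arg(df_method)
  res <- residualize_on_env(data)
  long <- stack_long(data, res)
  terms <- colnames(res$attributes)
  re <- c("(1 | service)", "(1 | plot)")
  if (nlevels(droplevels(long$service)) < 2) re <- setdiff(re, "(1 | service)")
  if (nlevels(droplevels(long$plot)) < 2 ||
      nlevels(droplevels(long$plot)) >= nrow(long))
    re <- setdiff(re, "(1 | plot)")
  long$plot <- droplevels(long$plot)
  long$service <- droplevels(long$service)
  bt <- function(v) paste0("`", v, "`")
  if (!length(re)) {                 # degenerate: plain OLS
    f <- fit_lm(long$y, as.matrix(long[terms]))
    ct <- f$coefficients
    tab <- coef_table(ct[, 1], ct[, 2], rep(f$n - f$k + 1, nrow(ct)))
    return(structure(list(table = tab, full_table = tab,
                          retained = rownames(ct)[-1],
                          varcor = c(residual = stats::sigma(f$lm)^2),
                          n_obs = f$n, df_method = "residual",
                          singular = FALSE, fit = f$lm),
                     class = "es_net_effects"))
  }
  fml_full <- stats::as.formula(paste("y ~", paste(c(bt(terms), re),
                                                   collapse = " + ")))
  lf <- lme4::lFormula(fml_full, data = long, REML = TRUE,
                       control = lme4::lmerControl(
                         check.nobs.vs.nlev = "ignore",
                         check.nobs.vs.nRE = "ignore"))
  be <- backward_eliminate_lmm(lf, terms, alpha)
  report_fit <- function(keep) {
    fml <- stats::as.formula(paste("y ~",
      paste(c(if (length(keep)) bt(keep) else "1", re), collapse = " + ")))
    ctrl <- lme4::lmerControl(optimizer = "bobyqa")
    if (df_method == "satterthwaite") {
      fit <- suppressMessages(lmerTest::lmer(fml, data = long, REML = TRUE,
                                             control = ctrl))
      sm <- stats::coef(summary(fit))
      tab <- coef_table(sm[, "Estimate"], sm[, "Std. Error"], sm[, "df"],
                        rn = rownames(sm))
    } else {
      fit <- suppressMessages(lme4::lmer(fml, data = long, REML = TRUE,
                                         control = ctrl))
      sm <- stats::coef(summary(fit))
      tab <- coef_table(sm[, "Estimate"], sm[, "Std. Error"],
                        rep(Inf, nrow(sm)), rn = rownames(sm))
    }
    list(fit = fit, table = tab)
  }
  simp <- report_fit(be$retained)
  full <- report_fit(terms)
  vc <- as.data.frame(lme4::VarCorr(simp$fit))
  varcor <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                            vc$grp))
  structure(list(table = simp$table, full_table = full$table,
                 retained = be$retained, varcor = varcor,
                 n_obs = nrow(long), df_method = df_method,
                 singular = lme4::isSingular(simp$fit), fit = simp$fit),
            class = "es_net_effects")
}

coef_table <- function(est, se, df, rn = names(est)) {
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(Estimate = est, `Std.error` = se, DF = df, t = t, p = p,
             signif = stars(p), row.names = rn, check.names = FALSE,
             stringsAsFactors = FALSE)
}

stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
    ifelse(p <= 0.05, "*", "")))
}

#' @export
print.es_net_effects <- function(x, digits = 3, ...) {
  cat("Net effects of forest attributes across services\n")
  cat(sprintf("  stacked observations: %d; df method: %s%s\n", x$n_obs,
              x$df_method,
              if (isTRUE(x$singular)) " (singular random-effect fit)" else ""))
  cat("  random-effect variances:",
      paste(names(x$varcor), signif(x$varcor, 3), sep = " = ",
            collapse = ", "), "\n\n")
  tab <- x$table
  tab[1:5] <- lapply(tab[1:5], function(v) round(v, digits))
  print(tab)
  invisible(x)
}

#' @export
coef.es_net_effects <- function(object, ...) {
  stats::setNames(object$table$Estimate, rownames(object$table))
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starting from the full model, repeatedly takes the single-term
#' deletion or addition with the lowest AIC until no move improves,
#' recording the path.  The selected model's AIC never exceeds the full
#' model's.  Ties are resolved by `stats::step()`'s deterministic move
#' ordering (deletions listed before additions, terms in formula
#' order).
#'
#' @param y numeric response.
#' @param X numeric predictor matrix.
#' @return object of class `es_stepwise`: list with `fit` (the selected
#'   `lm`), `selected` (predictor names), `path` (the step anova table),
#'   `aic_full`, `aic_selected`.
#' @export
stepwise_aic <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  rows <- !is.na(y) & stats::complete.cases(X)
  df <- data.frame(.y = y[rows], X[rows, , drop = FALSE], check.names = FALSE)
  full <- stats::lm(.y ~ ., data = df)
  sel <- stats::step(full, scope = list(lower = .y ~ 1,
                                        upper = stats::formula(full)),
                     direction = "both", trace = 0)
  path <- sel$anova
  structure(list(fit = sel, selected = attr(stats::terms(sel),
                                            "term.labels"),
                 path = path, aic_full = stats::extractAIC(full)[2],
                 aic_selected = stats::extractAIC(sel)[2], rows = rows),
            class = "es_stepwise")
}

#' @export
print.es_stepwise <- function(x, ...) {
  cat("Stepwise AIC selection:", length(x$selected), "of",
      length(attr(stats::terms(stats::formula(paste("~",
        paste(colnames(x$fit$model)[-1], collapse = "+")))), "term.labels")),
      "terms retained\n")
  cat(sprintf("AIC: full %.2f -> selected %.2f\n", x$aic_full,
              x$aic_selected))
  if (!is.null(x$path)) print(x$path)
  invisible(x)
}

#' F-ratio backward simplification of a linear model
#'
#' Iteratively removes the term with the largest single-term-deletion
#' F-test p-value above `alpha` and refits, until every remaining term
#' is significant.  For a single-df term the F statistic equals the
#' squared t statistic of its coefficient.
#'
#' @param fit an `lm` (or the `fit` element of [stepwise_aic()]).
#' @param alpha significance threshold (default 0.05).
#' @return the simplified `lm`.
#' @export
f_simplify <- function(fit, alpha = 0.05) {
  if (inherits(fit, "es_stepwise")) fit <- fit$fit
  stopifnot(inherits(fit, "lm"))
  mf <- stats::model.frame(fit)
  resp <- names(mf)[1]
  bt <- function(v) paste0("`", gsub("`", "", v), "`")
  repeat {
    tl <- attr(stats::terms(fit), "term.labels")
    if (!length(tl)) break
    dr <- stats::drop1(fit, test = "F")
    p <- dr[["Pr(>F)"]][-1]
    names(p) <- rownames(dr)[-1]
    if (max(p) <= alpha) break
    keep <- setdiff(tl, names(which.max(p)))
    fml <- stats::reformulate(if (length(keep)) bt(keep) else "1",
                              response = bt(resp))
    fit <- stats::lm(fml, data = mf)
  }
  fit
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: reports both the rejection flags at
#' level `q` and the monotone BH-adjusted p-values.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return list with `reject` (logical), `adjusted` (numeric), `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(reject = adj <= q, adjusted = adj, q = q)
}

#' Per-service attribute effects with selection and FDR control
#'
#' For each ecosystem service (residualized on the environment and
#' standardized), selects forest attributes by bidirectional stepwise
#' AIC ([stepwise_aic()]) followed by F-ratio backward simplification
#' ([f_simplify()]).  Because model simplification entails many
#' comparisons, every attribute's p-value in the *full* (unsimplified)
#' model is also recorded, and the Benjamini-Hochberg procedure is run
#' on the pooled family of all attribute x service full-model tests
#' (12 x 14 = 168 by default; set `family = "per_service"` to adjust
#' within each service instead).  Each retained effect gets a
#' significance tier: `fdr5` if its full-model q-value passes the
#' stricter rate, `fdr25` at the looser rate, `simplified_only`
#' otherwise.  Partial-effect curves (fit and pointwise 95% CI over the
#' observed predictor range, other predictors at 0) are returned for
#' plotting.
#'
#' @param data a [plot_data] object (standardized).
#' @param q_levels two FDR levels, strict then loose (default 0.05,
#'   0.25).
#' @param alpha F-simplification threshold.
#' @param family `"pooled"` (default) or `"per_service"` BH family.
#' @return object of class `es_service_effects`: list with `effects`
#'   (data frame: service, attribute, estimate, se, t, p_simplified,
#'   p_full, q_full, tier), `full_pvalues` (attribute x service matrix),
#'   `partial` (list of per-effect curves), `models` (per-service
#'   selection records), `q_levels`.
#' @export
fit_all_services <- function(data, q_levels = c(0.05, 0.25), alpha = 0.05,
                             family = c("pooled", "per_service")) {
  stopifnot(inherits(data, "plot_data"))
  family <- match.arg(family)
  res <- residualize_on_env(data)
  svc <- colnames(res$services)
  attrs <- colnames(res$attributes)
  full_p <- matrix(NA_real_, length(attrs), length(svc),
                   dimnames = list(attrs, svc))
  models <- list(); eff_rows <- list(); partial <- list()
  for (s in svc) {
    y <- res$services[, s]
    rec <- tryCatch({
      st <- stepwise_aic(y, res$attributes)
      simp <- f_simplify(st$fit, alpha = alpha)
      fullfit <- fit_lm(y, res$attributes)
      full_p[, s] <- fullfit$coefficients[attrs, 4]
      sm <- summary(simp)$coefficients
      kept <- setdiff(rownames(sm), "(Intercept)")
      kept <- gsub("^`|`$", "", kept)
      for (a in kept) {
        arow <- paste0("`", a, "`")
        arow <- if (arow %in% rownames(sm)) arow else a
        eff_rows[[length(eff_rows) + 1L]] <- data.frame(
          service = s, attribute = a, estimate = sm[arow, 1],
          se = sm[arow, 2], t = sm[arow, 3], p_simplified = sm[arow, 4],
          p_full = full_p[a, s], stringsAsFactors = FALSE)
        partial[[paste(s, a, sep = ":")]] <-
          partial_effect(simp, a, res$attributes[, a])
      }
      list(service = s, stepwise = st, simplified = simp, full = fullfit)
    }, error = function(e) {
      warning("skipping service '", s, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) models[[s]] <- rec
  }
  effects <- if (length(eff_rows)) do.call(rbind, eff_rows) else
    data.frame(service = character(), attribute = character())
  pv <- as.vector(full_p)
  ok <- !is.na(pv)
  q_all <- rep(NA_real_, length(pv))
  if (family == "pooled") {
    q_all[ok] <- stats::p.adjust(pv[ok], method = "BH")
  } else {
    for (s in seq_along(svc)) {
      idx <- (s - 1) * length(attrs) + seq_along(attrs)
      oks <- ok[idx]
      q_all[idx][oks] <- stats::p.adjust(pv[idx][oks], method = "BH")
    }
  }
  full_q <- matrix(q_all, length(attrs), length(svc),
                   dimnames = dimnames(full_p))
  if (nrow(effects)) {
    effects$q_full <- full_q[cbind(effects$attribute, effects$service)]
    effects$tier <- ifelse(effects$q_full <= q_levels[1], "fdr5",
                    ifelse(effects$q_full <= q_levels[2], "fdr25",
                           "simplified_only"))
  }
  structure(list(effects = effects, full_pvalues = full_p,
                 full_qvalues = full_q, partial = partial, models = models,
                 q_levels = q_levels, family = family),
            class = "es_service_effects")
}

partial_effect <- function(fit, term, x_obs, level = 0.95, n_grid = 50) {
  x_obs <- x_obs[!is.na(x_obs)]
  grid <- seq(min(x_obs), max(x_obs), length.out = n_grid)
  cn <- rownames(summary(fit)$coefficients)
  tn <- if (paste0("`", term, "`") %in% cn) paste0("`", term, "`") else term
  b <- stats::coef(fit)[c("(Intercept)", tn)]
  V <- stats::vcov(fit)[c("(Intercept)", tn), c("(Intercept)", tn)]
  est <- b[1] + b[2] * grid
  se <- sqrt(V[1, 1] + grid^2 * V[2, 2] + 2 * grid * V[1, 2])
  zc <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(x = grid, fit = est, lower = est - zc * se,
             upper = est + zc * se)
}

#' @export
print.es_service_effects <- function(x, digits = 3, ...) {
  e <- x$effects
  cat("Per-service attribute effects (stepwise AIC + F simplification)\n")
  cat(sprintf("  %d retained effects across %d services\n", nrow(e),
              length(x$models)))
  if (nrow(e)) {
    cat(sprintf("  tiers: %d at FDR %.0f%%, %d more at FDR %.0f%%, %d simplified-only\n",
                sum(e$tier == "fdr5"), 100 * x$q_levels[1],
                sum(e$tier == "fdr25"), 100 * x$q_levels[2],
                sum(e$tier == "simplified_only")))
    e[c("estimate", "se", "t")] <- lapply(e[c("estimate", "se", "t")],
                                          round, digits)
    e[c("p_simplified", "p_full", "q_full")] <-
      lapply(e[c("p_simplified", "p_full", "q_full")], signif, digits)
    print(utils::head(e, 20), row.names = FALSE)
    if (nrow(e) > 20) cat("  ...", nrow(e) - 20, "more rows\n")
  }
  invisible(x)
}
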