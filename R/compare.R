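#' Two-group equality test for correlation matrices
#'
#' Tests whether the service correlation structure differs between two
#' data matrices (e.g. services before vs after a residualization step)
#' with a two-group maximum-likelihood discrepancy statistic, and
#' reports the incremental and non-centrality fit indices commonly used
#' to judge correlation-structure equivalence.
#'
#' With per-group correlation matrices R_g, pooled estimate R (the
#' sample-size weighted average rescaled to unit diagonal), and ML
#' discrepancy `F(S, Sigma) = log det Sigma - log det S +
#' tr(S Sigma^-1) - p`, the statistic is
#' `chi2 = sum_g (n_g - 1) F(R_g, R)` on `df = p(p-1)/2` degrees of
#' freedom, with Box's small-sample scaling factor applied (the raw ML
#' statistic rejects slightly too often at n in the low hundreds).  The independence baseline (diagonal target) gives
#' `chi0 = sum_g (n_g - 1)(-log det R_g)` on `df0 = p(p-1)`.  CFI, TLI
#' and McDonald's non-centrality index Mc are computed from these in the
#' standard way, with `Mc = exp(-0.5 max(chi2 - df, 0)/(N - 1))` and N
#' the total sample size.  Values of CFI/TLI above 0.95 and Mc near 0.9
#' or higher indicate negligible difference between the matrices.
#'
#' When the two groups are the raw and residualized versions of the same
#' plots the independence-of-groups assumption is only approximate; the
#' result carries a `dependent_groups` note for that use.
#'
#' @param data_before,data_after numeric matrices (plots x services)
#'   with identical column sets; `NA` allowed.
#' @param n optional length-2 vector of group sample sizes; defaults to
#'   the median pairwise-complete sample size of each matrix.
#' @return object of class `es_matrix_test`: list with `chi2`, `df`,
#'   `p_value`, `cfi`, `tli`, `mc`, `chi0`, `df0`, `n`.
#' @export
compare_matrices <- function(data_before, data_after, n = NULL) {
  Y <- list(as.matrix(data_before), as.matrix(data_after))
  p <- ncol(Y[[1]])
  if (ncol(Y[[2]]) != p) stop("matrices must have the same services")
  R <- lapply(Y, function(y)
    suppressWarnings(stats::cor(y, use = "pairwise.complete.obs")))
  if (is.null(n))
    n <- vapply(Y, function(y)
      stats::median(crossprod(!is.na(y))[upper.tri(diag(p))]), numeric(1))
  for (g in 1:2) {
    ev <- eigen(R[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10)
      stop("correlation matrix of group ", g, " is singular ",
           "(smallest eigenvalue ", format(min(ev)), "); near-collinear ",
           "services must be removed")
  }
  Rp <- stats::cov2cor(((n[1] - 1) * R[[1]] + (n[2] - 1) * R[[2]]) /
                         (sum(n) - 2))
  fml <- function(S, Sig) {
    as.numeric(determinant(Sig)$modulus - determinant(S)$modulus +
                 sum(diag(S %*% solve(Sig))) - p)
  }
  chi2 <- sum((n - 1) * vapply(R, fml, numeric(1), Sig = Rp))
  # Box small-sample scaling: the raw ML discrepancy statistic is mildly
  # anti-conservative at n in the low hundreds
  G <- 2
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (G - 1)) *
    (sum(1 / (n - 1)) - 1 / sum(n - 1))
  chi2 <- max(chi2 * (1 - c1), 0)
  df <- p * (p - 1) / 2
  chi0 <- sum((n - 1) * vapply(R, function(S)
    -as.numeric(determinant(S)$modulus), numeric(1)))
  df0 <- p * (p - 1)
  cfi <- 1 - max(chi2 - df, 0) / max(chi0 - df0, chi2 - df, 0)
  if (!is.finite(cfi)) cfi <- 1
  tli <- if (chi0 / df0 > 1) ((chi0 / df0) - (chi2 / df)) / ((chi0 / df0) - 1)
         else NA_real_
  mc <- exp(-0.5 * max(chi2 - df, 0) / (sum(n) - 1))
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 cfi = min(cfi, 1), tli = tli, mc = mc,
                 chi0 = chi0, df0 = df0, n = n,
                 dependent_groups = TRUE),
            class = "es_matrix_test")
}

#' @export
print.es_matrix_test <- function(x, ...) {
  cat(sprintf("Correlation-matrix equality test (n = %s)\n",
              paste(round(x$n), collapse = ", ")))
  cat(sprintf("  chi2 = %.3f on df = %d, p = %.4g\n", x$chi2, x$df,
              x$p_value))
  cat(sprintf("  CFI = %.3f, TLI = %.3f, Mc = %.3f\n", x$cfi, x$tli, x$mc))
  cat("  note: groups treated as independent even when derived from the",
      "same plots\n")
  invisible(x)
}

#' Zou confidence interval for the difference of two dependent
#' correlations
#'
#' Confidence interval for `r12 - r34`, two correlations with no shared
#' variable, measured on the same sample (dependent groups).  Individual
#' Fisher-z confidence limits for each correlation are back-transformed
#' and combined with a dependence correction
#' `c = cov(r12_hat, r34_hat) / ((1 - r12^2)(1 - r34^2))`, where the
#' covariance term is the Pearson-Filon expression evaluated on the
#' 4 x 4 correlation matrix of the underlying variables.  With `c = 0`
#' the interval reduces exactly to the independent-groups form.  If the
#' interval excludes zero the two correlations differ at level `alpha`.
#'
#' @param r12 correlation between variables 1 and 2.
#' @param r34 correlation between variables 3 and 4.
#' @param dependence 4 x 4 correlation matrix of the four variables in
#'   order (1, 2, 3, 4); entries `[1,2]` and `[3,4]` should equal `r12`
#'   and `r34`.  Must be positive semi-definite.
#' @param n sample size (shared by both correlations); must exceed 3.
#' @param alpha significance level (default 0.05).
#' @return length-2 vector `c(lower, upper)` with attributes `estimate`
#'   (`r12 - r34`), `c` (the dependence correction) and `alpha`.
#' @references Zou, G. Y. (2007) Toward using confidence intervals to
#'   compare correlations. Psychological Methods 12, 399-413.
#' @export
zou_interval <- function(r12, r34, dependence, n, alpha = 0.05) {
  if (n <= 3) stop("n must exceed 3")
  if (abs(r12) >= 1 || abs(r34) >= 1)
    stop("correlations must lie strictly inside (-1, 1)")
  M <- as.matrix(dependence)
  if (!all(dim(M) == c(4, 4))) stop("dependence must be a 4 x 4 matrix")
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("dependence matrix is not positive semi-definite")
  r13 <- M[1, 3]; r14 <- M[1, 4]; r23 <- M[2, 3]; r24 <- M[2, 4]
  cov_term <- 0.5 * r12 * r34 * (r13^2 + r14^2 + r23^2 + r24^2) +
    r13 * r24 + r14 * r23 -
    (r12 * r13 * r14 + r12 * r23 * r24 + r13 * r23 * r34 +
       r14 * r24 * r34)
  cc <- cov_term / ((1 - r12^2) * (1 - r34^2))
  cc <- max(min(cc, 1), -1)
  zc <- stats::qnorm(1 - alpha / 2)
  ci_one <- function(r) tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
  ci1 <- ci_one(r12); l1 <- ci1[1]; u1 <- ci1[2]
  ci2 <- ci_one(r34); l2 <- ci2[1]; u2 <- ci2[2]
  d <- r12 - r34
  lower <- d - sqrt((r12 - l1)^2 + (u2 - r34)^2 -
                      2 * cc * (r12 - l1) * (u2 - r34))
  upper <- d + sqrt((u1 - r12)^2 + (r34 - l2)^2 -
                      2 * cc * (u1 - r12) * (r34 - l2))
  structure(c(lower = lower, upper = upper), estimate = d, c = cc,
            alpha = alpha)
}

#' Pairwise tests for change in service correlations along the cascade
#'
#' For every pair of services, compares the Pearson correlation between
#' the three cascade steps (all factors vs environment removed,
#' environment removed vs attributes also removed, and all factors vs
#' everything removed) with a [zou_interval()] for each difference.  The
#' four realized variables entering each comparison (both services at
#' both steps) are taken on their shared complete cases, on which both
#' correlations and the empirical 4 x 4 dependence matrix are computed.
#'
#' @param cascade an [correlation_cascade()] object.
#' @param alpha significance level for the intervals.
#' @param min_n pairs with fewer shared complete cases are skipped
#'   with a reason (default 10).
#' @return object of class `es_pair_tests`: data frame with one row per
#'   pair and comparison (`step1_vs_step2`, `step2_vs_step3`,
#'   `step1_vs_step3`), columns `r_before`, `r_after`, `lower`, `upper`,
#'   `significant`, `n`.  Skipped pairs are recorded in the `skipped`
#'   attribute.
#' @export
compare_pairs <- function(cascade, alpha = 0.05, min_n = 10) {
  stopifnot(inherits(cascade, "es_cascade"))
  svc <- cascade$services
  S <- length(svc)
  steps <- c("step1", "step2", "step3")
  cmps <- list(step1_vs_step2 = c(1, 2), step2_vs_step3 = c(2, 3),
               step1_vs_step3 = c(1, 3))
  rows <- list(); skipped <- list()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    for (cname in names(cmps)) {
      ab <- cmps[[cname]]
      xi_a <- cascade$Y[[ab[1]]][, i]; xj_a <- cascade$Y[[ab[1]]][, j]
      xi_b <- cascade$Y[[ab[2]]][, i]; xj_b <- cascade$Y[[ab[2]]][, j]
      ok <- !is.na(xi_a) & !is.na(xj_a) & !is.na(xi_b) & !is.na(xj_b)
      nn <- sum(ok)
      if (nn < min_n) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          service_i = svc[i], service_j = svc[j], comparison = cname,
          reason = paste0("only ", nn, " shared complete cases"))
        next
      }
      V <- cbind(xi_a, xj_a, xi_b, xj_b)[ok, ]
      M <- stats::cor(V)
      ci <- tryCatch(
        zou_interval(M[1, 2], M[3, 4], M, nn, alpha = alpha),
        error = function(e) NULL)
      if (is.null(ci)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          service_i = svc[i], service_j = svc[j], comparison = cname,
          reason = "degenerate dependence matrix")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        service_i = svc[i], service_j = svc[j], comparison = cname,
        r_before = M[1, 2], r_after = M[3, 4],
        lower = ci[["lower"]], upper = ci[["upper"]],
        significant = ci[["lower"]] > 0 || ci[["upper"]] < 0,
        n = nn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha,
            skipped = if (length(skipped)) do.call(rbind, skipped),
            class = c("es_pair_tests", "data.frame"))
}

#' @export
print.es_pair_tests <- function(x, ...) {
  cat("Pairwise correlation-change tests (Zou CIs, alpha =",
      attr(x, "alpha"), ")\n")
  tab <- table(x$comparison, x$significant)
  print(tab)
  sk <- attr(x, "skipped")
  if (!is.null(sk)) cat(nrow(sk), "comparison(s) skipped\n")
  invisible(x)
}

#' Classify service pairs by the driver of their correlation
#'
#' Combines the cascade correlations and the pairwise Zou tests into
#' per-pair driver flags:
#'
#' * `main`: `|r|` at step 1 at or above `threshold` (default 0.1);
#' * `consistent` (intrinsic candidate): `|r| >= threshold` with the
#'   same sign in all three matrices;
#' * `env_driven`: step 1 vs step 2 significantly different;
#' * `attr_driven`: step 2 vs step 3 significantly different;
#' * `combined`: step 1 vs step 3 significant while neither single-step
#'   change is.
#'
#' Flags are not mutually exclusive and all applicable ones are
#' reported.  A synergy is a positive step-1 correlation, a trade-off a
#' negative one.
#'
#' @param tests an [compare_pairs()] result.
#' @param cascade the [correlation_cascade()] the tests came from.
#' @param threshold main-correlation magnitude threshold (default 0.1).
#' @return object of class `es_classification`: data frame with one row
#'   per pair (`r_step1..3`, `sign`, and the logical flags), with a
#'   `counts` attribute.
#' @export
classify_pairs <- function(tests, cascade, threshold = 0.1) {
  stopifnot(inherits(tests, "es_pair_tests"), inherits(cascade, "es_cascade"))
  svc <- cascade$services
  S <- length(svc)
  ij <- which(upper.tri(diag(S)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  sig <- function(i, j, cmp) {
    row <- tests$service_i == svc[i] & tests$service_j == svc[j] &
      tests$comparison == cmp
    if (!any(row)) NA else tests$significant[row]
  }
  rows <- lapply(seq_len(nrow(ij)), function(k) {
    i <- ij[k, 1]; j <- ij[k, 2]
    r1 <- cascade$cor$step1[i, j]; r2 <- cascade$cor$step2[i, j]
    r3 <- cascade$cor$step3[i, j]
    s12 <- sig(i, j, "step1_vs_step2"); s23 <- sig(i, j, "step2_vs_step3")
    s13 <- sig(i, j, "step1_vs_step3")
    data.frame(service_i = svc[i], service_j = svc[j],
               r_step1 = r1, r_step2 = r2, r_step3 = r3,
               sign = ifelse(r1 > 0, "synergy", "trade-off"),
               main = abs(r1) >= threshold,
               consistent = abs(r1) >= threshold & abs(r2) >= threshold &
                 abs(r3) >= threshold & sign(r1) == sign(r2) &
                 sign(r2) == sign(r3),
               env_driven = isTRUE(s12),
               attr_driven = isTRUE(s23),
               combined = isTRUE(s13) & !isTRUE(s12) & !isTRUE(s23),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  counts <- c(pairs = nrow(out), main = sum(out$main),
              consistent = sum(out$consistent),
              env_driven = sum(out$env_driven),
              attr_driven = sum(out$attr_driven),
              combined = sum(out$combined))
  structure(out, counts = counts, threshold = threshold,
            class = c("es_classification", "data.frame"))
}

#' @export
print.es_classification <- function(x, ...) {
  cn <- attr(x, "counts")
  cat("Driver classification of service pairs (|r| threshold ",
      attr(x, "threshold"), ")\n", sep = "")
  cat(sprintf("  %d pairs: %d main, %d consistent (intrinsic candidates),\n",
              cn["pairs"], cn["main"], cn["consistent"]))
  cat(sprintf("  %d environment-driven, %d attribute-driven, %d combined\n",
              cn["env_driven"], cn["attr_driven"], cn["combined"]))
  invisible(x)
}

#' Sensitivity of the attribute effect to excluding service groups
#'
#' Drops one category of services at a time (e.g. all supporting
#' services), recomputes the cascade on the remaining services and
#' re-runs the step 2 vs step 3 matrix comparison -- the test of whether
#' forest attributes affect the correlation structure beyond the
#' environment.  As a reference, the same number of randomly chosen
#' services is dropped `n_random` times per category and the observed
#' chi-square is located within that null distribution.
#'
#' @param data a (standardized) [plot_data] object.
#' @param groups named character vector mapping every service to a
#'   category; see [service_categories()].
#' @param n_random random exclusion draws per category (default 100).
#' @param seed integer seed for the random draws (required, logged).
#' @return object of class `es_exclusion`: list with `observed` (data
#'   frame per category: chi2, p, CFI, TLI, Mc, quantile of the observed
#'   chi2 within the random distribution), `random` (long data frame of
#'   the random-draw statistics), `baseline` (the no-exclusion matrix
#'   test) and `seed`.
#' @export
group_exclusion_test <- function(data, groups, n_random = 100, seed) {
  stopifnot(inherits(data, "plot_data"))
  svc <- colnames(data$services)
  if (!all(svc %in% names(groups)))
    stop("every service needs a category; missing: ",
         paste(setdiff(svc, names(groups)), collapse = ", "))
  groups <- groups[svc]
  if (missing(seed)) stop("seed is required for the random exclusions")
  seed <- as.integer(seed)   # force before the RNG state is saved
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  step23 <- function(keep) {
    cc <- correlation_cascade(subset_services(data, keep))
    compare_matrices(cc$Y$step2, cc$Y$step3)
  }
  baseline <- step23(svc)
  cats <- unique(groups)
  obs <- list(); rnd <- list()
  for (ct in cats) {
    excl <- svc[groups == ct]
    if (length(excl) >= length(svc))
      stop("category '", ct, "' covers all services")
    keep <- setdiff(svc, excl)
    m <- step23(keep)
    draws <- vapply(seq_len(n_random), function(b) {
      keep_b <- setdiff(svc, sample(svc, length(excl)))
      step23(keep_b)$chi2
    }, numeric(1))
    obs[[ct]] <- data.frame(category = ct, n_excluded = length(excl),
                            chi2 = m$chi2, df = m$df, p_value = m$p_value,
                            cfi = m$cfi, tli = m$tli, mc = m$mc,
                            random_quantile = mean(draws <= m$chi2),
                            stringsAsFactors = FALSE)
    rnd[[ct]] <- data.frame(category = ct, draw = seq_len(n_random),
                            chi2 = draws, stringsAsFactors = FALSE)
  }
  structure(list(observed = do.call(rbind, obs), random = do.call(rbind, rnd),
                 baseline = baseline, seed = seed, n_random = n_random),
            class = "es_exclusion")
}

#' @export
print.es_exclusion <- function(x, digits = 3, ...) {
  cat("Group-exclusion sensitivity (step 2 vs step 3 comparison;",
      x$n_random, "random draws per category, seed", x$seed, ")\n")
  cat(sprintf("baseline (all services): chi2 = %.2f, p = %.4g\n",
              x$baseline$chi2, x$baseline$p_value))
  df <- x$observed
  df[-(1:2)] <- lapply(df[-(1:2)], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
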