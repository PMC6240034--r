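test_that("BH step-up matches its hand-computed and brute-force oracles", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 6))$reject, rep(FALSE, 6))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    res <- bh_fdr(p, q)
    expect_identical(res$reject, bh_brute(p, q))
    expect_true(all(res$adjusted >= p - 1e-15))
    expect_true(all(diff(res$adjusted[order(p)]) >= -1e-15))
  }
})

test_that("stepwise selection keeps strong predictors and never worsens
           the full-model AIC", {
  set.seed(2)
  found <- replicate(60, {
    n <- 150
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("x", 1:8)))
    y <- drop(X[, 1:2] %*% c(0.8, 0.6)) + rnorm(n)
    st <- stepwise_aic(y, X)
    expect_lte(st$aic_selected, st$aic_full + 1e-9)
    all(c("x1", "x2") %in% st$selected)
  })
  expect_gte(mean(found), 0.95)
  # pure noise: still never worse than the full model
  noise_ok <- replicate(20, {
    X <- matrix(rnorm(50 * 6), 50, 6)
    st <- stepwise_aic(rnorm(50), X)
    st$aic_selected <= st$aic_full + 1e-9
  })
  expect_true(all(noise_ok))
})

test_that("stepwise records a non-increasing AIC path", {
  set.seed(3)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- drop(X %*% c(1, 0.5, rep(0, 4))) + rnorm(120)
  st <- stepwise_aic(y, X)
  expect_true(all(diff(st$path$AIC) <= 1e-9))
})

test_that("F simplification drops null terms and matches the t-square
           identity", {
  set.seed(4)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  dropped <- replicate(40, {
    y <- drop(X[, 1] * 0.9) + rnorm(n)
    fit <- lm(y ~ ., data = data.frame(y = y, X))
    simp <- f_simplify(fit)
    !"x3" %in% attr(terms(simp), "term.labels")
  })
  expect_gte(mean(dropped), 0.9)
  y <- drop(X %*% c(0.9, 0.8, 0.7, 0.6, 0.5)) + rnorm(n)
  fit <- lm(y ~ ., data = data.frame(y = y, X))
  # all terms significant: unchanged
  expect_identical(formula(f_simplify(fit)), formula(fit))
  # single-df deletion F equals squared t
  dr <- drop1(fit, test = "F")
  tt <- summary(fit)$coefficients
  expect_equal(dr["x2", "F value"], tt["x2", "t value"]^2,
               tolerance = 1e-8)
})

test_that("the stacked mixed model recovers a planted uniform net
           effect", {
  Bas <- matrix(0, 12, 14)
  Bas[5, ] <- 0.08                       # vertical heterogeneity
  cfg <- synth_config(P = 150, B_attr_srv = Bas)
  set.seed(5)
  res <- replicate(25, {
    d <- std_data(cfg, seed = sample.int(1e6, 1))
    ne <- suppressWarnings(fit_net_effects(d))
    tab <- ne$table
    if (!"vertical_het" %in% rownames(tab)) return(c(FALSE, FALSE))
    c(TRUE, abs(tab["vertical_het", "Estimate"] - 0.08) <=
        2 * tab["vertical_het", "Std.error"])
  })
  expect_gte(mean(res[1, ]), 0.9)        # retained
  expect_gte(mean(res[2, ]), 0.9)        # and unbiased within 2 SE
})

test_that("with a single service and no random variance the mixed model
           reduces to OLS", {
  cfg <- synth_config(P = 80, S = 1, A = 4)
  d <- std_data(cfg, seed = 6)
  ne <- fit_net_effects(d)
  res <- residualize_on_env(d)
  ols <- fit_lm(res$services[, 1], res$attributes)
  expect_equal(ne$table[-1, "Estimate"],
               unname(ols$coefficients[-1, 1]), tolerance = 1e-6)
})

test_that("net-effect |t| equals |estimate/SE| and p-values are proper", {
  d <- std_data(preset_scenario("paper_like"), seed = 7)
  ne <- suppressWarnings(fit_net_effects(d))
  for (tab in list(ne$table, ne$full_table)) {
    expect_equal(abs(tab$t), abs(tab$Estimate / tab$`Std.error`),
                 tolerance = 1e-8)
    expect_true(all(tab$p >= 0 & tab$p <= 1))
  }
  expect_true(all(ne$retained %in% colnames(d$attributes)))
})

test_that("per-service effects report nested significance tiers", {
  d <- std_data(preset_scenario("paper_like"), seed = 8)
  fx <- suppressWarnings(fit_all_services(d))
  e <- fx$effects
  expect_true(all(table(e$service) <= 12))
  expect_true(all(e$q_full >= e$p_full - 1e-15))
  expect_true(all(e$tier[e$q_full <= 0.05] == "fdr5"))
  expect_true(all(e$tier[e$q_full > 0.05 & e$q_full <= 0.25] == "fdr25"))
  expect_equal(dim(fx$full_pvalues), c(12, 14))
  # partial-effect curves bracket their fit
  pc <- fx$partial[[1]]
  expect_true(all(pc$lower <= pc$fit & pc$fit <= pc$upper))
})

test_that("strong per-service effects are recovered with the right
           sign", {
  cfg <- preset_scenario("paper_like")
  truthB <- cfg$B_attr_srv
  set.seed(9)
  rates <- replicate(15, {
    d <- std_data(cfg, seed = sample.int(1e6, 1))
    fx <- suppressWarnings(fit_all_services(d))
    e <- fx$effects
    hit <- 0; tot <- 0
    for (a in rownames(truthB)) for (s in colnames(truthB)) {
      b <- truthB[a, s]
      if (abs(b) < 0.3) next              # standardized magnitude >= 0.25
      tot <- tot + 1
      row <- e[e$service == s & e$attribute == a, ]
      hit <- hit + (nrow(row) == 1 && sign(row$estimate) == sign(b))
    }
    hit / tot
  })
  expect_gte(mean(rates), 0.9)
})

test_that("a null dataset yields almost no FDR-significant effects", {
  cfg <- preset_scenario("null")
  set.seed(10)
  fr <- replicate(12, {
    d <- std_data(cfg, seed = sample.int(1e6, 1))
    fx <- suppressWarnings(fit_all_services(d))
    mean(fx$full_qvalues <= 0.05, na.rm = TRUE)
  })
  expect_lte(mean(fr), 0.05 + 2 * sd(fr) / sqrt(length(fr)) + 0.01)
})
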