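test_that("comparing a matrix with itself is a perfect fit", {
  set.seed(1)
  Y <- mvn_draw(150, diag(5) * 0.5 + 0.5)
  m <- compare_matrices(Y, Y)
  expect_equal(m$chi2, 0, tolerance = 1e-10)
  expect_equal(m$cfi, 1)
  expect_equal(m$mc, 1)
  expect_equal(m$df, 10)
})

test_that("the matrix test rejects strong differences and flags them as
           poor fit", {
  set.seed(2)
  R1 <- diag(5); R1[1, 2] <- R1[2, 1] <- 0.1
  R2 <- diag(5); R2[1, 2] <- R2[2, 1] <- 0.5
  res <- replicate(150, {
    m <- compare_matrices(mvn_draw(150, R1), mvn_draw(150, R2))
    c(rej = m$p_value < 0.05, poor = m$cfi < 0.95 && m$tli < 0.95)
  })
  expect_gte(mean(res["rej", ]), 0.7)
  expect_gte(mean(res["poor", ]), 0.8)
})

test_that("near-singular service sets are refused by name", {
  set.seed(3)
  Y <- mvn_draw(100, diag(3))
  Y2 <- cbind(Y, Y[, 1] + rnorm(100, sd = 1e-9))
  expect_error(compare_matrices(Y2, Y2), "eigenvalue")
})

test_that("Zou interval reduces to the independent form when c = 0", {
  dep <- diag(4)
  dep[1, 2] <- dep[2, 1] <- 0.42
  dep[3, 4] <- dep[4, 3] <- -0.17
  ci <- zou_interval(0.42, -0.17, dep, n = 150)
  expect_equal(attr(ci, "c"), 0)
  expect_equal(as.numeric(ci),
               as.numeric(zou_independent(0.42, -0.17, 150, 150)),
               tolerance = 1e-12)
})

test_that("equal correlations under exchangeable dependence give a
           symmetric interval", {
  M <- diag(4)
  M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- 0.3
  M[1, 3] <- M[3, 1] <- M[2, 4] <- M[4, 2] <- 0.5
  M[1, 4] <- M[4, 1] <- M[2, 3] <- M[3, 2] <- 0.5
  ci <- zou_interval(0.3, 0.3, M, n = 100)
  expect_equal(ci[["lower"]], -ci[["upper"]], tolerance = 1e-12)
  expect_equal(attr(ci, "estimate"), 0)
})

test_that("degenerate Zou inputs are rejected", {
  M <- diag(4)
  M[1, 3] <- M[3, 1] <- 2     # impossible correlation
  expect_error(zou_interval(0.2, 0.1, M, 100), "positive semi-definite")
  expect_error(zou_interval(0.2, 0.1, diag(4), 3), "exceed 3")
  expect_error(zou_interval(1, 0.1, diag(4), 50), "inside")
})

test_that("pairwise tests are strongly conservative, never liberal,
           under the null cascade", {
  set.seed(4)
  tot <- 0; sig <- 0
  cfg <- preset_scenario("null")
  for (r in 1:4) {
    d <- std_data(cfg, seed = sample.int(1e6, 1))
    pt <- suppressWarnings(compare_pairs(correlation_cascade(d)))
    tot <- tot + nrow(pt); sig <- sig + sum(pt$significant)
  }
  expect_lt(sig / tot, 0.065)
})

test_that("planted drivers are flagged by the right comparison", {
  set.seed(5)
  cfg_env <- preset_scenario("env_only")
  cfg_att <- preset_scenario("attr_only")
  hits <- replicate(25, {
    de <- std_data(cfg_env, seed = sample.int(1e6, 1))
    pe <- suppressWarnings(compare_pairs(correlation_cascade(de)))
    da <- std_data(cfg_att, seed = sample.int(1e6, 1))
    pa <- suppressWarnings(compare_pairs(correlation_cascade(da)))
    row_e <- pe$comparison == "step1_vs_step2" &
      pe$service_i == "root_decomp" & pe$service_j == "dung_removal"
    row_a <- pa$comparison == "step2_vs_step3" &
      pa$service_i == "root_decomp" & pa$service_j == "dung_removal"
    c(env = pe$significant[row_e], att = pa$significant[row_a])
  })
  expect_gte(mean(hits["env", ]), 0.9)
  expect_gte(mean(hits["att", ]), 0.9)
})

test_that("classification flags follow their definitions", {
  d <- std_data(preset_scenario("paper_like"), seed = 6)
  cc <- correlation_cascade(d)
  pt <- suppressWarnings(compare_pairs(cc))
  cl <- classify_pairs(pt, cc)
  df <- as.data.frame(cl)
  # main flag is a pure threshold rule
  expect_identical(df$main, abs(df$r_step1) >= 0.1)
  weak <- df[abs(df$r_step1) < 0.1, ]
  expect_false(any(weak$main))
  # consistent implies sign stability above threshold at every step
  for (k in which(df$consistent)) {
    expect_true(all(abs(unlist(df[k, c("r_step1", "r_step2", "r_step3")]))
                    >= 0.1))
    expect_equal(length(unique(sign(unlist(
      df[k, c("r_step1", "r_step2", "r_step3")])))), 1L)
  }
  # combined excludes single-step significance by definition
  pt_df <- as.data.frame(pt)
  for (k in which(df$combined)) {
    sub <- pt_df[pt_df$service_i == df$service_i[k] &
                   pt_df$service_j == df$service_j[k], ]
    expect_false(any(sub$significant[sub$comparison != "step1_vs_step3"]))
  }
  cn <- attr(cl, "counts")
  expect_equal(cn[["pairs"]], 91)
})

test_that("group exclusion reproduces the baseline and its shape", {
  d <- std_data(preset_scenario("paper_like", P = 80), seed = 7)
  grp <- service_categories()
  ex <- suppressWarnings(group_exclusion_test(d, grp, n_random = 8,
                                              seed = 42))
  cc <- correlation_cascade(d)
  base <- compare_matrices(cc$Y$step2, cc$Y$step3)
  expect_equal(ex$baseline$chi2, base$chi2, tolerance = 1e-10)
  expect_equal(nrow(ex$observed), 4)
  expect_equal(table(ex$random$category)[["cultural"]], 8L)
  expect_error(group_exclusion_test(d, setNames(rep("all", 14),
                                                names(grp)), 5, seed = 1),
               "covers all services")
  expect_error(group_exclusion_test(d, grp[1:3], 5, seed = 1),
               "category")
  # same seed, same draws
  ex2 <- suppressWarnings(group_exclusion_test(d, grp, n_random = 8,
                                               seed = 42))
  expect_equal(ex$random$chi2, ex2$random$chi2)
})

test_that("excluding the group that carries the attribute signal stands
           out against random exclusions", {
  Bes <- matrix(0, 5, 10); Bas <- matrix(0, 12, 10)
  Bes[3, 1:2] <- Bes[4, 3:4] <- 0.9        # env pairs among supporting
  Bas[1, 6:7] <- Bas[2, 8:9] <- 0.9        # attr pairs among the rest
  cfg <- synth_config(P = 150, S = 10, B_env_srv = Bes, B_attr_srv = Bas,
                      srv_names = paste0("s", 1:10))
  grp <- setNames(rep(c("supporting", "other"), each = 5),
                  paste0("s", 1:10))
  set.seed(8)
  hi <- replicate(12, {
    d <- std_data(cfg, seed = sample.int(1e6, 1))
    ex <- suppressWarnings(group_exclusion_test(d, grp, n_random = 30,
                                                seed = sample.int(1e6, 1)))
    ex$observed$random_quantile[ex$observed$category == "supporting"] >= 0.9
  })
  expect_gte(mean(hi), 0.8)
})
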