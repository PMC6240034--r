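test_that("identical seeds reproduce the dataset bit for bit", {
  cfg <- preset_scenario("paper_like")
  a <- generate_dataset(cfg, seed = 7)
  b <- generate_dataset(cfg, seed = 7)
  expect_identical(a$data, b$data)
  c_ <- generate_dataset(cfg, seed = 8)
  expect_false(identical(a$data$services, c_$data$services))
  # ground truth depends on the config only
  expect_identical(a$truth, c_$truth)
})

test_that("the generator does not disturb the caller's RNG stream", {
  cfg <- random_config(5)
  set.seed(123)
  x1 <- runif(1)
  g1 <- generate_dataset(cfg, seed = 99)
  x2 <- runif(1)
  set.seed(123)
  y1 <- runif(1)
  y2 <- runif(1)
  expect_identical(c(x1, x2), c(y1, y2))
  # and a seed drawn lazily from the caller's stream still varies
  set.seed(5)
  s1 <- generate_dataset(cfg, seed = sample.int(1e6, 1))
  s2 <- generate_dataset(cfg, seed = sample.int(1e6, 1))
  expect_false(identical(s1$data$services, s2$data$services))
})

test_that("uncoupled services are uncorrelated at large P", {
  cfg <- preset_scenario("null", P = 10000)
  d <- generate_dataset(cfg, seed = 1)$data
  r <- cor(d$services)
  expect_lt(max(abs(r[upper.tri(r)])), 0.045)
})

test_that("planted couplings reach their closed-form correlations", {
  # single intrinsic pair, rho = 0.5, untouched by residualization
  Sig <- diag(4)
  Sig[1, 2] <- Sig[2, 1] <- 0.5
  cfg <- synth_config(P = 10000, S = 4, A = 2, Sigma_res = Sig)
  d <- apply_transforms(generate_dataset(cfg, seed = 2)$data)
  cc <- correlation_cascade(d)
  expect_equal(cc$cor$step1[1, 2], 0.5, tolerance = 0.03)
  steps <- sapply(cc$cor, function(m) m[1, 2])
  expect_lt(max(steps) - min(steps), 0.05)
  # shared attribute with unit coefficients: cov = 1, var = 2, rho = 1/2
  Bas <- matrix(0, 2, 4)
  Bas[1, 1:2] <- 1
  cfg2 <- synth_config(P = 10000, S = 4, A = 2, B_attr_srv = Bas)
  d2 <- generate_dataset(cfg2, seed = 3)$data
  expect_equal(cor(d2$services[, 1], d2$services[, 2]), 0.5,
               tolerance = 0.03)
})

test_that("analytic population covariance matches sample moments", {
  for (cfg in list(preset_scenario("paper_like", P = 10000),
                   random_config(17, P = 10000, S = 4, A = 5))) {
    cfg$missing_rate <- 0
    d <- generate_dataset(cfg, seed = 4)$data
    pop <- population_service_cov(cfg)
    expect_lt(max(abs(cov(d$services) - pop$step1)), 0.05 *
                max(1, max(abs(pop$step1))))
  }
})

test_that("presets encode their documented structure", {
  n0 <- preset_scenario("null")
  expect_true(all(n0$B_env_srv == 0) && all(n0$B_attr_srv == 0) &&
                all(n0$B_env_attr == 0))
  expect_equal(unname(n0$Sigma_res), diag(14))
  intr <- preset_scenario("intrinsic")
  off <- intr$Sigma_res[upper.tri(intr$Sigma_res)]
  expect_equal(sum(off > 0), 4)   # four planted synergies
  expect_equal(sum(off < 0), 4)   # four planted trade-offs
  pl <- ground_truth(preset_scenario("paper_like"))
  expect_true(all(c("none", "intrinsic", "environment", "attribute",
                    "combined") %in% pl$pairs$class))
  expect_error(preset_scenario("unheard_of"), "arg")
})

test_that("configuration invariants are enforced", {
  Sig <- diag(3)
  Sig[1, 2] <- Sig[2, 1] <- 1.2      # not positive-definite
  expect_error(synth_config(S = 3, Sigma_res = Sig), "positive-definite")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(B_env_srv = matrix(0, 2, 2)), "must be")
})

test_that("ground-truth flags follow the structural sharing rule", {
  # services 1,2 share an env driver; 2,3 share an attribute; 1,3 nothing
  Bes <- matrix(0, 4, 3)
  Bes[3, 1:2] <- 0.5
  Bas <- matrix(0, 2, 3)
  Bas[1, 2:3] <- 0.5
  cfg <- synth_config(K = 2, S = 3, A = 2, B_env_srv = Bes,
                      B_attr_srv = Bas)
  tr <- ground_truth(cfg)$pairs
  get <- function(i, j) tr[tr$service_i == cfg$srv_names[i] &
                             tr$service_j == cfg$srv_names[j], ]
  expect_equal(get(1, 2)$class, "environment")
  expect_equal(get(2, 3)$class, "attribute")
  expect_equal(get(1, 3)$class, "none")
  # an env-driven attribute shared by two services flags both mechanisms
  Bea <- matrix(0, 4, 2)
  Bea[4, 1] <- 0.5
  cfg2 <- synth_config(K = 2, S = 3, A = 2, B_attr_srv = Bas,
                       B_env_attr = Bea)
  tr2 <- ground_truth(cfg2)$pairs
  both <- tr2[tr2$service_i == cfg2$srv_names[2] &
                tr2$service_j == cfg2$srv_names[3], ]
  expect_true(both$environment && both$attribute)
  expect_equal(both$class, "combined")
})
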