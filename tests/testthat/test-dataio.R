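test_that("a generated table reloads to the documented shape", {
  sim <- generate_dataset(preset_scenario("paper_like"), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(sim$data, f)
  d <- load_plot_table(f, plot_schema(sim$data))
  expect_equal(unname(dim(d)), c(150L, 5L, 12L, 14L))
  expect_equal(nlevels(d$region), 3L)
})

test_that("write/load round trip preserves values to 1e-12", {
  sim <- generate_dataset(preset_scenario("paper_like"), seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_plot_table(sim$data, f)
  d <- load_plot_table(f, plot_schema(sim$data))
  for (b in c("env", "attributes", "services"))
    expect_equal(d[[b]], sim$data[[b]], tolerance = 1e-12)
  expect_identical(d$plot_id, sim$data$plot_id)
  expect_identical(as.character(d$region), as.character(sim$data$region))
})

test_that("loading rejects bad tables and schemas", {
  sim <- generate_dataset(random_config(1), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plot_table(sim$data, f)
  sch <- plot_schema(sim$data)
  expect_error(load_plot_table(f, sch[c("id", "region", "env")]),
               "missing required role")
  expect_error(load_plot_table("no/such/file.csv", sch), "not found")
  # duplicated plot id
  tab <- read.csv(f, check.names = FALSE)
  tab$plot_id[2] <- tab$plot_id[1]
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f2, row.names = FALSE)
  expect_error(load_plot_table(f2, sch), "duplicate plot id")
  # non-numeric entry in a numeric column
  tab <- read.csv(f, check.names = FALSE)
  tab[[sch$service[1]]] <- as.character(tab[[sch$service[1]]])
  tab[3, sch$service[1]] <- "high"
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f3, row.names = FALSE)
  expect_error(load_plot_table(f3, sch), "non-numeric")
  # unmapped columns are ignored with a warning
  sch2 <- sch
  sch2$attribute <- sch$attribute[-1]
  expect_warning(load_plot_table(f, sch2), "unmapped")
})

test_that("plot_data enforces its invariants", {
  sim <- generate_dataset(random_config(2), seed = 2)
  d <- sim$data
  expect_error(plot_data(d$plot_id, d$region,
                         `[<-`(d$env, 1, 1, NA), d$attributes, d$services),
               "environmental")
  expect_error(plot_data(d$plot_id, d$region, d$env,
                         `[<-`(d$attributes, 1, 1, NA), d$services),
               "attributes")
  const <- d$services
  const[, 1] <- 1
  expect_error(plot_data(d$plot_id, d$region, d$env, d$attributes, const),
               "constant")
})

test_that("transforms follow their closed forms and domains", {
  y <- matrix(c(1, 4, 9, 16, 0, exp(1) - 1, 3, 7), ncol = 2,
              dimnames = list(NULL, c("sq", "lg")))
  d <- plot_data(paste0("p", 1:4), factor(rep(c("a", "b"), 2)),
                 matrix(rnorm(4), 4, 1, dimnames = list(NULL, "e1")),
                 matrix(rnorm(4), 4, 1, dimnames = list(NULL, "a1")), y)
  out <- apply_transforms(d, transform_spec(
    c(sq = "sqrt", lg = "log"), standardize = FALSE))
  expect_equal(out$services[, "sq"], c(1, 2, 3, 4))
  # zeros present, so the default offset is 1: log(0+1)=0, log(e-1+1)=1
  expect_equal(out$services[1:2, "lg"], c(0, 1))
  neg <- d
  neg$services[1, "sq"] <- -1
  expect_error(apply_transforms(neg, transform_spec(c(sq = "sqrt"),
                                                    standardize = FALSE)),
               "sqrt transform undefined")
  expect_error(apply_transforms(d, transform_spec(c(lg = "log"),
                                                  log_offset = 0,
                                                  standardize = FALSE)),
               "log transform undefined")
})

test_that("standardization gives exact z-scores and is idempotent", {
  sim <- generate_dataset(preset_scenario("paper_like"), seed = 3)
  d1 <- apply_transforms(sim$data)
  for (b in c("env", "attributes", "services")) {
    mu <- apply(d1[[b]], 2, function(x) mean(x[!is.na(x)]))
    sd1 <- apply(d1[[b]], 2, function(x) sd(x[!is.na(x)]))
    expect_lt(max(abs(mu)), 1e-10)
    expect_lt(max(abs(sd1 - 1)), 1e-10)
  }
  d2 <- apply_transforms(d1)
  expect_equal(d2$services, d1$services, tolerance = 1e-10)
  # missingness is preserved
  expect_identical(is.na(d1$services), is.na(sim$data$services))
})

test_that("transformation precedes standardization", {
  set.seed(9)
  skewed <- exp(rnorm(60))
  y <- cbind(sv = skewed, o = rnorm(60))
  d <- plot_data(paste0("p", 1:60), factor(rep(c("a", "b"), 30)),
                 matrix(rnorm(60), dimnames = list(NULL, "e1")),
                 matrix(rnorm(60), dimnames = list(NULL, "a1")), y)
  out <- apply_transforms(d, transform_spec(c(sv = "log")))
  expect_equal(out$services[, "sv"], zscore(log(skewed)), tolerance = 1e-12)
})
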