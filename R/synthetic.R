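#' Configuration of the synthetic plot-data generator
#'
#' Describes a generative model with the causal ordering the analysis
#' pipeline assumes: environment (region mean shifts + unit-normal
#' noise) partially determines forest attributes, and services are
#' driven by environment, attributes and a multivariate-normal residual
#' whose off-diagonal covariance plants intrinsic service couplings.
#'
#' The environmental design has E = (K-1) + E_cont columns: K-1 region
#' indicators followed by the continuous factors, and the coefficient
#' matrices are indexed on that design.
#'
#' @param P number of plots (default 150, 3 regions of 50, the standard
#'   large plot network size this generator emulates).
#' @param K number of regions.
#' @param E_cont number of continuous environmental factors.
#' @param A number of forest attributes.
#' @param S number of ecosystem services.
#' @param B_env_attr E x A matrix, environment -> attribute coefficients.
#' @param B_env_srv E x S matrix, direct environment -> service
#'   coefficients.
#' @param B_attr_srv A x S matrix, attribute -> service coefficients.
#' @param Sigma_res S x S positive-definite residual covariance of the
#'   services; nonzero off-diagonal entries plant intrinsic couplings.
#' @param noise_sd_attr per-attribute residual SD (recycled to length A).
#' @param missing_rate per-service probability in `[0, 1)` that a value
#'   is missing (completely at random).
#' @param region_shift K x E_cont matrix of region mean shifts on the
#'   continuous environmental factors (region as confounder).
#' @param seed default integer seed used by [generate_dataset()].
#' @param env_names,attr_names,srv_names optional column names.
#' @return an object of class `synth_config`.
#' @seealso [generate_dataset()], [preset_scenario()], [ground_truth()]
#' @export
synth_config <- function(P = 150, K = 3, E_cont = 3, A = 12, S = 14,
                         B_env_attr = NULL, B_env_srv = NULL,
                         B_attr_srv = NULL, Sigma_res = diag(S),
                         noise_sd_attr = 1, missing_rate = 0,
                         region_shift = NULL, seed = 1L,
                         env_names = NULL, attr_names = NULL,
                         srv_names = NULL) {
  E <- (K - 1L) + E_cont
  if (is.null(env_names))
    env_names <- default_names("env", E_cont)
  if (is.null(attr_names)) attr_names <- default_names("attr", A)
  if (is.null(srv_names)) srv_names <- default_names("srv", S)
  region_levels <- paste0("region", LETTERS[seq_len(K)])
  design_names <- c(paste0("region_", region_levels[-1]), env_names)
  zmat <- function(m, nr, nc, rn, cn, what) {
    if (is.null(m)) m <- matrix(0, nr, nc)
    m <- as.matrix(m)
    if (!all(dim(m) == c(nr, nc)))
      stop(what, " must be ", nr, " x ", nc)
    dimnames(m) <- list(rn, cn)
    m
  }
  B_env_attr <- zmat(B_env_attr, E, A, design_names, attr_names, "B_env_attr")
  B_env_srv <- zmat(B_env_srv, E, S, design_names, srv_names, "B_env_srv")
  B_attr_srv <- zmat(B_attr_srv, A, S, attr_names, srv_names, "B_attr_srv")
  Sigma_res <- zmat(Sigma_res, S, S, srv_names, srv_names, "Sigma_res")
  if (max(abs(Sigma_res - t(Sigma_res))) > 1e-12)
    stop("Sigma_res must be symmetric")
  ev <- eigen(Sigma_res, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Sigma_res is not positive-definite (smallest eigenvalue ",
         format(min(ev)), ")")
  region_shift <- zmat(region_shift, K, E_cont, region_levels, env_names,
                       "region_shift")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  noise_sd_attr <- rep_len(noise_sd_attr, A)
  if (any(noise_sd_attr <= 0)) stop("noise_sd_attr must be positive")
  structure(list(P = as.integer(P), K = as.integer(K),
                 E_cont = as.integer(E_cont), A = as.integer(A),
                 S = as.integer(S), B_env_attr = B_env_attr,
                 B_env_srv = B_env_srv, B_attr_srv = B_attr_srv,
                 Sigma_res = Sigma_res, noise_sd_attr = noise_sd_attr,
                 missing_rate = missing_rate, region_shift = region_shift,
                 seed = as.integer(seed), region_levels = region_levels,
                 env_names = env_names, attr_names = attr_names,
                 srv_names = srv_names, design_names = design_names),
            class = "synth_config")
}

default_names <- function(prefix, n) {
  pool <- switch(prefix,
    env = c("slope", "soil_depth", "soil_ph"),
    attr = c("mean_dbh", "canopy_cover", "conifer_cover", "oak_cover",
             "vertical_het", "horizontal_het", "tree_richness",
             "tree_evenness", "shrub_richness", "shrub_evenness",
             "beech_regen", "deadwood_vol"),
    srv = c("root_decomp", "dung_removal", "p_availability",
            "n_availability", "mycorrhizal_div", "pest_control",
            "temp_regulation", "soil_carbon", "tree_carbon", "timber",
            "edible_fungi", "edible_plants", "cultural_plants",
            "birdwatching"))
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, paste0(prefix, seq_len(n - length(pool))))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic plot-data configuration\n")
  cat(sprintf("  P = %d plots, %d regions; E = %d (%d indicators + %d continuous)\n",
              x$P, x$K, length(x$design_names), x$K - 1L, x$E_cont))
  cat(sprintf("  A = %d attributes, S = %d services, missing rate %.2f\n",
              x$A, x$S, x$missing_rate))
  cat(sprintf("  nonzero coefficients: env->attr %d, env->srv %d, attr->srv %d; coupled residual pairs %d\n",
              sum(x$B_env_attr != 0), sum(x$B_env_srv != 0),
              sum(x$B_attr_srv != 0),
              sum(x$Sigma_res[upper.tri(x$Sigma_res)] != 0)))
  invisible(x)
}

#' Generate a synthetic plot-level dataset with planted ground truth
#'
#' Draws environment, attributes and services under the hierarchical
#' generative model of a [synth_config]: continuous environmental
#' factors get region-specific mean shifts plus standard-normal noise;
#' attributes are linear in the environmental design plus independent
#' noise; services are linear in environment and attributes plus a
#' multivariate-normal residual with covariance `Sigma_res`.  Service
#' values are then masked completely at random at `missing_rate`.
#' Identical seeds give bit-identical datasets; the ground truth depends
#' only on the configuration, never on the seed.
#'
#' @param config a [synth_config].
#' @param seed integer seed; defaults to `config$seed`.  The global RNG
#'   state is restored on exit.
#' @return list of class `es_sim` with elements `data` (a [plot_data])
#'   and `truth` (a [ground_truth()] object).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  seed <- as.integer(seed)   # force before the RNG state is saved
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  P <- config$P; K <- config$K
  region <- factor(rep_len(config$region_levels, P),
                   levels = config$region_levels)
  region <- region[order(region)]
  env <- config$region_shift[as.integer(region), , drop = FALSE] +
    matrix(stats::rnorm(P * config$E_cont), P, config$E_cont)
  colnames(env) <- config$env_names
  ind <- stats::model.matrix(~ region, data.frame(region = region))[, -1,
                                                                    drop = FALSE]
  colnames(ind) <- paste0("region_", config$region_levels[-1])
  design <- cbind(ind, env)
  attributes <- design %*% config$B_env_attr +
    matrix(stats::rnorm(P * config$A), P, config$A) %*%
      diag(config$noise_sd_attr, config$A)
  colnames(attributes) <- config$attr_names
  eps <- matrix(stats::rnorm(P * config$S), P, config$S) %*%
    chol(config$Sigma_res)
  services <- design %*% config$B_env_srv +
    attributes %*% config$B_attr_srv + eps
  colnames(services) <- config$srv_names
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(P * config$S) < config$missing_rate,
                   P, config$S)
    services[mask] <- NA_real_
  }
  data <- plot_data(plot_id = sprintf("plot_%03d", seq_len(P)),
                    region = region, env = env, attributes = attributes,
                    services = services)
  structure(list(data = data, truth = ground_truth(config), config = config,
                 seed = seed),
            class = "es_sim")
}

#' @export
print.es_sim <- function(x, ...) {
  cat("Synthetic dataset (seed", x$seed, ")\n")
  print(x$data)
  tt <- table(x$truth$pairs$class)
  cat("planted pair classes:",
      paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Population covariance of the environmental design
#'
#' Exact second moments of the (K-1 indicators + continuous factors)
#' design implied by equal region proportions and the configured region
#' mean shifts, with unit within-region noise variance.
#'
#' @param config a [synth_config].
#' @return E x E covariance matrix.
#' @keywords internal
env_population_cov <- function(config) {
  K <- config$K; Ec <- config$E_cont
  pk <- rep(1 / K, K)
  mu <- config$region_shift                       # K x Ec
  mbar <- colSums(pk * mu)
  E <- (K - 1L) + Ec
  Sig <- matrix(0, E, E, dimnames = list(config$design_names,
                                         config$design_names))
  # indicators for regions 2..K
  for (i in seq_len(K - 1L)) for (j in seq_len(K - 1L))
    Sig[i, j] <- if (i == j) pk[i + 1] * (1 - pk[i + 1]) else
      -pk[i + 1] * pk[j + 1]
  # indicator x continuous: E[I_k x_j] - E[I_k] E[x_j]
  for (i in seq_len(K - 1L)) for (j in seq_len(Ec))
    Sig[i, K - 1L + j] <- Sig[K - 1L + j, i] <-
      pk[i + 1] * (mu[i + 1, j] - mbar[j])
  # continuous block: within-region unit noise + between-region shifts
  for (i in seq_len(Ec)) for (j in seq_len(Ec))
    Sig[K - 1L + i, K - 1L + j] <- (i == j) +
      sum(pk * (mu[, i] - mbar[i]) * (mu[, j] - mbar[j]))
  Sig
}

#' Population service covariance at each cascade step
#'
#' Closed-form service covariance implied by a [synth_config] under the
#' generative model, before and after the two residualization steps of
#' the cascade: step 1 is the marginal covariance, step 2 removes the
#' (linear) environmental part, step 3 additionally removes the
#' attribute part, leaving the planted residual covariance.
#'
#' @param config a [synth_config].
#' @return list of S x S matrices `step1`, `step2`, `step3`.
#' @export
population_service_cov <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  SigE <- env_population_cov(config)
  Tot <- config$B_env_srv + config$B_env_attr %*% config$B_attr_srv
  Du <- diag(config$noise_sd_attr^2, config$A)
  s3 <- config$Sigma_res
  s2 <- t(config$B_attr_srv) %*% Du %*% config$B_attr_srv + s3
  s1 <- t(Tot) %*% SigE %*% Tot + s2
  dimnames(s1) <- dimnames(s2) <- dimnames(s3) <-
    list(config$srv_names, config$srv_names)
  list(step1 = s1, step2 = s2, step3 = s3)
}

#' Planted ground truth of a synthetic configuration
#'
#' Derives, deterministically from the configuration (never from a
#' realized dataset), the driver class of every service pair from the
#' mechanisms that couple the two services:
#' * `intrinsic` -- nonzero planted residual covariance;
#' * `environment` -- the services share an environmental driver: some
#'   design column has a nonzero total effect (direct plus via
#'   attributes) on both;
#' * `attribute` -- the services share a forest-attribute driver (a
#'   nonzero `B_attr_srv` row entry for both);
#' * `combined` -- both of the above;
#' * `none` -- no coupling mechanism.
#'
#' The rule is structural, not numerical: removing a service's own
#' (unshared) drivers rescales its variance and hence shifts the pair
#' correlation slightly between cascade steps, but introduces no
#' coupling mechanism and is not flagged.  All applicable mechanism
#' flags are reported per pair; the `class` label resolves multiplicity
#' as combined > environment > attribute > intrinsic > none.  The
#' population correlations at each cascade step are reported alongside.
#'
#' @param config a [synth_config].
#' @return list of class `ground_truth`: `pairs` (data frame with flags,
#'   class and the three population correlations), `net_effects` (row
#'   means of `B_attr_srv`), `pop_cor` (the three population correlation
#'   matrices).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  pc <- lapply(population_service_cov(config), stats::cov2cor)
  S <- config$S
  ij <- which(upper.tri(diag(S)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  r1 <- pc$step1[ij]; r2 <- pc$step2[ij]; r3 <- pc$step3[ij]
  intrinsic <- config$Sigma_res[ij] != 0
  Tot <- config$B_env_srv + config$B_env_attr %*% config$B_attr_srv
  shares <- function(B) crossprod(B != 0) > 0   # S x S: any common driver
  env <- shares(Tot)[ij]
  att <- shares(config$B_attr_srv)[ij]
  class <- ifelse(env & att, "combined",
           ifelse(env, "environment",
           ifelse(att, "attribute",
           ifelse(intrinsic, "intrinsic", "none"))))
  pairs <- data.frame(service_i = config$srv_names[ij[, 1]],
                      service_j = config$srv_names[ij[, 2]],
                      intrinsic = intrinsic, environment = env,
                      attribute = att, class = class,
                      r_pop_step1 = r1, r_pop_step2 = r2, r_pop_step3 = r3,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 net_effects = rowMeans(config$B_attr_srv),
                 pop_cor = pc),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted ground truth:", nrow(x$pairs), "service pairs\n")
  print(table(x$pairs$class))
  nz <- x$net_effects[x$net_effects != 0]
  if (length(nz)) {
    cat("nonzero planted net attribute effects:\n")
    print(round(nz, 4))
  }
  invisible(x)
}

#' Preset synthetic scenarios
#'
#' Documented configurations used throughout the test battery.  Effect
#' sizes are chosen for statistical detectability at the default P = 150
#' (see the methods vignette for the power reasoning), not as estimates
#' of any real forest landscape:
#'
#' * `"null"`: all coefficients zero, identity residual covariance.
#' * `"env_only"`: two service pairs share an environmental driver;
#'   attributes are pure noise.
#' * `"attr_only"`: two service pairs share an attribute driver;
#'   attributes are independent of the environment.
#' * `"combined"`: one pair shares both a (moderate) environmental and a
#'   (moderate) attribute driver.
#' * `"intrinsic"`: four planted synergies (residual correlation +0.5)
#'   and four planted trade-offs (-0.5); no env/attribute drivers.
#' * `"paper_like"`: P = 150, K = 3, A = 12, S = 14 with a mix of
#'   planted classes covering all five, region-shifted environment,
#'   env-driven nuisance attributes, per-service individual drivers and
#'   5% missingness.
#'
#' @param name scenario id.
#' @param P plot count override.
#' @param seed default seed stored in the config.
#' @return a [synth_config].
#' @export
preset_scenario <- function(name = c("null", "env_only", "attr_only",
                                     "combined", "intrinsic", "paper_like"),
                            P = 150, seed = 1L) {
  name <- match.arg(name)
  A <- 12L; S <- 14L; E <- 5L
  # region mean shifts on slope and pH; the two patterns are orthogonal
  # so the continuous factors stay uncorrelated in the population
  shift <- cbind(c(-0.8, 0, 0.8),            # slope
                 c(0, 0, 0),                 # soil depth
                 c(0.57, -1.14, 0.57))       # soil pH
  Bes <- matrix(0, E, S); Bas <- matrix(0, A, S); Bea <- matrix(0, E, A)
  Sig <- diag(S)
  cfg <- switch(name,
    null = synth_config(P = P, seed = seed),
    env_only = {
      Bes[3, 1:2] <- 0.9      # slope drives services 1 and 2
      Bes[4, 3:4] <- 0.9      # soil depth drives services 3 and 4
      synth_config(P = P, B_env_srv = Bes, region_shift = shift, seed = seed)
    },
    attr_only = {
      Bas[1, 1:2] <- 0.9      # mean DBH drives services 1 and 2
      Bas[2, 3:4] <- 0.9      # canopy cover drives services 3 and 4
      synth_config(P = P, B_attr_srv = Bas, seed = seed)
    },
    combined = {
      Bes[5, 1:2] <- 0.55     # soil pH, moderate
      Bas[1, 1:2] <- 0.55     # mean DBH, moderate
      synth_config(P = P, B_env_srv = Bes, B_attr_srv = Bas,
                   region_shift = shift, seed = seed)
    },
    intrinsic = {
      syn <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
      trd <- rbind(c(9, 10), c(9, 11), c(12, 13), c(12, 14))
      for (k in seq_len(nrow(syn))) Sig[syn[k, 1], syn[k, 2]] <-
        Sig[syn[k, 2], syn[k, 1]] <- 0.5
      for (k in seq_len(nrow(trd))) Sig[trd[k, 1], trd[k, 2]] <-
        Sig[trd[k, 2], trd[k, 1]] <- -0.5
      synth_config(P = P, Sigma_res = Sig, seed = seed)
    },
    paper_like = {
      Sig[1, 2] <- Sig[2, 1] <- 0.5          # intrinsic synergy
      Sig[3, 4] <- Sig[4, 3] <- -0.5         # intrinsic trade-off
      Bes[3, 5:6] <- 0.9                     # env-driven pair (slope)
      Bas[1, 7:8] <- 0.9                     # attribute-driven pair (DBH)
      Bes[5, 9:10] <- 0.55                   # combined pair (pH + canopy)
      Bas[2, 9:10] <- 0.55
      # individual drivers: realism for varpart/effects, no pair coupling
      solo <- cbind(srv = c(1, 2, 3, 4, 11, 12, 13, 14),
                    att = c(3, 4, 5, 6, 7, 8, 9, 10))
      Bas[cbind(solo[, "att"], solo[, "srv"])] <- 0.35
      # nuisance attributes under environmental control (confounding)
      Bea[1, 11] <- 0.6; Bea[3, 11] <- 0.4   # region B + slope -> beech regen
      Bea[5, 12] <- 0.5                      # soil pH -> deadwood volume
      synth_config(P = P, B_env_attr = Bea, B_env_srv = Bes,
                   B_attr_srv = Bas, Sigma_res = Sig,
                   region_shift = shift, missing_rate = 0.05, seed = seed)
    })
  cfg
}

#' Default service category map for the 14-service layout
#'
#' Assigns each default service to one of the four standard
#' ecosystem-service categories (supporting, regulating, provisioning,
#' cultural), as used by [group_exclusion_test()].
#'
#' @param srv_names service names (defaults to the standard 14).
#' @return named character vector service -> category.
#' @export
service_categories <- function(srv_names = default_names("srv", 14)) {
  stats::setNames(c(rep("supporting", 5), rep("regulating", 4),
                    "provisioning", rep("cultural", 4))[seq_along(srv_names)],
                  srv_names)
}
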