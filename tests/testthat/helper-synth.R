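# Shared fixtures, all built in code.

# standardized dataset from a scenario/config
std_data <- function(cfg, seed) {
  apply_transforms(generate_dataset(cfg, seed = seed)$data)
}

# small random configuration with arbitrary (seeded) coefficients;
# used by the algebraic-identity sweeps
random_config <- function(seed, P = 40, S = 3, A = 4, E_cont = 2, K = 2) {
  set.seed(seed)
  E <- (K - 1) + E_cont
  synth_config(P = P, K = K, E_cont = E_cont, A = A, S = S,
               B_env_attr = matrix(rnorm(E * A, sd = 0.4), E, A),
               B_env_srv = matrix(rnorm(E * S, sd = 0.4), E, S),
               B_attr_srv = matrix(rnorm(A * S, sd = 0.4), A, S),
               region_shift = matrix(rnorm(K * E_cont, sd = 0.5), K, E_cont),
               seed = seed)
}

# did a pair receive its planted flags?  combined pairs count as
# recovered when both mechanism flags fire or the conjunction flag does;
# none pairs when nothing fires.
recovered_flag <- function(class, cl_row) {
  switch(class,
    none = !cl_row$env_driven && !cl_row$attr_driven && !cl_row$combined &&
      !cl_row$consistent,
    intrinsic = cl_row$consistent,
    environment = cl_row$env_driven,
    attribute = cl_row$attr_driven,
    combined = (cl_row$env_driven && cl_row$attr_driven) || cl_row$combined)
}

# independent-groups Zou interval: oracle for the c = 0 limiting case
zou_independent <- function(r1, r2, n1, n2, alpha = 0.05) {
  zc <- qnorm(1 - alpha / 2)
  ci <- function(r, n) tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
  a <- ci(r1, n1); b <- ci(r2, n2)
  c(lower = r1 - r2 - sqrt((r1 - a[1])^2 + (b[2] - r2)^2),
    upper = r1 - r2 + sqrt((a[2] - r1)^2 + (r2 - b[1])^2))
}

# brute-force BH step-up: oracle for bh_fdr
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# brute-force R^2 through explicit normal equations: oracle for fit_lm
r2_brute <- function(y, X) {
  Z <- cbind(1, X)
  b <- solve(crossprod(Z), crossprod(Z, y))
  e <- y - Z %*% b
  1 - sum(e^2) / sum((y - mean(y))^2)
}

mvn_draw <- function(n, R) matrix(rnorm(n * ncol(R)), n) %*% chol(R)
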