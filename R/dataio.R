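#' esdrivers: attribution of ecosystem-service trade-offs and synergies
#'
#' Analysis pipeline for plot-level ecosystem-service data: variance
#' partitioning between forest attributes and environmental factors,
#' residualization-cascade attribution of service synergies and
#' trade-offs, and net/per-service attribute effect estimation, plus a
#' synthetic data generator with planted ground truth.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a plot-level dataset
#'
#' Bundles the three variable blocks of a plot-level study -- continuous
#' environmental factors, stand-level forest attributes and
#' ecosystem-service proxies -- together with plot identifiers and a
#' region (location) factor.  All blocks must share row order.  Missing
#' values are permitted only in the service block: services were not
#' measured on every plot, whereas environment and attributes describe
#' the plot itself and must be complete.
#'
#' @param plot_id character or coercible vector of unique plot ids.
#' @param region factor (or coercible) of length P; the categorical
#'   location/region variable.  Expanded to treatment-coded indicator
#'   columns (reference = first level alphabetically) wherever a model
#'   matrix is needed.
#' @param env numeric matrix or data frame, P x E_cont, continuous
#'   environmental factors (e.g. slope, soil depth, soil pH).
#' @param attributes numeric matrix or data frame, P x A, forest
#'   attributes.
#' @param services numeric matrix or data frame, P x S, ecosystem-service
#'   proxies; `NA` marks services not measured on a plot.
#' @return An object of class `plot_data`: a list with elements
#'   `plot_id`, `region`, `env`, `attributes`, `services` and the
#'   logical missingness mask `miss` (same shape as `services`).
#' @seealso [env_design()], [load_plot_table()], [apply_transforms()]
#' @examples
#' d <- generate_dataset(preset_scenario("null", P = 40))$data
#' d
#' @export
plot_data <- function(plot_id, region, env, attributes, services) {
  plot_id <- as.character(plot_id)
  region <- as.factor(region)
  env <- as_numeric_matrix(env, "env")
  attributes <- as_numeric_matrix(attributes, "attributes")
  services <- as_numeric_matrix(services, "services")
  P <- length(plot_id)
  if (anyDuplicated(plot_id))
    stop("duplicate plot ids: ",
         paste(unique(plot_id[duplicated(plot_id)]), collapse = ", "))
  if (length(region) != P || nrow(env) != P || nrow(attributes) != P ||
      nrow(services) != P)
    stop("all blocks must have one row per plot (P = ", P, ")")
  if (anyNA(env))
    stop("missing values in environmental factors are not allowed")
  if (anyNA(attributes))
    stop("missing values in forest attributes are not allowed")
  if (anyNA(region)) stop("missing region values are not allowed")
  for (blk in list(env = env, attributes = attributes, services = services)) {
    cst <- apply(blk, 2, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0 && max(x) - min(x) == 0
    })
    if (any(cst))
      stop("constant column(s) after dropping missing rows: ",
           paste(colnames(blk)[cst], collapse = ", "))
  }
  structure(list(plot_id = plot_id, region = region, env = env,
                 attributes = attributes, services = services,
                 miss = is.na(services)),
            class = "plot_data")
}

as_numeric_matrix <- function(x, what) {
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, logical(1))
    if (any(bad))
      stop("non-numeric value(s) in ", what, " column(s): ",
           paste(names(x)[bad], collapse = ", "))
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) stop("non-numeric values in ", what)
  rownames(x) <- NULL
  if (is.null(colnames(x)))
    colnames(x) <- paste0(substr(what, 1, 3), seq_len(ncol(x)))
  x
}

#' @export
print.plot_data <- function(x, ...) {
  cat("Plot-level dataset:", length(x$plot_id), "plots,",
      nlevels(x$region), "regions\n")
  cat("  environment:", ncol(x$env), "continuous factor(s) +",
      nlevels(x$region) - 1L, "region indicator(s)\n")
  cat("  attributes: ", ncol(x$attributes), "\n")
  cat("  services:   ", ncol(x$services), sprintf("(%.1f%% missing)\n",
      100 * mean(x$miss)))
  invisible(x)
}

#' @export
dim.plot_data <- function(x) {
  c(P = length(x$plot_id), E = ncol(env_design(x)),
    A = ncol(x$attributes), S = ncol(x$services))
}

#' Environmental design matrix
#'
#' Expands the region factor to K-1 treatment-coded indicator columns
#' (reference level = first alphabetically) and binds the continuous
#' environmental factors, yielding the predictor matrix used by every
#' environment model in the pipeline.
#'
#' @param data a [plot_data] object.
#' @return numeric matrix, P x ((K-1) + E_cont).
#' @export
env_design <- function(data) {
  stopifnot(inherits(data, "plot_data"))
  K <- nlevels(data$region)
  if (K > 1) {
    ind <- stats::model.matrix(~ region, data.frame(region = data$region))
    ind <- ind[, -1, drop = FALSE]
    colnames(ind) <- paste0("region_", levels(data$region)[-1])
    cbind(ind, data$env)
  } else {
    data$env
  }
}

#' Read a plot-level table from CSV/TSV
#'
#' Reads a delimited plot table and assembles a [plot_data] object
#' according to a column-role schema.  Columns present in the file but
#' not mentioned in the schema are ignored with a warning.
#'
#' @param path path to a CSV (comma) or TSV (tab) file with a header
#'   row; the delimiter is chosen from the file extension (`.tsv`/`.tab`
#'   = tab, otherwise comma).
#' @param schema named list with elements `id`, `region`, `env`,
#'   `attribute` and `service`, each giving the column name(s) holding
#'   that role.
#' @return a [plot_data] object.
#' @examples
#' sim <- generate_dataset(preset_scenario("null", P = 30))
#' f <- tempfile(fileext = ".csv")
#' write_plot_table(sim$data, f)
#' d <- load_plot_table(f, plot_schema(sim$data))
#' @export
load_plot_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  req <- c("id", "region", "env", "attribute", "service")
  missing_roles <- setdiff(req, names(schema))
  if (length(missing_roles))
    stop("schema is missing required role(s): ",
         paste(missing_roles, collapse = ", "))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  used <- unlist(schema, use.names = FALSE)
  absent <- setdiff(used, names(tab))
  if (length(absent))
    stop("schema column(s) not present in file: ",
         paste(absent, collapse = ", "))
  unmapped <- setdiff(names(tab), used)
  if (length(unmapped))
    warning("ignoring unmapped column(s): ", paste(unmapped, collapse = ", "))
  num_block <- function(cols, what) {
    blk <- tab[cols]
    bad <- !vapply(blk, function(x) is.numeric(x) || all(is.na(x)), logical(1))
    if (any(bad))
      stop("non-numeric value in numeric ", what, " column(s): ",
           paste(cols[bad], collapse = ", "))
    blk[] <- lapply(blk, as.numeric)
    blk
  }
  plot_data(plot_id = tab[[schema$id]],
            region = tab[[schema$region]],
            env = num_block(schema$env, "environment"),
            attributes = num_block(schema$attribute, "attribute"),
            services = num_block(schema$service, "service"))
}

#' Write a plot-level table to CSV/TSV
#'
#' Inverse of [load_plot_table()]: writes plot id, region, continuous
#' environmental factors, attributes and services as one flat table.
#' Values survive a write/load round trip to full double precision.
#'
#' @param data a [plot_data] object.
#' @param path output file; `.tsv`/`.tab` extension selects tabs.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(data, path) {
  stopifnot(inherits(data, "plot_data"))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- data.frame(plot_id = data$plot_id, region = as.character(data$region),
                    data$env, data$attributes, data$services,
                    check.names = FALSE)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Column-role schema of a dataset
#'
#' @param data a [plot_data] object.
#' @return named list with roles `id`, `region`, `env`, `attribute`,
#'   `service`, suitable for [load_plot_table()].
#' @export
plot_schema <- function(data) {
  stopifnot(inherits(data, "plot_data"))
  list(id = "plot_id", region = "region",
       env = colnames(data$env),
       attribute = colnames(data$attributes),
       service = colnames(data$services))
}

#' Per-column transformation specification
#'
#' Describes the variance-stabilising transformations applied before
#' analysis: a per-column choice among identity, natural log and square
#' root, followed (optionally) by z-standardization of every column.
#' Skewed count- or cover-like service proxies typically take log or
#' square-root transforms.
#'
#' @param transform named character vector mapping column names to one
#'   of `"identity"`, `"log"`, `"sqrt"`; unnamed columns default to
#'   identity.
#' @param log_offset non-negative offset added inside the log,
#'   `log(x + offset)`.  The default `NULL` picks, per column, 1 when
#'   zeros are present and 0 otherwise.
#' @param standardize logical; z-score every column (mean 0, sample SD 1
#'   with the n-1 denominator, complete cases only) after transforming.
#'   Region indicator columns are never standardized.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(transform = character(), log_offset = NULL,
                           standardize = TRUE) {
  transform <- vapply(transform, match.arg,
                      character(1), c("identity", "log", "sqrt"))
  if (!is.null(log_offset) && any(log_offset < 0))
    stop("log_offset must be non-negative")
  structure(list(transform = transform, log_offset = log_offset,
                 standardize = isTRUE(standardize)),
            class = "transform_spec")
}

#' Apply transformations and z-standardization
#'
#' Applies the per-column transforms of a [transform_spec] to the named
#' columns (searched across the environment, attribute and service
#' blocks), then -- if `spec$standardize` -- z-scores every column of
#' every block using complete cases only.  Transformation always
#' precedes standardization.  Missing entries stay missing.
#'
#' @param data a [plot_data] object.
#' @param spec a [transform_spec]; the default transforms nothing and
#'   standardizes everything.
#' @return a transformed [plot_data] object.
#' @export
apply_transforms <- function(data, spec = transform_spec()) {
  stopifnot(inherits(data, "plot_data"), inherits(spec, "transform_spec"))
  blocks <- c("env", "attributes", "services")
  for (cn in names(spec$transform)) {
    kind <- spec$transform[[cn]]
    if (kind == "identity") next
    hit <- blocks[vapply(blocks, function(b) cn %in% colnames(data[[b]]),
                         logical(1))]
    if (!length(hit)) stop("transform names unknown column: ", cn)
    x <- data[[hit[1]]][, cn]
    ok <- !is.na(x)
    if (kind == "log") {
      off <- spec$log_offset
      if (is.null(off)) off <- if (any(x[ok] == 0)) 1 else 0
      if (any(x[ok] + off <= 0))
        stop("log transform undefined for column '", cn, "' at row(s) ",
             paste(utils::head(which(ok & x + off <= 0), 5), collapse = ", "))
      x[ok] <- log(x[ok] + off)
    } else {
      if (any(x[ok] < 0))
        stop("sqrt transform undefined for column '", cn, "' at row(s) ",
             paste(utils::head(which(ok & x < 0), 5), collapse = ", "))
      x[ok] <- sqrt(x[ok])
    }
    data[[hit[1]]][, cn] <- x
  }
  if (spec$standardize)
    for (b in blocks) data[[b]] <- apply(data[[b]], 2, zscore)
  data$miss <- is.na(data$services)
  validate_standardized(data)
  data
}

validate_standardized <- function(data) {
  for (b in c("env", "attributes", "services")) {
    cst <- apply(data[[b]], 2, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0 && max(x) - min(x) == 0
    })
    if (any(cst))
      stop("column(s) became constant after transformation: ",
           paste(colnames(data[[b]])[cst], collapse = ", "))
  }
  invisible(data)
}

#' z-score a vector (sample SD, complete cases)
#'
#' @param x numeric vector; `NA`s are preserved.
#' @return `(x - mean) / sd` using complete cases for the moments.
#' @export
zscore <- function(x) {
  ok <- !is.na(x)
  (x - mean(x[ok])) / stats::sd(x[ok])
}
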