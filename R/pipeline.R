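#' Run the full analysis pipeline from a single configuration
#'
#' Executes data loading (or synthetic generation), transformation,
#' variance partitioning, the trade-off cascade with pairwise tests and
#' classification (plus optional group-exclusion sensitivity), and the
#' attribute-effect analyses, writing every artifact and a structured
#' run manifest to the output directory.
#'
#' The configuration is a YAML file (or an equivalent list) with fields:
#' \preformatted{
#' data:
#'   source: synthetic            # or "table"
#'   scenario: paper_like         # synthetic: preset name
#'   seed: 42
#'   path: plots.csv              # table: file path
#'   roles: {id: plot_id, region: region, env: [...],
#'           attribute: [...], service: [...]}
#' transforms:
#'   standardize: true
#'   log: [edible_plants]         # optional per-column transforms
#'   sqrt: [p_availability]
#' stages: [varpart, tradeoffs, effects]
#' alpha: 0.05
#' threshold: 0.1
#' groups: {root_decomp: supporting, ...}   # optional exclusion test
#' n_random: 100
#' out_dir: results
#' }
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return the run manifest (class `es_manifest`), invisibly: config
#'   echo, seed, per-stage wall time, file digests, captured warnings.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  need <- function(x, field, parent = "") {
    if (is.null(x)) stop("config is missing required field: ",
                         paste0(parent, field))
    x
  }
  dat_cfg <- need(config$data, "data")
  src <- need(dat_cfg$source, "source", "data$")
  if (!src %in% c("synthetic", "table"))
    stop("config field data$source must be 'synthetic' or 'table'")
  out_dir <- out_dir %||% config$out_dir %||% "results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("varpart", "tradeoffs", "effects")
  alpha <- config$alpha %||% 0.05
  threshold <- config$threshold %||% 0.1
  seed <- dat_cfg$seed %||% 1L
  warns <- character()
  files <- character()
  timings <- numeric()
  note <- function(f) files <<- c(files, f)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[name] <<- round(proc.time()[3] - t0, 3)
    val
  }

  data <- run_stage("dataio", {
    if (src == "synthetic") {
      scen <- need(dat_cfg$scenario, "scenario", "data$")
      sim <- generate_dataset(preset_scenario(scen, seed = seed))
      f <- file.path(out_dir, "dataset.csv")
      write_plot_table(sim$data, f); note(f)
      tf <- file.path(out_dir, "ground_truth.json")
      jsonlite::write_json(sim$truth$pairs, tf, digits = NA); note(tf)
      sim$data
    } else {
      roles <- need(dat_cfg$roles, "roles", "data$")
      if (is.null(roles$service))
        stop("config is missing required field: data$roles$service")
      load_plot_table(need(dat_cfg$path, "path", "data$"), roles)
    }
  })
  tcfg <- config$transforms %||% list()
  spec <- transform_spec(
    transform = c(stats::setNames(rep("log", length(tcfg$log)), tcfg$log),
                  stats::setNames(rep("sqrt", length(tcfg$sqrt)), tcfg$sqrt)),
    standardize = tcfg$standardize %||% TRUE)
  data <- run_stage("transform", apply_transforms(data, spec))
  f <- file.path(out_dir, "dataset_transformed.csv")
  write_plot_table(data, f); note(f)

  results <- list()
  if ("varpart" %in% stages) {
    vp <- run_stage("varpart", varpart(data))
    f <- file.path(out_dir, "varpart.csv")
    utils::write.csv(as.data.frame(vp), f, row.names = FALSE); note(f)
    results$varpart <- vp
  }
  if ("tradeoffs" %in% stages) {
    res <- run_stage("tradeoffs", {
      cc <- correlation_cascade(data)
      pt <- compare_pairs(cc, alpha = alpha)
      cl <- classify_pairs(pt, cc, threshold = threshold)
      mt <- list(
        step1_vs_step2 = compare_matrices(cc$Y$step1, cc$Y$step2),
        step2_vs_step3 = compare_matrices(cc$Y$step2, cc$Y$step3),
        step1_vs_step3 = compare_matrices(cc$Y$step1, cc$Y$step3))
      ex <- if (!is.null(config$groups))
        group_exclusion_test(data, unlist(config$groups),
                             n_random = config$n_random %||% 100,
                             seed = seed)
      list(cascade = cc, pairs = pt, classes = cl, matrix_tests = mt,
           exclusion = ex)
    })
    for (st in names(res$cascade$cor)) {
      f <- file.path(out_dir, paste0("cascade_", st, ".csv"))
      utils::write.csv(res$cascade$cor[[st]], f); note(f)
    }
    f <- file.path(out_dir, "pair_tests.csv")
    utils::write.csv(as.data.frame(res$pairs), f, row.names = FALSE); note(f)
    f <- file.path(out_dir, "classification.csv")
    utils::write.csv(as.data.frame(res$classes), f, row.names = FALSE)
    note(f)
    f <- file.path(out_dir, "matrix_tests.json")
    jsonlite::write_json(lapply(res$matrix_tests, function(m)
      m[c("chi2", "df", "p_value", "cfi", "tli", "mc", "n")]), f,
      auto_unbox = TRUE, digits = NA); note(f)
    if (!is.null(res$exclusion)) {
      f <- file.path(out_dir, "exclusion.csv")
      utils::write.csv(res$exclusion$observed, f, row.names = FALSE); note(f)
      f <- file.path(out_dir, "exclusion_random.csv")
      utils::write.csv(res$exclusion$random, f, row.names = FALSE); note(f)
    }
    results$tradeoffs <- res
  }
  if ("effects" %in% stages) {
    res <- run_stage("effects", {
      ne <- fit_net_effects(data, alpha = alpha)
      se <- fit_all_services(data, alpha = alpha)
      list(net = ne, per_service = se)
    })
    f <- file.path(out_dir, "net_effects.csv")
    utils::write.csv(cbind(Predictor = rownames(res$net$table),
                           res$net$table), f, row.names = FALSE); note(f)
    f <- file.path(out_dir, "service_effects.csv")
    utils::write.csv(res$per_service$effects, f, row.names = FALSE); note(f)
    results$effects <- res
  }

  manifest <- structure(list(
    package = "esdrivers",
    version = as.character(utils::packageVersion("esdrivers")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config, stages = stages,
    out_dir = out_dir,
    timings = as.list(timings),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    warnings = warns), class = "es_manifest")
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  attr(manifest, "results") <- results
  attr(manifest, "path") <- mf
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.es_manifest <- function(x, ...) {
  cat("Pipeline run manifest (", x$timestamp, ")\n", sep = "")
  cat("  seed:", x$seed, "; stages:", paste(x$stages, collapse = ", "), "\n")
  cat("  outputs:", length(x$files), "files in", x$out_dir, "\n")
  for (nm in names(x$timings))
    cat(sprintf("  %-10s %7.2fs\n", nm, x$timings[[nm]]))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Render a human-readable run report
#'
#' Builds a Markdown report from a pipeline run: variance-partitioning
#' table with across-service means, mean synergy/trade-off strength per
#' cascade step, the classified pair table, the net-effect table and
#' the per-service effect table.  Every number is read back from the
#' CSV artifacts of the run, so the report cannot drift from the files.
#' Sections whose stage did not run are marked unavailable.
#'
#' @param manifest an `es_manifest`, or the path to a `manifest.json`.
#' @param out output file (default `report.md` next to the manifest).
#' @return the report path, invisibly.
#' @export
render_report <- function(manifest, out = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  dir <- manifest$out_dir
  out <- out %||% file.path(dir, "report.md")
  has <- function(f) file.exists(file.path(dir, f))
  rd <- function(f, ...) utils::read.csv(file.path(dir, f), ...)
  num <- function(x) formatC(x, digits = 2, format = "f")
  lines <- c("# Ecosystem-service driver analysis",
             "",
             paste0("Run of ", manifest$timestamp, ", seed ", manifest$seed,
                    "."), "")
  lines <- c(lines, "## Variance partitioning", "")
  if (has("varpart.csv")) {
    vp <- rd("varpart.csv")
    lines <- c(lines, md_table(data.frame(
      service = vp$service, n = vp$n,
      explained = num(vp$r2_full), attributes_only = num(vp$unique_attr),
      environment_only = num(vp$unique_env), shared = num(vp$shared),
      unexplained = num(vp$unexplained))), "",
      sprintf("Mean explained %s [%s-%s]; attributes only %s; environment only %s; shared %s.",
              num(mean(vp$r2_full)), num(min(vp$r2_full)),
              num(max(vp$r2_full)), num(mean(vp$unique_attr)),
              num(mean(vp$unique_env)), num(mean(vp$shared))), "")
  } else lines <- c(lines, "_Section unavailable (stage not run)._", "")
  lines <- c(lines, "## Synergies and trade-offs along the cascade", "")
  if (has("cascade_step1.csv")) {
    stp <- lapply(paste0("cascade_step", 1:3, ".csv"), rd, row.names = 1)
    summ <- do.call(rbind, lapply(seq_along(stp), function(k) {
      r <- as.matrix(stp[[k]]); r <- r[upper.tri(r)]; r <- r[!is.na(r)]
      data.frame(step = paste0("step", k),
                 mean_synergy = num(if (any(r > 0)) mean(r[r > 0]) else NA),
                 mean_tradeoff = num(if (any(r < 0)) mean(r[r < 0]) else NA))
    }))
    lines <- c(lines, md_table(summ), "")
  } else lines <- c(lines, "_Section unavailable (stage not run)._", "")
  lines <- c(lines, "## Pair classification", "")
  if (has("classification.csv")) {
    cl <- rd("classification.csv")
    lines <- c(lines,
      sprintf("%d pairs; %d main (|r| >= threshold), %d consistent, %d environment-driven, %d attribute-driven, %d combined.",
              nrow(cl), sum(cl$main), sum(cl$consistent),
              sum(cl$env_driven), sum(cl$attr_driven), sum(cl$combined)),
      "", md_table(data.frame(
        pair = paste(cl$service_i, cl$service_j, sep = " / "),
        r1 = num(cl$r_step1), r2 = num(cl$r_step2), r3 = num(cl$r_step3),
        sign = cl$sign, consistent = cl$consistent,
        env = cl$env_driven, attr = cl$attr_driven,
        combined = cl$combined)[cl$main, ]), "")
  } else lines <- c(lines, "_Section unavailable (stage not run)._", "")
  lines <- c(lines, "## Net effects of forest attributes", "")
  if (has("net_effects.csv")) {
    ne <- rd("net_effects.csv")
    ne[c("Estimate", "Std.error", "t")] <-
      lapply(ne[c("Estimate", "Std.error", "t")], num)
    ne$p <- signif(ne$p, 3)
    lines <- c(lines, md_table(ne), "")
  } else lines <- c(lines, "_Section unavailable (stage not run)._", "")
  lines <- c(lines, "## Per-service attribute effects", "")
  if (has("service_effects.csv")) {
    se <- rd("service_effects.csv")
    if (nrow(se)) {
      se[c("estimate", "se", "t")] <- lapply(se[c("estimate", "se", "t")],
                                             num)
      se[c("p_simplified", "p_full", "q_full")] <-
        lapply(se[c("p_simplified", "p_full", "q_full")], signif, 3)
      lines <- c(lines, sprintf(
        "%d retained effects (%d at strict FDR, %d at loose FDR, %d simplified-only).",
        nrow(se), sum(se$tier == "fdr5"), sum(se$tier == "fdr25"),
        sum(se$tier == "simplified_only")), "", md_table(se), "")
    } else lines <- c(lines, "No attribute retained for any service.", "")
  } else lines <- c(lines, "_Section unavailable (stage not run)._", "")
  writeLines(lines, out)
  invisible(out)
}

md_table <- function(df) {
  df[] <- lapply(df, as.character)
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(hdr, sep, body)
}
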