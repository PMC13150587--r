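#' Workflow orchestration
#'
#' File-based front ends chaining the package's stages into the two
#' analysis routes (response-surface route and augmentation/benchmark
#' route) plus design generation and deactivation kinetics. Each
#' workflow takes a configuration list, writes its outputs atomically
#' (temporary file + rename, so a failed run never leaves partial
#' files) into `out_dir`, and finishes with a `manifest.json` recording
#' the package version, the configuration (including every defaulted
#' setting) and MD5 digests of all result files. All stochastic stages
#' draw per-stage seeds derived from the single master `seed` by fixed
#' offsets, so one integer reproduces a whole run byte-identically.
#'
#' `pipeline_design(config)` writes the Box-Behnken design CSV. Config:
#' `factors` (a `bbd_factors` set or a list of `list(name, low, center,
#' high)` blocks), `center_points` (default 3), `out_dir`.
#'
#' `pipeline_fit_rsm(config)` reads a design CSV with responses and
#' writes `model.json` (coefficients, unit space, factor set),
#' `anova.csv` (Source, DF, SS, MS, F, p), `summary.json` (R-squared
#' family, PRESS) and `optimization.json`. Config: `design_csv`,
#' `response` (default `"activity"`), optional `bounds`, `direction`,
#' `anova_space`, `out_dir`.
#'
#' `pipeline_benchmark(config)` reads a replicate CSV (or takes
#' `replicates` directly), runs [run_benchmark()] and writes
#' `benchmark.json`, `metrics.csv` (family x train/test grid) and
#' `taylor.csv` (plot-ready sd/correlation/centered-RMSE coordinates).
#' Config: `replicates_csv` or `replicates`, `seed`, and the
#' [run_benchmark()] settings.
#'
#' `pipeline_kinetics(config)` reads one or two kinetics CSVs (columns
#' `time_h`, `activity`) and writes `kinetics.json` with each fit's
#' inactivation constant, half-life and R-squared, plus the
#' stabilization factor when both free and immobilized series are given.
#' Config: `free_csv` and/or `immobilized_csv`, `out_dir`.
#'
#' @param config Named list as described per workflow.
#' @return The manifest, invisibly.
#' @name pipeline
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' d <- amylase_bbd()
#' write_design_csv(d, file.path(dir, "design.csv"))
#' pipeline_fit_rsm(list(design_csv = file.path(dir, "design.csv"),
#'                       out_dir = dir))
NULL

#' @rdname pipeline
#' @export
pipeline_design <- function(config) {
  config <- check_config(config, "factors")
  factors <- as_factor_set(config$factors)
  cp <- config$center_points %||% 3
  des <- bbd_design(factors, center_points = cp)
  out <- prepare_out_dir(config$out_dir)
  write_atomic(file.path(out, "design.csv"),
               function(tmp) write_design_csv(des, tmp))
  message("wrote ", nrow(des), "-run design")
  finish_manifest(out, "design",
                  config = list(center_points = cp,
                                factors = factor_blocks(factors)),
                  files = "design.csv")
}

#' @rdname pipeline
#' @export
pipeline_fit_rsm <- function(config) {
  config <- check_config(config, "design_csv")
  response <- config$response %||% "activity"
  des <- read_design_csv(config$design_csv)
  if (!response %in% names(des))
    stop("stage fit-rsm: design CSV lacks response column '", response, "'",
         call. = FALSE)
  factors <- design_factors(des)
  form <- stats::reformulate(factor_names(factors), response = response)
  fit <- rsm_quad(form, des)
  tab <- anova(fit, space = config$anova_space %||% "coded")
  st <- fit_stats(fit)
  opt <- optimize_response(fit, bounds = config$bounds,
                           direction = config$direction %||% "max")
  out <- prepare_out_dir(config$out_dir)
  write_json_atomic(list(coefficients = as.list(coef(fit)),
                         unit_space = "actual",
                         response = response,
                         sigma2 = fit$sigma2,
                         factors = factor_blocks(factors)),
                    file.path(out, "model.json"))
  write_atomic(file.path(out, "anova.csv"), function(tmp)
    utils::write.csv(as.data.frame(tab), tmp, row.names = FALSE, na = ""))
  write_json_atomic(unclass(st), file.path(out, "summary.json"))
  write_json_atomic(list(actual = as.list(opt$actual),
                         coded = as.list(opt$coded),
                         predicted = opt$predicted,
                         boundary = as.list(opt$boundary),
                         classification = opt$classification),
                    file.path(out, "optimization.json"))
  finish_manifest(out, "fit-rsm",
                  config = list(design_csv = config$design_csv,
                                response = response,
                                anova_space = attr(tab, "space"),
                                direction = opt$direction),
                  files = c("model.json", "anova.csv", "summary.json",
                            "optimization.json"))
}

#' @rdname pipeline
#' @export
pipeline_benchmark <- function(config) {
  config <- check_config(config, "seed")
  reps <- if (!is.null(config$replicates)) config$replicates
          else if (!is.null(config$replicates_csv))
            read_replicates_csv(config$replicates_csv)
          else stop("stage benchmark: need 'replicates' or 'replicates_csv'",
                    call. = FALSE)
  bm <- run_benchmark(
    reps, seed = config$seed,
    target_n = config$target_n %||% 750,
    test_fraction = config$test_fraction %||% 0.2,
    families = config$families %||% c("svr", "gpr", "rfr"),
    bounds = config$bounds,
    resolution = config$resolution %||% 101,
    response = config$response %||% "activity",
    split_mode = config$split_mode %||% "sample")
  out <- prepare_out_dir(config$out_dir)
  tay <- do.call(rbind, lapply(names(bm$taylor), function(fam)
    do.call(rbind, lapply(names(bm$taylor[[fam]]), function(lab) {
      ts <- bm$taylor[[fam]][[lab]]
      data.frame(family = fam, set = lab, sd_ref = ts$sd_ref,
                 sd_pred = ts$sd_pred, correlation = ts$correlation,
                 azimuth_rad = acos(ts$correlation), crmse = ts$crmse)
    }))))
  write_atomic(file.path(out, "metrics.csv"), function(tmp)
    utils::write.csv(bm$metrics, tmp, row.names = FALSE))
  write_atomic(file.path(out, "taylor.csv"), function(tmp)
    utils::write.csv(tay, tmp, row.names = FALSE))
  write_json_atomic(list(
    metrics = bm$metrics,
    optima = lapply(bm$optima, function(o)
      list(actual = as.list(o$actual), predicted = o$predicted,
           boundary = as.list(o$boundary))),
    provenance = bm$provenance[c("seed", "target_n", "test_fraction",
                                 "families", "split_mode", "resolution")],
    noise_rule = bm$provenance$augmentation$noise_rule,
    split_caveat = bm$provenance$augmentation$caveat),
    file.path(out, "benchmark.json"))
  finish_manifest(out, "benchmark", config = bm$provenance,
                  files = c("metrics.csv", "taylor.csv", "benchmark.json"))
}

#' @rdname pipeline
#' @export
pipeline_kinetics <- function(config) {
  config <- check_config(config)
  paths <- config[intersect(c("free_csv", "immobilized_csv"), names(config))]
  if (length(paths) == 0L)
    stop("stage kinetics: need 'free_csv' and/or 'immobilized_csv'",
         call. = FALSE)
  fits <- lapply(paths, function(p) {
    d <- utils::read.csv(p)
    if (!all(c("time_h", "activity") %in% names(d)))
      stop("kinetics CSV ", p, " must have columns time_h, activity",
           call. = FALSE)
    tryCatch(fit_deactivation(d$time_h, d$activity),
             error = function(e)
               stop("unusable series in ", p, ": ", conditionMessage(e),
                    call. = FALSE))
  })
  names(fits) <- sub("_csv$", "", names(paths))
  res <- lapply(fits, function(f)
    list(k_d = f$k_d, half_life_h = f$half_life, r_squared = f$r_squared,
         n_used = f$n_used))
  if (all(c("free", "immobilized") %in% names(fits)))
    res$SF <- stabilization_factor(fits$free, fits$immobilized)$SF
  out <- prepare_out_dir(config$out_dir)
  write_json_atomic(res, file.path(out, "kinetics.json"))
  finish_manifest(out, "kinetics", config = paths, files = "kinetics.json")
}

#' Read or write a replicate CSV
#'
#' Replicate CSV dialect: columns `run`, one actual-unit column per
#' factor, `rep` (replicate index) and the response.
#'
#' @param data Replicate data frame (e.g. from [simulate_bbd_dataset()]).
#' @param path File path.
#' @param factors Optional `bbd_factors`; inferred from the three
#'   distinct levels per factor column when `NULL`.
#' @param response Response column name.
#' @return `read_replicates_csv()` returns the data frame with the
#'   factor set attached.
#' @export
write_replicates_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_replicates_csv
#' @export
read_replicates_csv <- function(path, factors = NULL,
                                response = "activity") {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("run", "rep", response)
  if (!all(need %in% names(d)))
    stop("replicate CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  fcols <- setdiff(names(d), need)
  if (is.null(factors))
    factors <- infer_factors(as.matrix(d[fcols]))
  attr(d, "factors") <- factors
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_config <- function(config, required = character()) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (is.null(config$out_dir))
    stop("config field 'out_dir' is required", call. = FALSE)
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config field(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  config
}

as_factor_set <- function(x) {
  if (inherits(x, "bbd_factors")) return(x)
  fs <- lapply(x, function(b) {
    need <- c("name", "low", "center", "high")
    if (!all(need %in% names(b)))
      stop("malformed factor block: need fields ",
           paste(need, collapse = ", "), call. = FALSE)
    bbd_factor(b$name, b$low, b$center, b$high, unit = b$unit %||% "")
  })
  bbd_factors(fs)
}

factor_blocks <- function(factors) {
  lapply(unname(factors), function(f)
    list(name = f$name, unit = f$unit, low = f$low, center = f$center,
         high = f$high))
}

prepare_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

finish_manifest <- function(out_dir, stage, config, files) {
  paths <- file.path(out_dir, files)
  manifest <- list(
    tool = paste0("immobopt ",
                  as.character(utils::packageVersion("immobopt"))),
    stage = stage,
    config = config,
    files = stats::setNames(as.list(unname(tools::md5sum(paths))), files),
    written_at = format(Sys.time(), tz = "UTC"))
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
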