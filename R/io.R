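#' Read and write simulator tables as TSV
#'
#' TSV is the canonical tabular format: header row, tab-delimited, `NA` for
#' the not-available marker, full floating-point precision (17 significant
#' digits) so a write/read round trip reproduces the in-memory values
#' exactly.
#'
#' @param x A `sim_feature` object or its long-format `records` data frame.
#' @param path Output/input file path.
#' @return `write_long_tsv()` returns `path` invisibly; `read_long_tsv()`
#'   returns the records data frame with columns `Y`, `ID`, `time`, `group`,
#'   `Y_obs`.
#' @name long_tsv
NULL

format_full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  df
}

write_tsv_raw <- function(df, path) {
  utils::write.table(format_full_precision(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname long_tsv
#' @export
write_long_tsv <- function(x, path) {
  rec <- if (inherits(x, "sim_feature")) x$records else x
  stopifnot(is.data.frame(rec),
            all(c("Y", "ID", "time", "group", "Y_obs") %in% names(rec)))
  write_tsv_raw(rec[, c("Y", "ID", "time", "group", "Y_obs")], path)
}

#' @rdname long_tsv
#' @export
read_long_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    colClasses = c(Y = "numeric", ID = "integer",
                                   time = "numeric", group = "character",
                                   Y_obs = "numeric"))
}

#' Write a community dataset as feature-table and metadata TSVs
#'
#' The feature table is features x samples with row names in the first
#' column (`feature`); the metadata table has columns `ID`, `time`, `group`,
#' `Sample_ID` in sample (column) order.
#'
#' @param community A `sim_community` from [simulate_community()].
#' @param feature_path,meta_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_community_tsv <- function(community, feature_path, meta_path) {
  stopifnot(inherits(community, "sim_community"))
  ft <- data.frame(feature = rownames(community$abundance),
                   community$abundance, check.names = FALSE)
  write_tsv_raw(ft, feature_path)
  write_tsv_raw(community$sample_meta, meta_path)
  invisible(c(feature_path, meta_path))
}

#' Read a community feature table and metadata written by
#' [write_community_tsv()]
#'
#' @param feature_path,meta_path File paths.
#' @return A `sim_community` object.
#' @export
read_community_tsv <- function(feature_path, meta_path) {
  ft <- utils::read.delim(feature_path, sep = "\t", check.names = FALSE,
                          na.strings = "NA")
  abundance <- as.matrix(ft[, -1L, drop = FALSE])
  rownames(abundance) <- ft$feature
  meta <- utils::read.delim(meta_path, sep = "\t", na.strings = "NA",
                            colClasses = c(ID = "integer", time = "numeric",
                                           group = "character",
                                           Sample_ID = "character"))
  rownames(meta) <- meta$Sample_ID
  structure(list(abundance = abundance, sample_meta = meta),
            class = "sim_community")
}

#' Export a community abundance matrix as a BIOM file
#'
#' Writes the feature table in BIOM format (JSON) via the biomformat
#' package. Missing markers (`NA`) are not representable in BIOM and cause an
#' error; simulate with a numeric `miss_val` (e.g. 0) for BIOM export.
#'
#' @param community A `sim_community`.
#' @param path Output `.biom` path.
#' @return Invisibly, `path`.
#' @export
write_community_biom <- function(community, path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("BIOM export requires the 'biomformat' package", call. = FALSE)
  }
  if (anyNA(community$abundance)) {
    stop("BIOM cannot encode NA; use a numeric miss_val", call. = FALSE)
  }
  b <- biomformat::make_biom(community$abundance)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Export a dense covariance matrix as TSV
#'
#' Assembles a [block_covariance()] object (or accepts a plain matrix) and
#' writes it tab-delimited for inspection. Intended for small `N` only.
#'
#' @param sigma A `block_cov` object or numeric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sigma_tsv <- function(sigma, path) {
  m <- if (inherits(sigma, "block_cov")) as.matrix(sigma) else sigma
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- configuration files -------------------------------------------------

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
}

trend_from_config <- function(cfg) {
  if (is.null(cfg) || is.null(cfg$form)) {
    stop("trend config requires a 'form' field", call. = FALSE)
  }
  trend_spec(form = cfg$form,
             beta = if (is.null(cfg$beta)) numeric() else as.numeric(cfg$beta),
             ip = if (is.null(cfg$ip)) numeric() else as.numeric(cfg$ip))
}

cov_from_config <- function(cfg) {
  if (is.null(cfg) || is.null(cfg$structure)) {
    stop("covariance config requires a 'structure' field", call. = FALSE)
  }
  cov_spec(structure = cfg$structure,
           sigma = if (is.null(cfg$sigma)) 1 else cfg$sigma,
           rho = if (is.null(cfg$rho)) 0 else cfg$rho)
}

trunc_from_config <- function(cfg) {
  if (is.null(cfg)) return(truncation_spec())
  truncation_spec(
    enabled = if (is.null(cfg$enabled)) TRUE else isTRUE(cfg$enabled),
    a = if (is.null(cfg$a)) 0 else cfg$a,
    acceptance_threshold = if (is.null(cfg$acceptance_threshold)) 0.1
                           else cfg$acceptance_threshold,
    pilot_draws = if (is.null(cfg$pilot_draws)) 1000L else cfg$pilot_draws
  )
}

miss_val_from_config <- function(v) {
  if (is.null(v)) return(NA_real_)
  if (is.character(v)) {
    if (toupper(v) == "NA") return(NA_real_)
    return(as.numeric(v))
  }
  as.numeric(v)
}

#' Build a simulation design from a config mapping
#'
#' Configs are YAML or JSON files whose field names mirror [sim_design()]:
#' scalars at the top level (`n_control`, `n_treat`, `control_mean`,
#' `num_timepoints`, `t_interval`, `asynch_time`, `missing_pct`,
#' `missing_per_subject`, `miss_val`, `seed`) plus nested mappings
#' `trend: {form, beta, ip}`, `covariance: {structure, sigma, rho}` and
#' optionally `truncation: {enabled, a, acceptance_threshold, pilot_draws}`.
#' `miss_val` may be a number or the string `"NA"`.
#'
#' @param x A file path or an already-parsed list.
#' @return A [sim_design()].
#' @export
design_from_config <- function(x) {
  cfg <- if (is.character(x)) read_config_file(x) else x
  need <- c("n_control", "n_treat", "control_mean", "num_timepoints",
            "t_interval", "trend", "covariance")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop("design config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sim_design(
    n_control = cfg$n_control, n_treat = cfg$n_treat,
    control_mean = cfg$control_mean,
    covariance = cov_from_config(cfg$covariance),
    trend = trend_from_config(cfg$trend),
    num_timepoints = cfg$num_timepoints,
    t_interval = as.numeric(cfg$t_interval),
    asynch_time = isTRUE(cfg$asynch_time),
    missing_pct = if (is.null(cfg$missing_pct)) 0 else cfg$missing_pct,
    missing_per_subject = if (is.null(cfg$missing_per_subject)) 0L
                          else cfg$missing_per_subject,
    miss_val = miss_val_from_config(cfg$miss_val),
    truncation = trunc_from_config(cfg$truncation),
    seed = cfg$seed
  )
}

design_to_config <- function(design) {
  list(
    n_control = design$n_control, n_treat = design$n_treat,
    control_mean = design$control_mean,
    covariance = design$covariance[c("structure", "sigma", "rho")],
    trend = list(form = design$trend$form, beta = design$trend$beta,
                 ip = design$trend$ip),
    num_timepoints = design$num_timepoints,
    t_interval = design$t_interval,
    asynch_time = design$asynch_time,
    missing_pct = design$missing_pct,
    missing_per_subject = design$missing_per_subject,
    miss_val = if (is.na(design$miss_val)) "NA" else design$miss_val,
    truncation = unclass(design$truncation),
    seed = design$seed
  )
}

#' Build a sweep configuration from a config mapping
#'
#' Expects top-level fields `grids` (named map of value lists),
#' `repetitions`, `detector`, `seed`, `base_design` (a design mapping as in
#' [design_from_config()]) and optionally `trends`, a named map of trend
#' mappings.
#'
#' @param x A file path or an already-parsed list.
#' @return A [sweep_config()].
#' @export
sweep_from_config <- function(x) {
  cfg <- if (is.character(x)) read_config_file(x) else x
  need <- c("grids", "repetitions", "base_design")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop("sweep config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  grids <- lapply(cfg$grids, function(g) suppressWarnings(as.numeric(g)))
  if (any(vapply(grids, anyNA, logical(1)))) {
    stop("malformed grid value: grids must be numeric", call. = FALSE)
  }
  trends <- if (!is.null(cfg$trends)) {
    lapply(cfg$trends, trend_from_config)
  } else NULL
  sweep_config(
    grids = grids,
    repetitions = cfg$repetitions,
    base_design = design_from_config(cfg$base_design),
    trends = trends,
    detector = if (is.null(cfg$detector)) "oracle" else cfg$detector,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed
  )
}

#' Write a run manifest
#'
#' Every CLI run writes a JSON manifest alongside its outputs: the config
#' snapshot, the seed, the package version, the output file paths, and the
#' per-subject sampling modes used — enough to reproduce the run exactly.
#'
#' @param path Manifest output path.
#' @param config Config snapshot (list).
#' @param seed The seed the run used.
#' @param outputs Named character vector/list of output paths.
#' @param modes Optional per-block sampling modes.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, config, seed, outputs, modes = NULL) {
  manifest <- list(
    package = "longdasim",
    version = as.character(utils::packageVersion("longdasim")),
    seed = seed,
    config = config,
    outputs = as.list(outputs),
    sampling_modes = if (is.null(modes)) NULL else as.list(table(modes))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
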