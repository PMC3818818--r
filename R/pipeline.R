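# End-to-end driver: synthetic (or supplied) Ct table -> fold changes ->
# Z-scores -> average-linkage CIM, plus the model simulation and delay
# scans, with a reproducibility manifest of seeds and output hashes.

#' Read a flat key-value run configuration
#'
#' Same \code{name = value} format as the parameter files; values that parse
#' as numbers become numeric.  Unknown keys are kept verbatim.
#'
#' @param path file path.
#' @return Named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line in ", path)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  structure(vals, class = "run_config")
}

#' Default demonstration configuration
#'
#' @param out_dir output directory.
#' @param seed run seed.
#' @return A \code{run_config} list.
#' @export
demo_config <- function(out_dir = tempfile("nfkb_run_"), seed = 1L) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    reference_gene = "POLB", control_condition = "control",
    theta = 0.10, grid_min = 0, grid_max = 600, grid_step = 15,
    scan_axes = "traf1_only", run_combinatorial = 0,
    noise_sd = 0.25, missing_rate = 0.04,
    log_level = "info"), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: generate (or read) a Ct table; comparative-Ct fold changes;
#' row-wise Z-scores; average-linkage clustering and CIM export; nominal
#' model simulation; single-axis delay scan (and, if requested, the full
#' combinatorial scan with contour export).  Every artifact is written under
#' \code{config$out_dir} and listed, with its MD5 hash, in
#' \code{manifest.tsv}; re-running with the same configuration reproduces
#' identical hashes for all deterministic stages.
#'
#' @param config a \code{run_config} (see \code{\link{demo_config}} /
#'   \code{\link{read_run_config}}).
#' @param params model parameters (default: shipped calibrated set).
#' @param ct optional pre-existing \code{\link{ct_table}}; when absent a
#'   synthetic table is generated from the default plan with
#'   \code{config$seed}.
#' @return Invisible list with the manifest data frame and the stage
#'   outputs.
#' @export
run_pipeline <- function(config = demo_config(), params = default_params(),
                         ct = NULL) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  note <- function(path) artifacts[[length(artifacts) + 1]] <<- path

  plan <- .stage("gen-data", generator_plan(
    noise_sd = config$noise_sd, missing_rate = config$missing_rate,
    seed = config$seed, reference_gene = config$reference_gene))
  if (is.null(ct)) {
    ct <- .stage("gen-data", gen_ct_timecourse(plan))
    p <- file.path(out, "ct_table.csv"); write_ct_table(ct, p); note(p)
  }

  fc <- .stage("ddct", ddct_fold_change(ct, config$reference_gene,
                                        config$control_condition))
  p <- file.path(out, "fold_change.tsv"); write_expr_matrix(fc, p); note(p)

  z <- .stage("zscore", zscore_transform(fc))
  p <- file.path(out, "zscore.tsv"); write_expr_matrix(z, p); note(p)

  tree <- .stage("cluster", cluster_average_linkage(z))
  cim_tsv <- file.path(out, "cim.tsv")
  cim_png <- file.path(out, "cim.png")
  .stage("cim", export_cim(z, tree, cim_tsv, cim_png))
  note(cim_tsv)   # the PNG is rendered but not hashed (raster metadata)

  traj <- .stage("simulate", simulate_model(params, t_end_min = 600,
                                            dt_out_min = 5))
  p <- file.path(out, "trajectory_nominal.tsv"); write_trajectory(traj, p); note(p)

  spec <- delay_scan_spec(config$grid_min, config$grid_max, config$grid_step,
                          axes = config$scan_axes)
  scan <- .stage("scan-single", scan_single_delay(params, spec,
                                                  theta = config$theta))
  p <- file.path(out, "scan_single.csv"); write_scan_csv(scan, p); note(p)

  both <- NULL
  if (isTRUE(config$run_combinatorial == 1)) {
    both <- .stage("scan-both", scan_combinatorial(
      params, delay_scan_spec(config$grid_min, config$grid_max,
                              config$grid_step, axes = "both"),
      theta = config$theta))
    p <- file.path(out, "scan_both.csv"); write_scan_csv(both, p); note(p)
    p <- file.path(out, "contour.tsv"); scan_contour_matrix(both, p); note(p)
  }

  manifest <- data.frame(
    file = basename(unlist(artifacts)),
    md5 = unname(tools::md5sum(unlist(artifacts))),
    stringsAsFactors = FALSE)
  info <- c(sprintf("# nfkbcoupler run manifest"),
            sprintf("# package_version = %s",
                    as.character(utils::packageVersion("nfkbcoupler"))),
            sprintf("# seed = %d", as.integer(config$seed)),
            sprintf("# config_hash = %s",
                    .hash_config(config)))
  mpath <- file.path(out, "manifest.tsv")
  writeLines(info, mpath)
  suppressWarnings(utils::write.table(manifest, mpath, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(list(manifest = manifest, ct = ct, fold_change = fc, zscore = z,
                 tree = tree, trajectory = traj, scan_single = scan,
                 scan_both = both, out_dir = out))
}

.hash_config <- function(config) {
  keys <- sort(setdiff(names(config), "out_dir"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(keys, vapply(config[keys], function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}
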