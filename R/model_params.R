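# Parameter and species bookkeeping for the reduced NF-kB coupling model.
# The order of .param_order and .species_names is shared with src/dde.cpp.

.param_order <- c(
  "tau_traf1_min", "tau_nfkb2_min", "ikk_act_rate", "ikk_inact_rate",
  "txn_max_ikba", "txn_max_traf1", "txn_max_p100", "txn_max_canon_reporter",
  "txn_max_tnip1", "hill_K_rela", "hill_K_p52", "hill_h",
  "tln_rate_ikba", "tln_rate_traf1", "tln_rate_p100",
  "deg_mrna", "deg_ikba", "deg_traf1", "deg_p100", "deg_p52",
  "nik_synth_rate", "nik_fast_deg", "nik_stable_deg", "traf1_nik_bind",
  "proc_rate", "proc_K", "ikba_rela_assoc", "ikba_deg_by_ikk",
  "rela_total", "basal_txn")

.species_names <- c(
  "IKK_active", "IkBa_mRNA", "IkBa_protein", "RelA_IkBa_complex",
  "RelA_nuclear", "CanonReporter_mRNA", "TRAF1_mRNA", "TRAF1_protein",
  "NIK_free", "TRAF1_NIK_complex", "p100_mRNA", "p100_protein", "p52",
  "TNIP1_mRNA")

#' Species names of the reduced NF-kB coupling model
#'
#' @return Character vector of the 14 state variables, in model order.
#' @export
model_species <- function() .species_names

#' Construct a validated model parameter set
#'
#' Builds the parameter vector of the reduced canonical/noncanonical NF-kB
#' network.  Unnamed defaults come from the calibrated configuration shipped
#' with the package (see \code{\link{default_params}}); any parameter can be
#' overridden by name.
#'
#' Units: time in minutes, abundances in arbitrary units (a.u.).  The two
#' translational delays \code{tau_traf1_min} and \code{tau_nfkb2_min} are the
#' lags between an mRNA's appearance and its translation (nominally 120 and
#' 90 min).
#'
#' @param ... named parameter overrides.
#' @param base named numeric vector to start from (default: shipped
#'   calibrated set).
#' @return Named numeric vector of class \code{nfkb_params}.
#' @examples
#' p <- model_params(tau_traf1_min = 0, tau_nfkb2_min = 0)
#' @export
model_params <- function(..., base = default_params()) {
  p <- base
  mod <- list(...)
  if (length(mod)) {
    bad <- setdiff(names(mod), .param_order)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(mod)] <- vapply(mod, as.numeric, numeric(1))
  }
  validate_params(p)
  structure(p[.param_order], class = "nfkb_params")
}

validate_params <- function(p) {
  missing <- setdiff(.param_order, names(p))
  if (length(missing)) stop("missing parameter(s): ", paste(missing, collapse = ", "))
  p <- p[.param_order]
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p < 0)) {
    stop("negative parameter(s): ",
         paste(names(p)[p < 0], collapse = ", "))
  }
  if (p[["hill_h"]] < 1) stop("hill_h must be >= 1")
  if (p[["rela_total"]] <= 0) stop("rela_total must be > 0")
  for (tau in c("tau_traf1_min", "tau_nfkb2_min")) {
    if (p[[tau]] > 600) stop(tau, " must lie in [0, 600] minutes")
  }
  invisible(p)
}

.params_cache <- new.env(parent = emptyenv())

#' Calibrated default parameters
#'
#' Reads (and caches) the calibrated parameter configuration shipped in
#' \code{inst/extdata/default_params.conf}.  This set is the output of
#' \code{\link{calibrate_nominal}}: at the nominal delays (120, 90) min the
#' p52 coupling interval is 6 h, at (0, 0) it is below one 15-min grid step,
#' and the canonical reporter peaks within the first hour of TNF stimulation.
#'
#' @return Named numeric vector of class \code{nfkb_params}.
#' @export
default_params <- function() {
  if (is.null(.params_cache$default)) {
    path <- system.file("extdata", "default_params.conf",
                        package = "nfkbcoupler", mustWork = TRUE)
    .params_cache$default <- read_params(path)
  }
  .params_cache$default
}

#' Read a flat key-value parameter file
#'
#' One \code{name = value} pair per line; \code{#} starts a comment.
#'
#' @param path file path.
#' @return Named numeric vector of class \code{nfkb_params}.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed line(s) in ", path, ": ", lines[bad][1])
  p <- vapply(kv, function(x) as.numeric(trimws(x[2])), numeric(1))
  names(p) <- vapply(kv, function(x) trimws(x[1]), character(1))
  validate_params(p)
  structure(p[.param_order], class = "nfkb_params")
}

#' Write a parameter set to a flat key-value file
#'
#' @param params parameter vector from \code{\link{model_params}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  units <- c(
    tau_traf1_min = "min", tau_nfkb2_min = "min",
    hill_K_rela = "a.u.", hill_K_p52 = "a.u.", hill_h = "dimensionless",
    proc_K = "a.u.", rela_total = "a.u.", basal_txn = "a.u./min")
  lines <- vapply(.param_order, function(nm) {
    u <- if (nm %in% names(units)) units[[nm]] else "per min or a.u./min"
    sprintf("%s = %.17g  # %s", nm, unname(params[[nm]]), u)
  }, character(1))
  writeLines(c("# nfkbcoupler model parameters", lines), path)
  invisible(path)
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("NF-kB coupling model parameters (", length(x), " values)\n", sep = "")
  cat(sprintf("  delays: TRAF1 %g min, NF-kB2 %g min\n",
              x[["tau_traf1_min"]], x[["tau_nfkb2_min"]]))
  print(unclass(x), ...)
  invisible(x)
}
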