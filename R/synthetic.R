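# Seeded generators emulating the study's data structures: the 50-gene qPCR
# panel over a 6-point TNF time course in EMT (+TGFb) and control (-TGFb)
# conditions, genomic-DNA dilution series, and noisy p52 trajectories for
# the delay-recovery experiments.  All generators are pure functions of
# (plan, seed).

#' Primer panel of the expression assay
#'
#' The 50-gene Q-RT-PCR panel (pathway group, accession, amplicon length and
#' primer pair per gene) shipped with the package.
#'
#' @return Data frame with columns \code{pathway}, \code{gene},
#'   \code{accession}, \code{amplicon_bp}, \code{fwd_primer},
#'   \code{rev_primer}.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "primer_panel.tsv", package = "nfkbcoupler",
                      mustWork = TRUE)
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(all(c("pathway", "gene", "accession", "amplicon_bp",
                  "fwd_primer", "rev_primer") %in% names(panel)))
  if (any(panel$amplicon_bp < 50 | panel$amplicon_bp > 160)) {
    stop("amplicon length outside [50, 160] bp")
  }
  primers <- c(panel$fwd_primer, panel$rev_primer)
  if (any(grepl("[^ACGT]", primers))) stop("primers must contain only A/C/G/T")
  invisible(panel)
}

#' Generator plan for a synthetic Ct time course
#'
#' Defines the planned fold-change profile of every panel gene over the
#' stimulation time course in both conditions, the Ct-scale noise model and
#' the missingness rate.  The default plan encodes the study's qualitative
#' cluster structure: NF-kB-dependent and growth-factor genes upregulated by
#' TNF with stronger induction under EMT, the EMT program itself induced in
#' the EMT condition, and the interferon/ISG cluster suppressed by EMT.
#' TRAF1 peaks at 12 h with a 20-fold EMT amplitude versus 3-fold in
#' control.
#'
#' @param panel primer panel data frame (default \code{\link{default_panel}}).
#' @param times_min stimulation time points, minutes (default the 0-24 h
#'   course \{0, 1, 3, 6, 12, 24\} h).
#' @param noise_sd additive Gaussian noise on the Ct scale, cycles.
#' @param missing_rate probability a (gene, condition, time) cell is missing
#'   (in [0, 0.2]).
#' @param n_replicates technical replicates per cell.
#' @param seed RNG seed recorded in the plan.
#' @param reference_gene name of the housekeeping assay row added to the
#'   table.
#' @return List of class \code{generator_plan} including \code{profiles}, the
#'   planned genes x (condition, time) fold-change matrix.
#' @export
generator_plan <- function(panel = default_panel(),
                           times_min = c(0, 60, 180, 360, 720, 1440),
                           noise_sd = 0.25, missing_rate = 0.04,
                           n_replicates = 2, seed = 1L,
                           reference_gene = "POLB") {
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop("missing_rate must lie in [0, 0.2]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  genes <- panel$gene
  conds <- c("control", "EMT")
  cols <- expand.grid(time_min = times_min, condition = conds,
                      KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  lab <- paste0(cols$condition, "_t", cols$time_min)
  prof <- matrix(1, length(genes), nrow(cols), dimnames = list(genes, lab))

  # TNF induction shape: rise to a peak then partial relaxation (peak index
  # by group), scaled per condition.
  shape <- function(peak_fold, peak_idx, end_frac = 0.6) {
    k <- length(times_min)
    up <- seq(0, 1, length.out = peak_idx)
    down <- seq(1, end_frac, length.out = k - peak_idx + 1)[-1]
    peak_fold^c(up, down)
  }
  set_profile <- function(gene, control_fold, emt_fold, peak_idx = 4) {
    prof[gene, cols$condition == "control"] <<- shape(control_fold, peak_idx)
    prof[gene, cols$condition == "EMT"] <<- shape(emt_fold, peak_idx)
  }
  for (g in genes) {
    grp <- panel$pathway[panel$gene == g][1]
    if (g == "TRAF1") {
      set_profile(g, 3, 20, peak_idx = 5)           # peaks at 12 h
    } else if (g == "NFKB2") {
      set_profile(g, 2.5, 8, peak_idx = 5)
    } else if (g == "TNIP1") {
      set_profile(g, 4, 10, peak_idx = 4)
    } else if (grp == "Canonical") {
      set_profile(g, 6, 12, peak_idx = 2)           # early canonical burst
    } else if (grp == "Noncanonical EMT") {
      # EMT program: induced by TGFb regardless of TNF time
      prof[g, cols$condition == "EMT"] <- 8
      prof[g, cols$condition == "EMT" & cols$time_min == 0] <- 6
    } else if (grp == "IFN") {
      set_profile(g, 5, 1.2, peak_idx = 3)          # EMT suppresses ISGs
      prof[g, cols$condition == "EMT"] <-
        prof[g, cols$condition == "EMT"] * 0.25
    } else if (grp == "Growth factor") {
      set_profile(g, 3, 7, peak_idx = 3)
    } else {
      set_profile(g, 1.5, 2.5, peak_idx = 3)        # ROS/DNA, cell cycle
    }
  }
  # fold changes are relative to (control, first time): force that column to 1
  prof[, cols$condition == "control" & cols$time_min == min(times_min)] <- 1

  structure(list(panel = panel, times_min = times_min, conditions = conds,
                 columns = cols, profiles = prof, noise_sd = noise_sd,
                 missing_rate = missing_rate, n_replicates = n_replicates,
                 seed = as.integer(seed), reference_gene = reference_gene,
                 ref_ct = 20, base_offset = 5),
            class = "generator_plan")
}

#' Generate a synthetic Ct table from a plan
#'
#' Inverts the comparative-Ct formula: each gene's Ct is the reference Ct
#' plus a gene-level offset minus log2 of the planned fold change, plus
#' seeded Gaussian noise per replicate; missing cells are injected at the
#' planned rate.  At zero noise and zero missingness,
#' \code{\link{ddct_fold_change}} recovers the planned fold-change matrix
#' exactly.
#'
#' @param plan a \code{\link{generator_plan}}.
#' @return A \code{\link{ct_table}} with the plan seed attached as attribute
#'   \code{"seed"}.
#' @export
gen_ct_timecourse <- function(plan) {
  stopifnot(inherits(plan, "generator_plan"))
  rng <- .seeded_rng(plan$seed)
  cols <- plan$columns
  genes <- rownames(plan$profiles)
  planned_ct <- plan$ref_ct + plan$base_offset - log2(plan$profiles)
  if (any(planned_ct <= 0 | planned_ct > 40)) {
    bad <- genes[apply(planned_ct <= 0 | planned_ct > 40, 1, any)]
    stop("plan implies Ct outside (0, 40] for gene(s): ",
         paste(bad, collapse = ", "))
  }
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    grp <- plan$panel$pathway[plan$panel$gene == g][1]
    for (ci in seq_len(nrow(cols))) {
      # the control anchor (control condition, first time) is never blanked:
      # the study's fold-change tables are defined relative to it
      anchor <- cols$condition[ci] == "control" &&
        cols$time_min[ci] == min(plan$times_min)
      miss <- !anchor && rng$runif(1) < plan$missing_rate
      for (r in seq_len(plan$n_replicates)) {
        ct <- if (miss) NA_real_ else {
          planned_ct[gi, ci] + rng$rnorm(1, 0, plan$noise_sd)
        }
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, pathway = grp, condition = cols$condition[ci],
          time_min = cols$time_min[ci], replicate = r, ct = ct)
      }
    }
  }
  # reference assay: noiseless anchor, never missing
  for (ci in seq_len(nrow(cols))) {
    for (r in seq_len(plan$n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = plan$reference_gene, pathway = "Reference",
        condition = cols$condition[ci], time_min = cols$time_min[ci],
        replicate = r, ct = plan$ref_ct)
    }
  }
  out <- ct_table(do.call(rbind, rows))
  attr(out, "seed") <- plan$seed
  out
}

# local RNG stream that does not disturb the caller's .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    st
  })
  call_with <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = call_with(stats::rnorm), runif = call_with(stats::runif))
}

#' Noisy p52 trajectory at known delays
#'
#' Simulates the model at the given (lattice) delays and applies seeded
#' multiplicative Gaussian noise to every p52 output sample.  Input for the
#' delay-recovery experiments.
#'
#' @param params parameter vector.
#' @param true_delays numeric \code{c(tau_traf1_min, tau_nfkb2_min)} on the
#'   15-min lattice.
#' @param noise_sd_fraction multiplicative noise SD (>= 0; 0.05 = 5%).
#' @param seed RNG seed.
#' @param dt_out_min output sampling interval, minutes.
#' @param h_min internal integration step, minutes.
#' @return List with \code{times_min}, \code{p52} (noisy), \code{clean},
#'   \code{true_delays} and \code{seed}.
#' @export
gen_noisy_trajectory <- function(params, true_delays, noise_sd_fraction = 0.05,
                                 seed = 1L, dt_out_min = 15, h_min = 0.05) {
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be >= 0")
  if (any(true_delays %% 15 != 0)) {
    stop("true delays must lie on the 15-min lattice")
  }
  traj <- .simulate_at_delays(validate_params(params), true_delays[1],
                              true_delays[2], dt_out_min, h_min)
  clean <- unname(traj$values[, "p52"])
  rng <- .seeded_rng(seed)
  noisy <- clean * (1 + rng$rnorm(length(clean), 0, noise_sd_fraction))
  list(times_min = traj$times_min, p52 = noisy, clean = clean,
       true_delays = c(tau_traf1_min = true_delays[1],
                       tau_nfkb2_min = true_delays[2]),
       seed = as.integer(seed))
}

#' Synthetic genomic-DNA dilution series
#'
#' Cts from a known standard-curve line plus seeded Gaussian noise.
#'
#' @param true_slope Ct per log10 ng (negative for a valid curve).
#' @param true_intercept Ct at 1 ng.
#' @param masses_ng template masses, ng (> 0; default the study's 1-100 ng
#'   series).
#' @param noise_sd Ct noise SD, cycles.
#' @param seed RNG seed.
#' @return Data frame with \code{mass_ng} and \code{ct}.
#' @export
gen_dilution_series <- function(true_slope, true_intercept,
                                masses_ng = c(1, 10, 100), noise_sd = 0,
                                seed = 1L) {
  if (length(masses_ng) == 0) stop("empty mass list")
  if (any(masses_ng <= 0)) stop("masses must be > 0")
  rng <- .seeded_rng(seed)
  data.frame(mass_ng = masses_ng,
             ct = true_slope * log10(masses_ng) + true_intercept +
               rng$rnorm(length(masses_ng), 0, noise_sd))
}
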