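# Relative quantification of qPCR time courses: comparative-Ct fold changes
# against a reference assay, and the row-wise Z-score transform used for the
# clustered image maps.  Amplification efficiency is taken as 100% (exact
# doubling per cycle) throughout.

#' Construct / validate a Ct table
#'
#' Long-format threshold-cycle records: one row per (gene, condition,
#' stimulation time, replicate).  Missing measurements are \code{NA} Cts.
#'
#' @param df data frame with columns \code{gene}, \code{pathway},
#'   \code{condition}, \code{time_min}, \code{replicate}, \code{ct}.
#' @return The validated data frame, classed \code{ct_table}.
#' @export
ct_table <- function(df) {
  need <- c("gene", "pathway", "condition", "time_min", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("ct_table lacks column(s): ", paste(missing, collapse = ", "))
  ok <- is.na(df$ct) | (df$ct > 0 & df$ct <= 40)
  if (!all(ok)) {
    stop("Ct values outside (0, 40] for gene(s): ",
         paste(unique(df$gene[!ok]), collapse = ", "))
  }
  key <- paste(df$gene, df$condition, df$time_min, df$replicate)
  if (anyDuplicated(key)) stop("duplicate (gene, condition, time, replicate) records")
  class(df) <- c("ct_table", class(df))
  df
}

#' Read / write Ct tables (comma-separated, NA for missing)
#'
#' @param path file path.
#' @return A \code{\link{ct_table}}.
#' @export
read_ct_table <- function(path) {
  ct_table(utils::read.csv(path, na.strings = "NA"))
}

#' @rdname read_ct_table
#' @param ct a \code{ct_table}.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, na = "NA")
  invisible(path)
}

.expr_matrix <- function(m, value_kind) {
  structure(m, value_kind = value_kind, class = c("expr_matrix", class(m)))
}

#' Comparative-Ct (delta-delta-Ct) fold changes
#'
#' Replicate Cts are first averaged per (gene, condition, time) on the Ct
#' scale (geometric-mean behaviour on the linear scale).  For each column
#' (condition, time), delta-Ct is the gene's mean Ct minus the reference
#' gene's mean Ct; delta-delta-Ct subtracts the delta-Ct of the control
#' sample (control condition at the earliest time point), and the fold
#' change is 2^-ddCt.  The control column therefore equals 1 by
#' construction.  Missing Cts propagate to missing fold changes; a column
#' missing the reference gene becomes entirely missing, with a warning.
#'
#' @param ct a \code{\link{ct_table}}.
#' @param reference_gene housekeeping assay name (default \code{"POLB"},
#'   human polymerase beta).
#' @param control_condition condition of the control sample.
#' @return Genes x (condition, time) matrix of fold changes, classed
#'   \code{expr_matrix} with \code{value_kind = "fold_change"}.  Columns are
#'   labelled \code{condition_t<minutes>}; the reference gene is dropped
#'   from the rows.
#' @export
ddct_fold_change <- function(ct, reference_gene = "POLB",
                             control_condition = "control") {
  stopifnot(inherits(ct, "ct_table"))
  if (!reference_gene %in% ct$gene) {
    stop("reference gene '", reference_gene, "' absent from the Ct table")
  }
  if (!control_condition %in% ct$condition) {
    stop("control condition '", control_condition, "' absent from the Ct table")
  }
  agg <- stats::aggregate(ct ~ gene + condition + time_min,
                          data = as.data.frame(ct), FUN = mean,
                          na.action = stats::na.pass)
  times <- sort(unique(agg$time_min))
  conds <- unique(agg$condition)
  conds <- c(control_condition, setdiff(conds, control_condition))
  cols <- expand.grid(time_min = times, condition = conds,
                      KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  col_lab <- paste0(cols$condition, "_t", cols$time_min)
  genes <- setdiff(sort(unique(agg$gene)), reference_gene)

  get_ct <- function(g, cond, tm) {
    v <- agg$ct[agg$gene == g & agg$condition == cond & agg$time_min == tm]
    if (length(v) == 0) NA_real_ else v
  }
  ref_ct <- mapply(function(cond, tm) get_ct(reference_gene, cond, tm),
                   cols$condition, cols$time_min)
  if (any(is.na(ref_ct))) {
    warning("reference gene Ct missing for column(s): ",
            paste(col_lab[is.na(ref_ct)], collapse = ", "),
            "; those columns are reported as missing")
  }

  dct <- matrix(NA_real_, length(genes), nrow(cols),
                dimnames = list(genes, col_lab))
  for (g in genes) {
    gct <- mapply(function(cond, tm) get_ct(g, cond, tm),
                  cols$condition, cols$time_min)
    dct[g, ] <- gct - ref_ct
  }
  ctrl_col <- which(cols$condition == control_condition &
                    cols$time_min == min(times))
  fc <- 2^(-(dct - dct[, ctrl_col]))
  .expr_matrix(fc, "fold_change")
}

#' Row-wise Z-score transform of a fold-change matrix
#'
#' Each row's observed entries are centred by the row mean and scaled by the
#' sample (n-1) standard deviation, so every observed row ends up with mean
#' 0 and SD 1.  Missing entries are preserved; constant rows map to all
#' zeros; rows with fewer than two observed entries become entirely missing.
#'
#' @param m an \code{expr_matrix} of fold changes (or plain numeric matrix).
#' @return \code{expr_matrix} with \code{value_kind = "zscore"}.
#' @export
zscore_transform <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0) {
    stop("zscore_transform needs a non-empty matrix")
  }
  vk <- attr(m, "value_kind")
  if (!is.null(vk) && vk != "fold_change") {
    stop("zscore_transform expects fold changes (value_kind = 'fold_change')")
  }
  z <- t(apply(m, 1, function(row) {
    obs <- !is.na(row)
    if (sum(obs) < 2) return(rep(NA_real_, length(row)))
    s <- stats::sd(row[obs])
    if (s == 0) {
      row[obs] <- 0
      return(row)
    }
    (row - mean(row[obs])) / s
  }))
  dimnames(z) <- dimnames(m)
  .expr_matrix(z, "zscore")
}

#' Read / write an expression matrix as TSV (NA for missing)
#'
#' @param m matrix with row labels (genes) and column labels.
#' @param path file path.
#' @param value_kind stored kind tag (\code{"fold_change"} or
#'   \code{"zscore"}) used when reading back.
#' @return \code{path} (write) or an \code{expr_matrix} (read).
#' @export
write_expr_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path, value_kind = "fold_change") {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  .expr_matrix(m, value_kind)
}
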