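#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with quartiles computed by linear interpolation
#' between order statistics. A robust, scale-invariant dispersion measure
#' used to compare how variable linear and nonlinear plasticity are across
#' traits.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @return The dimensionless QCD; lies in \[0, 1\] for all-positive inputs.
#' @examples
#' quartile_coefficient_dispersion(1:5) # 1/3
#' @export
quartile_coefficient_dispersion <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] + q[2] == 0) {
    stop("QCD undefined: Q1 + Q3 is zero", call. = FALSE)
  }
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Per-line plasticity summary from a Finlay-Wilkinson fit
#'
#' Assembles one row per fitted line carrying its genetic value (g), slope
#' deviation (b, so linear plasticity is 1 + b), nonlinear plasticity
#' (residual variance) and the line metadata (gene, event, material class)
#' found in the records.
#'
#' @param fit An `fw_fit`.
#' @param records The phenotype records the fit was computed from (used to
#'   look up line metadata).
#' @param year Optional year label to attach (fits are usually run per
#'   year).
#' @return A data frame with columns `line_id`, `gene_id`, `event_id`,
#'   `material_class`, `trait`, `year`, `g`, `b`, `nonlinear`.
#' @export
line_plasticity <- function(fit, records, year = NA) {
  stopifnot(inherits(fit, "fw_fit"))
  meta <- unique(records[c("line_id", "gene_id", "event_id",
                           "material_class")])
  idx <- match(names(fit$g), meta$line_id)
  data.frame(
    line_id = names(fit$g),
    gene_id = meta$gene_id[idx],
    event_id = meta$event_id[idx],
    material_class = meta$material_class[idx],
    trait = fit$trait,
    year = year,
    g = unname(fit$g),
    b = unname(fit$b),
    nonlinear = unname(fit$residual_variance),
    stringsAsFactors = FALSE
  )
}

#' Correlations among genetic value, linear and nonlinear plasticity
#'
#' The 3x3 correlation matrix over (g, b, nonlinear plasticity) across
#' lines, summarising whether lines with higher mean phenotype also respond
#' more strongly (g-b correlation) or less predictably (g-nonlinear
#' correlation) to the environment.
#'
#' @param summaries A line-plasticity table from [line_plasticity()] (or
#'   any data frame with numeric columns `g`, `b`, `nonlinear`).
#' @param method Correlation estimator (`"pearson"` default, `"spearman"`
#'   available for a rank-based view).
#' @return A symmetric 3x3 correlation matrix with unit diagonal;
#'   zero-variance columns give missing entries with a warning.
#' @export
plasticity_correlations <- function(summaries, method = "pearson") {
  m <- as.matrix(summaries[, c("g", "b", "nonlinear")])
  if (nrow(m) < 3) stop("need at least 3 lines", call. = FALSE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                    method = method))
  diag(cc) <- ifelse(sds > 0, 1, NA_real_)
  cc
}

#' Express plasticity summaries relative to the wild-type reference
#'
#' Adds `delta_g = g - g_WT` and `delta_b = b - b_WT` per trait and year,
#' anchoring every line's genetic value and slope to the shared wild-type
#' recipient line. The wild-type's own deltas are exactly zero.
#'
#' @param summaries A line-plasticity table.
#' @param wildtype_id The wild-type line identifier.
#' @return The table with `delta_g` and `delta_b` columns filled.
#' @export
wt_relative <- function(summaries, wildtype_id = "WT") {
  key <- paste(summaries$trait, summaries$year, sep = "\r")
  summaries$delta_g <- NA_real_
  summaries$delta_b <- NA_real_
  for (k in unique(key)) {
    sel <- key == k
    wt <- sel & summaries$line_id == wildtype_id
    if (sum(wt) == 0) {
      stop("no wild-type line '", wildtype_id, "' for trait '",
           summaries$trait[sel][1], "', year ", summaries$year[sel][1],
           call. = FALSE)
    }
    if (sum(wt) > 1) {
      stop("multiple wild-type rows for trait '", summaries$trait[sel][1],
           "', year ", summaries$year[sel][1], call. = FALSE)
    }
    summaries$delta_g[sel] <- summaries$g[sel] - summaries$g[wt]
    summaries$delta_b[sel] <- summaries$b[sel] - summaries$b[wt]
  }
  summaries
}
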