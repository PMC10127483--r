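#' Classify lines into wild-type-relative quadrants
#'
#' Labels each line by the signs of its wild-type-relative genetic value and
#' slope: `g+b+` (higher mean, stronger response than wild-type), `g+b-`,
#' `g-b+`, `g-b-`. Exact ties with the wild-type are assigned to the `+`
#' side and flagged.
#'
#' @param summaries A line-plasticity table with `delta_g` and `delta_b`
#'   (see [wt_relative()]).
#' @return The table with `quadrant` and logical `tie` columns added.
#' @export
classify_quadrants <- function(summaries) {
  if (is.null(summaries$delta_g) || is.null(summaries$delta_b)) {
    stop("summaries must carry delta_g and delta_b; run wt_relative() first",
         call. = FALSE)
  }
  gp <- summaries$delta_g >= 0
  bp <- summaries$delta_b >= 0
  summaries$quadrant <- paste0("g", ifelse(gp, "+", "-"),
                               "b", ifelse(bp, "+", "-"))
  summaries$tie <- summaries$delta_g == 0 | summaries$delta_b == 0
  summaries
}

#' Select candidate genes for one year
#'
#' The per-year screening rule: a gene is a candidate when its genetic
#' value exceeds the wild-type's (strictly, `g > g_WT`) in at least
#' `min_events` independent transformation events. The returned table also
#' counts events exceeding wild-type in both g and b, which describes how
#' consistently a gene raises the mean and the environmental response.
#'
#' @param summaries A line-plasticity table for one trait and year with
#'   deltas filled (see [wt_relative()]).
#' @param trait_name Trait to screen on.
#' @param wildtype_id Wild-type line identifier (excluded from gene
#'   counting).
#' @param min_events Minimum number of events with `g > g_WT` (default 3).
#' @return A list with `genes` (character vector of retained gene IDs) and
#'   `table`, a per-gene data frame with columns `gene_id`, `year`,
#'   `material_class`, `n_events`, `n_events_g_above_wt`,
#'   `n_events_gb_above_wt`, `passed_event_rule`.
#' @export
select_candidates_per_year <- function(summaries, trait_name,
                                       wildtype_id = "WT", min_events = 3) {
  s <- summaries[summaries$trait == trait_name &
                   summaries$line_id != wildtype_id, , drop = FALSE]
  if (nrow(s) == 0) stop("no lines for trait '", trait_name, "'",
                         call. = FALSE)
  if (any(is.na(s$delta_g))) {
    stop("delta_g missing; run wt_relative() first", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(split(s, s$gene_id), function(d) {
    data.frame(
      gene_id = d$gene_id[1],
      year = d$year[1],
      material_class = d$material_class[1],
      n_events = nrow(d),
      n_events_g_above_wt = sum(d$delta_g > 0),
      n_events_gb_above_wt = sum(d$delta_g > 0 & d$delta_b > 0),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  tab$passed_event_rule <- tab$n_events_g_above_wt >= min_events
  list(genes = tab$gene_id[tab$passed_event_rule], table = tab)
}

#' Combine candidate gene sets from two years
#'
#' Splits the union of two per-year candidate sets into genes found in both
#' years and genes found in only one, the categorisation used to report the
#' final candidate list.
#'
#' @param candidates_y1,candidates_y2 Character vectors of gene IDs.
#' @param year_labels Labels for the two years.
#' @return An object of class `final_candidate_set`: a list with `table`
#'   (gene_id, category), `sizes` (named counts for both/first-only/
#'   second-only and the total) and the input `year_labels`.
#' @examples
#' combine_years(c("a", "b", "c"), c("b", "d"))$sizes
#' @export
combine_years <- function(candidates_y1, candidates_y2,
                          year_labels = c("2018", "2019")) {
  c1 <- unique(as.character(candidates_y1))
  c2 <- unique(as.character(candidates_y2))
  both <- intersect(c1, c2)
  only1 <- setdiff(c1, c2)
  only2 <- setdiff(c2, c1)
  table <- data.frame(
    gene_id = c(both, only1, only2),
    category = c(rep("both_years", length(both)),
                 rep("first_year_only", length(only1)),
                 rep("second_year_only", length(only2))),
    stringsAsFactors = FALSE
  )
  sizes <- c(both_years = length(both),
             first_year_only = length(only1),
             second_year_only = length(only2),
             total = length(both) + length(only1) + length(only2))
  structure(list(table = table, sizes = sizes, year_labels = year_labels),
            class = "final_candidate_set")
}

#' @export
print.final_candidate_set <- function(x, ...) {
  cat("Candidate gene set:", x$sizes["total"], "genes\n")
  cat("  both years:        ", x$sizes["both_years"], "\n")
  cat("  ", x$year_labels[1], " only:         ", x$sizes["first_year_only"],
      "\n", sep = "")
  cat("  ", x$year_labels[2], " only:         ", x$sizes["second_year_only"],
      "\n", sep = "")
  invisible(x)
}

#' Filter out candidates with only a small advantage over wild-type
#'
#' Removes genes whose advantage over the wild-type is marginal: a gene is
#' retained only if the median `delta_g` over its events that beat the
#' wild-type is at least `min_delta_g_sd` population standard deviations of
#' g. With `min_delta_g_sd = 0` the filter is the identity; the rule is
#' monotone in the threshold.
#'
#' @param summaries A line-plasticity table for the screened trait/year
#'   with deltas filled.
#' @param candidates Character vector of candidate gene IDs.
#' @param trait_name Trait on which the advantage is measured.
#' @param min_delta_g_sd Threshold in SD-of-g units (default 0.25).
#' @param wildtype_id Wild-type line identifier.
#' @return A list with `genes` (retained gene IDs), `margins` (per-gene
#'   median delta_g of passing events) and `threshold` (the trait-scale
#'   cutoff used).
#' @export
advantage_filter <- function(summaries, candidates, trait_name,
                             min_delta_g_sd = 0.25, wildtype_id = "WT") {
  if (min_delta_g_sd < 0) stop("min_delta_g_sd must be >= 0", call. = FALSE)
  s <- summaries[summaries$trait == trait_name &
                   summaries$line_id != wildtype_id, , drop = FALSE]
  sd_g <- stats::sd(s$g, na.rm = TRUE)
  threshold <- min_delta_g_sd * sd_g
  margins <- vapply(candidates, function(gene) {
    d <- s$delta_g[s$gene_id == gene & s$delta_g > 0]
    if (length(d) == 0) -Inf else stats::median(d)
  }, numeric(1))
  keep <- margins >= threshold
  list(genes = candidates[keep], margins = margins, threshold = threshold)
}

#' Check candidates on supporting traits
#'
#' For each candidate gene, reports the median wild-type-relative genetic
#' value and slope on supporting traits (by default ear length and number
#' of kernels per row, the components of kernel number), flagging genes
#' whose supporting-trait advantage is negative. Genes without a fit for a
#' trait are marked not evaluated.
#'
#' @param summaries A line-plasticity table spanning the supporting traits
#'   with deltas filled.
#' @param candidates Character vector of candidate gene IDs.
#' @param traits Supporting trait names.
#' @param wildtype_id Wild-type line identifier.
#' @return A data frame with one row per candidate x trait: median
#'   `delta_g` and `delta_b` over the gene's events, a logical `flagged`
#'   (negative median delta_g), and `evaluated`.
#' @export
supporting_trait_check <- function(summaries, candidates,
                                   traits = c("ear length",
                                              "number of kernels per row"),
                                   wildtype_id = "WT") {
  s <- summaries[summaries$line_id != wildtype_id, , drop = FALSE]
  out <- expand.grid(gene_id = candidates, trait = traits,
                     stringsAsFactors = FALSE)
  out$delta_g <- NA_real_
  out$delta_b <- NA_real_
  out$evaluated <- FALSE
  for (r in seq_len(nrow(out))) {
    d <- s[s$gene_id == out$gene_id[r] & s$trait == out$trait[r], ,
           drop = FALSE]
    if (nrow(d) > 0 && !all(is.na(d$delta_g))) {
      out$delta_g[r] <- stats::median(d$delta_g, na.rm = TRUE)
      out$delta_b[r] <- stats::median(d$delta_b, na.rm = TRUE)
      out$evaluated[r] <- TRUE
    }
  }
  out$flagged <- out$evaluated & out$delta_g < 0
  out
}
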