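phenotype_columns <- c("line_id", "gene_id", "event_id", "material_class",
                       "year", "site", "block", "trait", "value")

#' Read a long-format phenotype table
#'
#' Reads a CSV with one row per (line, environment, trait) observation and
#' validates the schema. Unparseable numeric cells become missing values and
#' are counted in a warning rather than failing the read.
#'
#' @param path Path to a CSV file with header
#'   `line_id,gene_id,event_id,material_class,year,site,block,trait,value`.
#' @param max_replicates Maximum number of replicate observations allowed
#'   per (line, year, site, block, trait); more raises a validation error.
#' @return A data frame of typed phenotype records.
#' @export
read_phenotypes <- function(path, max_replicates = Inf) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(phenotype_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[phenotype_columns]
  was_na <- is.na(raw$value) | raw$value %in% c("", "NA", "NaN")
  value <- suppressWarnings(as.numeric(raw$value))
  n_bad <- sum(is.na(value) & !was_na)
  if (n_bad > 0 || any(was_na)) {
    warning(sum(is.na(value)), " value cell(s) set to missing (",
            n_bad, " unparseable)", call. = FALSE)
  }
  raw$value <- value
  key <- paste(raw$line_id, raw$year, raw$site, raw$block, raw$trait,
               sep = "\r")
  reps <- table(key)
  if (any(reps > max_replicates)) {
    stop("duplicate observations beyond ", max_replicates,
         " replicates for ", sum(reps > max_replicates), " key(s)",
         call. = FALSE)
  }
  raw
}

#' Write a long-format phenotype table
#'
#' @param records Phenotype records as returned by [simulate_dataset()] or
#'   [read_phenotypes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records[phenotype_columns], path, row.names = FALSE)
  invisible(path)
}

#' Interquartile-range outlier filter
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, the fence rule
#' applied to every trait in the population before plasticity analysis.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile(type = 7)`). Missing values are never flagged.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @param k Fence multiplier (1.5 by default).
#' @return A list with `kept` (values inside the fences, missing values
#'   retained), `removed_idx` (indices of flagged values) and `fences`.
#' @examples
#' filter_outliers_iqr(c(1, 2, 3, 4, 100))$removed_idx # 5
#' @export
filter_outliers_iqr <- function(values, k = 1.5) {
  obs <- !is.na(values)
  if (sum(obs) < 4) stop("need at least 4 non-missing values", call. = FALSE)
  q <- stats::quantile(values[obs], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  out <- obs & (values < fences[1] | values > fences[2])
  list(kept = values[!out], removed_idx = which(out), fences = fences)
}

#' Apply the IQR outlier filter to a phenotype table
#'
#' Filters each group (by default trait within year, i.e. the population a
#' fence is computed over) independently and drops flagged rows.
#'
#' @param records Phenotype records.
#' @param group_by Column names defining the filtering population.
#' @param k Fence multiplier.
#' @return A list with the filtered `records`, `n_removed` and the dropped
#'   rows in `removed`.
#' @export
filter_records_iqr <- function(records, group_by = c("trait", "year"),
                               k = 1.5) {
  key <- interaction(records[group_by], drop = TRUE)
  drop <- logical(nrow(records))
  for (lev in levels(key)) {
    sel <- which(key == lev)
    if (sum(!is.na(records$value[sel])) < 4) next
    res <- filter_outliers_iqr(records$value[sel], k = k)
    drop[sel[res$removed_idx]] <- TRUE
  }
  list(records = records[!drop, , drop = FALSE],
       n_removed = sum(drop),
       removed = records[drop, , drop = FALSE])
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Undefined when the mean is zero.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @param na.rm Drop missing values first.
#' @return The dimensionless CV; negative when the mean is negative (the
#'   sign follows the mean).
#' @examples
#' coefficient_of_variation(c(8, 12)) # ~0.2828
#' @export
coefficient_of_variation <- function(values, na.rm = TRUE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  stats::sd(values) / m
}

#' Per-line CV of a trait across environments
#'
#' Summarises environmental variation per line: for each line and trait,
#' the CV of its (replicate-averaged) values across environments.
#'
#' @param records Phenotype records.
#' @return A data frame with `line_id`, `trait`, `n_env` and `cv`.
#' @export
trait_cv_by_line <- function(records) {
  env <- paste(records$year, records$site, records$block, sep = ":")
  cell <- stats::aggregate(
    value ~ line_id + trait + env,
    data = cbind(records[c("line_id", "trait", "value")], env = env),
    FUN = mean, na.action = stats::na.omit
  )
  out <- do.call(rbind, lapply(
    split(cell, list(cell$line_id, cell$trait), drop = TRUE),
    function(d) {
      cv <- if (nrow(d) >= 2 && mean(d$value) != 0) {
        stats::sd(d$value) / mean(d$value)
      } else NA_real_
      data.frame(line_id = d$line_id[1], trait = d$trait[1],
                 n_env = nrow(d), cv = cv, stringsAsFactors = FALSE)
    }
  ))
  rownames(out) <- NULL
  out
}

#' Trait-by-trait correlation matrix
#'
#' Correlates line-level trait means (each line's average across
#' environments) between all pairs of traits, using pairwise-complete
#' observations so missing cells do not drop whole lines.
#'
#' @param records Phenotype records covering two or more traits.
#' @param method Correlation estimator passed to [stats::cor()].
#' @return A symmetric correlation matrix with unit diagonal; traits with
#'   zero variance get missing rows/columns with a warning.
#' @export
trait_correlation_matrix <- function(records, method = "pearson") {
  line_means <- stats::aggregate(value ~ line_id + trait, data = records,
                                 FUN = mean, na.action = stats::na.omit)
  wide <- stats::reshape(line_means, idvar = "line_id", timevar = "trait",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  if (nrow(m) < 3) stop("need at least 3 lines", call. = FALSE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                    method = method))
  degenerate <- !is.na(sds) & sds == 0
  if (any(degenerate)) {
    warning("zero-variance trait(s): ",
            paste(colnames(m)[degenerate], collapse = ", "), call. = FALSE)
    cc[degenerate, ] <- NA_real_
    cc[, degenerate] <- NA_real_
  }
  d <- diag(cc)
  d[!degenerate] <- 1
  diag(cc) <- d
  (cc + t(cc)) / 2
}
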