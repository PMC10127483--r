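# Impute missing cells of a two-way table with the additive (row + column)
# model, iterated to convergence. Returns the completed matrix and the
# imputed cell indices.
impute_additive <- function(Y, max_iter = 100, tol = 1e-10) {
  miss <- is.na(Y)
  if (!any(miss)) return(list(Y = Y, imputed = which(miss)))
  Yc <- Y
  Yc[miss] <- mean(Y, na.rm = TRUE)
  for (i in seq_len(max_iter)) {
    gm <- mean(Yc)
    fit <- outer(rowMeans(Yc) - gm, rep(1, ncol(Yc))) +
      outer(rep(1, nrow(Yc)), colMeans(Yc) - gm) + gm
    delta <- max(abs(Yc[miss] - fit[miss]))
    Yc[miss] <- fit[miss]
    if (delta < tol) break
  }
  list(Y = Yc, imputed = which(miss))
}

#' Fit the AMMI model to a genotype-by-environment table
#'
#' Additive Main effects and Multiplicative Interaction: the two-way table
#' of cell means is decomposed into grand mean, genotype and environment
#' main effects, and a singular value decomposition of the double-centred
#' interaction matrix. Genotype and environment IPCA scores are scaled by
#' the square root of the singular values, so the outer product of paired
#' score vectors reconstructs each multiplicative term. The AMMI stability
#' value (ASV) summarises each genotype's interaction footprint from the
#' first two IPCA axes, weighting IPCA1 by the ratio of their interaction
#' sums of squares; genotypes with ASV near zero interact little with the
#' environment.
#'
#' @param cell_means Numeric matrix (genotypes x environments) of cell
#'   means; missing cells are imputed with the additive model and flagged.
#' @return An object of class `ammi_fit`: `grand_mean`,
#'   `genotype_effects`, `environment_effects`, `interaction` (the
#'   double-centred matrix), `singular_values`, `genotype_scores`,
#'   `environment_scores`, `asv` (per genotype), `imputed_cells`.
#' @examples
#' y <- outer(c(0, 2, 4), c(-1, 0, 1), "+") + 10
#' fit_ammi(y)$singular_values # ~0: purely additive table
#' @export
fit_ammi <- function(cell_means) {
  Y <- as.matrix(cell_means)
  if (nrow(Y) < 2 || ncol(Y) < 2) {
    stop("need at least 2 genotypes and 2 environments", call. = FALSE)
  }
  imp <- impute_additive(Y)
  Y <- imp$Y
  gm <- mean(Y)
  ge <- rowMeans(Y) - gm
  ee <- colMeans(Y) - gm
  Z <- Y - outer(ge, rep(1, ncol(Y))) - outer(rep(1, nrow(Y)), ee) - gm
  sv <- svd(Z)
  k <- min(nrow(Y), ncol(Y)) - 1L
  d <- sv$d[seq_len(k)]
  gs <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sqrt(d), k)
  es <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sqrt(d), k)
  rownames(gs) <- rownames(Y)
  rownames(es) <- colnames(Y)
  colnames(gs) <- colnames(es) <- paste0("IPCA", seq_len(k))
  if (k >= 2 && d[2] > 0) {
    w <- d[1]^2 / d[2]^2
    asv <- sqrt((w * gs[, 1])^2 + gs[, 2]^2)
  } else {
    asv <- abs(gs[, 1])
  }
  structure(
    list(grand_mean = gm, genotype_effects = ge, environment_effects = ee,
         interaction = Z, singular_values = d,
         genotype_scores = gs, environment_scores = es, asv = asv,
         imputed_cells = imp$imputed),
    class = "ammi_fit"
  )
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit:", length(x$genotype_effects), "genotypes x",
      length(x$environment_effects), "environments\n")
  ss <- x$singular_values^2
  cat("  interaction SS:", format(sum(ss), digits = 6), "\n")
  if (length(ss) >= 2 && sum(ss) > 0) {
    cat("  IPCA1/IPCA2 share:",
        paste(format(100 * ss[1:2] / sum(ss), digits = 3), collapse = "% / "),
        "%\n")
  }
  invisible(x)
}

#' Mean / CV / ASV stability screen against the wild-type
#'
#' For every genotype in a genotype-by-environment table, computes the mean
#' across environments, the CV across environments and the AMMI stability
#' value, and flags genotypes that beat the wild-type: strictly higher
#' mean and no higher CV (and, optionally, no higher ASV). This is the
#' validation screen applied to candidate genes after the plasticity-based
#' selection.
#'
#' @param cell_means Numeric matrix (genotypes x environments).
#' @param wildtype_id Row name of the wild-type reference.
#' @param require_asv Also require `ASV <= ASV_WT` for a pass.
#' @return A data frame with one row per genotype: `mean`, `cv`, `asv`,
#'   logical `pass`.
#' @export
mean_stability_screen <- function(cell_means, wildtype_id = "WT",
                                  require_asv = FALSE) {
  Y <- as.matrix(cell_means)
  if (ncol(Y) < 2) stop("need at least 2 environments", call. = FALSE)
  if (!wildtype_id %in% rownames(Y)) {
    stop("wild-type '", wildtype_id, "' not in table", call. = FALSE)
  }
  fit <- fit_ammi(Y)
  mn <- rowMeans(Y, na.rm = TRUE)
  cv <- apply(Y, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else stats::sd(v) / mean(v)
  })
  wt <- match(wildtype_id, rownames(Y))
  pass <- mn > mn[wt] & cv <= cv[wt]
  if (require_asv) pass <- pass & fit$asv <= fit$asv[wt]
  data.frame(genotype = rownames(Y), mean = mn, cv = cv, asv = fit$asv,
             pass = pass, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype-by-environment table of cell means
#'
#' Averages replicate observations of one trait into a genotype x
#' environment matrix, at line level or aggregated to gene level (averaging
#' a gene's events), ready for [fit_ammi()].
#'
#' @param records Phenotype records.
#' @param trait_name Trait to tabulate.
#' @param level `"line"` or `"gene"`; at gene level the wild-type keeps its
#'   own row.
#' @return A numeric matrix with genotype row names and environment
#'   (`year:site:block`) column names; unobserved cells are `NA`.
#' @export
cell_mean_table <- function(records, trait_name, level = c("line", "gene")) {
  level <- match.arg(level)
  rec <- records[records$trait == trait_name & !is.na(records$value), ,
                 drop = FALSE]
  id <- if (level == "line") rec$line_id else rec$gene_id
  env <- paste(rec$year, rec$site, rec$block, sep = ":")
  agg <- stats::aggregate(rec$value, by = list(id = id, env = env), FUN = mean)
  ids <- sort(unique(agg$id))
  envs <- sort(unique(agg$env))
  Y <- matrix(NA_real_, length(ids), length(envs),
              dimnames = list(ids, envs))
  Y[cbind(match(agg$id, ids), match(agg$env, envs))] <- agg$x
  Y
}
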