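#' Describe a transgenic population and field design
#'
#' A population design specifies how many target genes are in the trial, how
#' many independent transformation events (lines) exist per gene, the mix of
#' overexpression (OE) and CRISPR knockout (Cas9) material, and the field
#' layout. Each (year, site, block) triple is one environment
#' (microenvironment); a single shared wild-type recipient line is always
#' included as the reference.
#'
#' @param n_genes Number of target genes (>= 1).
#' @param events_per_gene Events (independent transgenic lines) per gene:
#'   either a single integer recycled to all genes or an integer vector of
#'   length `n_genes`. Values must lie in 1..10.
#' @param prop_oe Fraction of genes whose events are overexpression lines;
#'   the rest are Cas9 knockouts. Assigned gene-wise.
#' @param years Vector of year labels.
#' @param sites_per_year Number of field sites per year.
#' @param blocks_per_site Number of blocks per site; blocks subdivide sites
#'   into microenvironments.
#' @param replicates Replicate ears measured per line per environment.
#' @param wt_replicates Replicate ears for the wild-type reference per
#'   environment. The shared wild-type is typically planted and measured
#'   far more densely than any single transgenic event, since every
#'   comparison in the population is anchored to it.
#' @param wildtype_id Identifier of the wild-type reference line.
#' @return An object of class `population_design`.
#' @examples
#' d <- population_design(n_genes = 10, events_per_gene = 3)
#' @export
population_design <- function(n_genes,
                              events_per_gene = 3,
                              prop_oe = 0.8,
                              years = c(2018L, 2019L),
                              sites_per_year = 3,
                              blocks_per_site = 2,
                              replicates = 1,
                              wt_replicates = replicates,
                              wildtype_id = "WT") {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  events_per_gene <- as.integer(events_per_gene)
  if (length(events_per_gene) == 1) {
    events_per_gene <- rep(events_per_gene, n_genes)
  }
  if (length(events_per_gene) != n_genes) {
    stop("events_per_gene must have length 1 or n_genes", call. = FALSE)
  }
  if (any(events_per_gene < 1) || any(events_per_gene > 10)) {
    stop("events_per_gene values must lie in 1..10", call. = FALSE)
  }
  if (sites_per_year < 1 || blocks_per_site < 1) {
    stop("sites_per_year and blocks_per_site must be positive", call. = FALSE)
  }
  n_env <- length(years) * sites_per_year * blocks_per_site
  if (n_env < 2) {
    stop("design yields fewer than 2 environments; slopes are unidentifiable",
         call. = FALSE)
  }
  structure(
    list(
      n_genes = n_genes,
      events_per_gene = events_per_gene,
      prop_oe = prop_oe,
      years = years,
      sites_per_year = as.integer(sites_per_year),
      blocks_per_site = as.integer(blocks_per_site),
      replicates = as.integer(replicates),
      wt_replicates = as.integer(wt_replicates),
      wildtype_id = wildtype_id
    ),
    class = "population_design"
  )
}

#' Distribution parameters for the generative Finlay-Wilkinson model
#'
#' The simulator draws each line's genetic value g and slope deviation b
#' from a (possibly correlated) bivariate Gaussian, environment effects h
#' from a centred Gaussian, and residuals from per-line Gaussians. Trait
#' values are then `mu + g_i + (1 + b_i) * h_j + eps_ij`.
#'
#' @param mu Population mean on the trait scale.
#' @param sd_g Standard deviation of the per-line genetic values.
#' @param sd_b Standard deviation of the per-line slope deviations
#'   (dimensionless; the line slope is `1 + b`).
#' @param sd_h Standard deviation of the environment effects.
#' @param sigma Residual standard deviation: a single value shared by all
#'   lines, or a length-2 range from which per-line values are drawn
#'   uniformly.
#' @param rho_gb Correlation between g and b across lines (emulates the
#'   genetic-value/plasticity correlation observed in field populations).
#' @param wt_null If `TRUE` (default) the wild-type line is generated with
#'   g = 0, b = 0 so that wild-type-relative comparisons have a known
#'   anchor; otherwise it is drawn like any other line.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(mu = 450,
                         sd_g = 45,
                         sd_b = 0.3,
                         sd_h = 45,
                         sigma = 15,
                         rho_gb = 0,
                         wt_null = TRUE) {
  if (any(c(sd_g, sd_b, sd_h) < 0) || any(sigma < 0)) {
    stop("distribution scales must be >= 0", call. = FALSE)
  }
  if (!length(sigma) %in% c(1, 2)) {
    stop("sigma must be a scalar or a length-2 range", call. = FALSE)
  }
  if (abs(rho_gb) > 1) stop("rho_gb must lie in [-1, 1]", call. = FALSE)
  structure(
    list(mu = mu, sd_g = sd_g, sd_b = sd_b, sd_h = sd_h, sigma = sigma,
         rho_gb = rho_gb, wt_null = wt_null),
    class = "truth_config"
  )
}

# Line metadata table (one row per line incl. wild-type) for a design.
design_lines <- function(design) {
  gene_ids <- sprintf("G%04d", seq_len(design$n_genes))
  n_oe <- round(design$prop_oe * design$n_genes)
  class_by_gene <- c(rep("OE", n_oe), rep("Cas9", design$n_genes - n_oe))
  gene <- rep(gene_ids, design$events_per_gene)
  cls <- rep(class_by_gene, design$events_per_gene)
  event <- unlist(lapply(design$events_per_gene, seq_len), use.names = FALSE)
  line_id <- paste0(gene, "_E", event)
  rbind(
    data.frame(line_id = line_id, gene_id = gene,
               event_id = paste0("E", event), material_class = cls,
               stringsAsFactors = FALSE),
    data.frame(line_id = design$wildtype_id, gene_id = design$wildtype_id,
               event_id = "E0", material_class = "WT",
               stringsAsFactors = FALSE)
  )
}

# Observation grid (line index x environment index x replicate) honouring
# the per-line replicate counts; the wild-type is the last line.
design_record_grid <- function(design, n_lines, n_env) {
  rep_counts <- rep(design$replicates, n_lines)
  rep_counts[n_lines] <- design$wt_replicates
  data.frame(
    line = rep(seq_len(n_lines), times = rep_counts * n_env),
    env = unlist(lapply(seq_len(n_lines), function(i) {
      rep(seq_len(n_env), each = rep_counts[i])
    }), use.names = FALSE)
  )
}

# Environment table: one row per (year, site, block) microenvironment.
design_environments <- function(design) {
  env <- expand.grid(
    block = paste0("B", seq_len(design$blocks_per_site)),
    site = paste0("S", seq_len(design$sites_per_year)),
    year = design$years,
    stringsAsFactors = FALSE
  )[, c("year", "site", "block")]
  env$env_id <- paste(env$year, env$site, env$block, sep = ":")
  env
}

#' Simulate a multi-environment transgenic trial with known ground truth
#'
#' Generates a long-format phenotype table from the Finlay-Wilkinson
#' generative model `y_ij = mu + g_i + (1 + b_i) h_j + eps_ij`, together
#' with the true parameters used, so that estimators and the screening
#' cascade can be validated against a known answer. Environment effects are
#' centred to sum to zero and slope deviations to mean zero, matching the
#' identifiability constraints of the fitted model.
#'
#' @param design A [population_design()].
#' @param config A [truth_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param trait_name Trait label attached to the records.
#' @param g_shift Optional named numeric vector of per-gene shifts added to
#'   the g of every event of that gene (used to plant signal genes).
#' @param missing_rate Fraction of values set missing completely at random.
#' @return A list with `records` (data frame with columns `line_id`,
#'   `gene_id`, `event_id`, `material_class`, `year`, `site`, `block`,
#'   `trait`, `value`) and `truth` (list with `mu`, per-line table `lines`
#'   holding g, b, sigma, and per-environment table `envs` holding h).
#' @examples
#' sim <- simulate_dataset(population_design(5), truth_config(), seed = 1)
#' head(sim$records)
#' @export
simulate_dataset <- function(design, config = truth_config(), seed,
                             trait_name = "normal kernel number",
                             g_shift = NULL, missing_rate = 0) {
  stopifnot(inherits(design, "population_design"),
            inherits(config, "truth_config"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))

  lines <- design_lines(design)
  envs <- design_environments(design)
  n_lines <- nrow(lines)
  n_env <- nrow(envs)
  if (n_env < 2) stop("fewer than 2 environments", call. = FALSE)

  # correlated (g, b) draws for transgenic lines; wild-type optionally null
  n_t <- n_lines - 1L
  z1 <- stats::rnorm(n_t)
  z2 <- stats::rnorm(n_t)
  g <- config$sd_g * z1
  b <- config$sd_b * (config$rho_gb * z1 + sqrt(1 - config$rho_gb^2) * z2)
  b <- b - mean(b) # transgenic b centred; with WT at 0 the population mean is 0
  if (config$wt_null) {
    g <- c(g, 0)
    b <- c(b, 0)
  } else {
    g <- c(g, stats::rnorm(1, 0, config$sd_g))
    b <- c(b, stats::rnorm(1, 0, config$sd_b))
    b <- b - mean(b)
  }
  if (!is.null(g_shift)) {
    idx <- match(lines$gene_id, names(g_shift))
    g <- g + ifelse(is.na(idx), 0, g_shift[idx])
  }
  sigma <- if (length(config$sigma) == 1) {
    rep(config$sigma, n_lines)
  } else {
    stats::runif(n_lines, config$sigma[1], config$sigma[2])
  }

  # environment effects are design-level: the n_env environments are the
  # complete set for the trial, so centre the draws and standardise their
  # population spread (1/n variance) to equal sd_h exactly
  h <- stats::rnorm(n_env, 0, config$sd_h)
  h <- h - mean(h)
  sd_pop <- sqrt(mean(h^2))
  if (config$sd_h > 0 && sd_pop > 0) {
    h <- h * config$sd_h / sd_pop
  }

  rec <- design_record_grid(design, n_lines, n_env)
  eps <- stats::rnorm(nrow(rec), 0, sigma[rec$line])
  value <- config$mu + g[rec$line] + (1 + b[rec$line]) * h[rec$env] + eps
  records <- data.frame(
    line_id = lines$line_id[rec$line],
    gene_id = lines$gene_id[rec$line],
    event_id = lines$event_id[rec$line],
    material_class = lines$material_class[rec$line],
    year = envs$year[rec$env],
    site = envs$site[rec$env],
    block = envs$block[rec$env],
    trait = trait_name,
    value = value,
    stringsAsFactors = FALSE
  )
  if (missing_rate > 0) {
    drop <- stats::runif(nrow(records)) < missing_rate
    records$value[drop] <- NA_real_
  }

  truth <- list(
    mu = config$mu,
    trait_name = trait_name,
    lines = data.frame(lines, g = g, b = b, sigma = sigma,
                       stringsAsFactors = FALSE),
    envs = data.frame(envs, h = h, stringsAsFactors = FALSE),
    seed = as.integer(seed),
    config = config
  )
  class(truth) <- "synthetic_truth"
  list(records = records, truth = truth)
}

#' Inject artificial outliers into a phenotype table
#'
#' Replaces a fixed fraction of the trait values with values displaced at
#' least `magnitude` interquartile ranges from the trait median, to exercise
#' outlier-filtering steps against a known contamination set.
#'
#' @param records Long-format phenotype records.
#' @param fraction Fraction of records to contaminate; must satisfy
#'   `0 <= fraction < 0.5` (at and beyond 0.5 the quartile-based filter's
#'   semantics break down).
#' @param magnitude Minimum displacement from the median, in IQR units.
#' @param seed Integer seed.
#' @return A list with the modified `records` and `outlier_idx`, the row
#'   indices of the injected outliers.
#' @export
inject_outliers <- function(records, fraction, magnitude = 3, seed) {
  if (fraction < 0 || fraction >= 0.5) {
    stop("fraction must lie in [0, 0.5)", call. = FALSE)
  }
  n <- nrow(records)
  k <- round(fraction * n)
  if (k == 0) return(list(records = records, outlier_idx = integer(0)))
  set.seed(as.integer(seed))
  idx <- sample.int(n, k)
  for (tr in unique(records$trait[idx])) {
    v <- records$value[records$trait == tr]
    med <- stats::median(v, na.rm = TRUE)
    iqr <- stats::IQR(v, na.rm = TRUE)
    if (iqr == 0) iqr <- max(stats::sd(v, na.rm = TRUE), 1)
    sel <- idx[records$trait[idx] == tr]
    disp <- iqr * (magnitude + stats::runif(length(sel)))
    sgn <- sample(c(-1, 1), length(sel), replace = TRUE)
    records$value[sel] <- med + sgn * disp
  }
  list(records = records, outlier_idx = sort(idx))
}

#' Simulate a skewed near-zero "negative-effect" trait
#'
#' Negative-effect indices such as bald tip length, proportion of bald tip
#' area and proportion of empty area are near zero for most ears with a
#' long right tail. This generator produces a zero-inflated exponential
#' trait over the full design grid; proportion traits are clipped to
#' \[0, 1\].
#'
#' @param design A [population_design()].
#' @param zero_inflation Probability that a value is exactly 0.
#' @param seed Integer seed.
#' @param trait_name Trait label; if registered as a proportion trait the
#'   values are clipped to \[0, 1\].
#' @param scale Mean of the non-zero exponential component (trait units).
#' @return A long-format phenotype data frame.
#' @export
simulate_skewed_trait <- function(design, zero_inflation = 0.6, seed,
                                  trait_name = "bald tip length",
                                  scale = 10) {
  stopifnot(inherits(design, "population_design"))
  if (zero_inflation < 0 || zero_inflation > 1) {
    stop("zero_inflation must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lines <- design_lines(design)
  envs <- design_environments(design)
  rec <- design_record_grid(design, nrow(lines), nrow(envs))
  n <- nrow(rec)
  value <- ifelse(stats::runif(n) < zero_inflation, 0,
                  stats::rexp(n, rate = 1 / scale))
  reg <- default_trait_registry()
  kind <- reg$kind[match(trait_name, reg$trait)]
  if (!is.na(kind) && kind == "proportion") {
    value <- pmin(pmax(value, 0), 1)
  }
  data.frame(
    line_id = lines$line_id[rec$line],
    gene_id = lines$gene_id[rec$line],
    event_id = lines$event_id[rec$line],
    material_class = lines$material_class[rec$line],
    year = envs$year[rec$env],
    site = envs$site[rec$env],
    block = envs$block[rec$env],
    trait = trait_name,
    value = value,
    stringsAsFactors = FALSE
  )
}

#' Planted-signal screening experiment
#'
#' Generates the benchmark dataset for end-to-end screening validation: a
#' population in which most genes are true nulls (their lines share the
#' wild-type genetic value, g = 0) and a known subset of "planted" genes
#' whose events all carry a strong positive shift in g. Because the ground
#' truth is binary, sensitivity and specificity of the screening cascade
#' are well defined. Shifts and residual noise are expressed in units of
#' the environment-effect standard deviation, the natural scale of
#' environmental variation for the trait.
#'
#' @param n_genes Total number of genes.
#' @param n_planted Number of planted signal genes (the first
#'   `n_planted` gene IDs).
#' @param events_per_gene Events per gene.
#' @param shift_sd Planted g shift in units of `sd_h`.
#' @param noise_sd Residual standard deviation in units of `sd_h`.
#' @param sd_h Environment-effect standard deviation (trait units).
#' @param sd_b Spread of per-line slope deviations; set to 0 for planted
#'   genes that differ from the wild-type in mean only.
#' @param replicates Ears measured per line per plot; every ear in a plot
#'   is phenotyped, so several replicate ears per environment is the norm.
#' @param wt_replicates Replicate ears for the wild-type reference per
#'   environment; the reference is measured densely so that its estimated
#'   (g, b) anchor is much more precise than any single event's.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [population_design()].
#' @return As [simulate_dataset()], plus `planted`, the planted gene IDs.
#' @export
planted_signal_experiment <- function(n_genes = 200, n_planted = 20,
                                      events_per_gene = 3, shift_sd = 1,
                                      noise_sd = 0.25, sd_h = 45, sd_b = 0.3,
                                      replicates = 5, wt_replicates = 20,
                                      seed, ...) {
  design <- population_design(n_genes, events_per_gene, years = 2018L,
                              replicates = replicates,
                              wt_replicates = wt_replicates, ...)
  config <- truth_config(sd_g = 0, sd_b = sd_b, sd_h = sd_h,
                         sigma = noise_sd * sd_h)
  planted <- sprintf("G%04d", seq_len(n_planted))
  sim <- simulate_dataset(design, config, seed = seed,
                          g_shift = stats::setNames(rep(shift_sd * sd_h,
                                                        n_planted), planted))
  sim$planted <- planted
  sim
}
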