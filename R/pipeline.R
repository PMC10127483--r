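#' Published candidate-gene reference set
#'
#' Loads the packaged table of the 34 published candidate regulatory genes
#' for kernel-number plasticity (material ID, material class, gene ID,
#' chromosome, year category: both years, 2018 only, or 2019 only), and the
#' corresponding [combine_years()] categorisation built from the per-year
#' gene sets it implies.
#'
#' @return A list with `table` (the candidate rows) and `combined` (a
#'   `final_candidate_set` rebuilt from the per-year sets).
#' @examples
#' fx <- make_table2_fixture()
#' fx$combined$sizes
#' @export
make_table2_fixture <- function() {
  path <- system.file("extdata", "table2_candidates.csv",
                      package = "earplast", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  y1 <- tab$gene_id[tab$year_category %in% c("2018", "2018-2019")]
  y2 <- tab$gene_id[tab$year_category %in% c("2019", "2018-2019")]
  list(table = tab,
       combined = combine_years(y1, y2, year_labels = c("2018", "2019")))
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one auditable
#' object. Either `input` (a phenotype CSV path) or `design`+`config` (a
#' simulation) must be given.
#'
#' @param input Optional path to a phenotype CSV.
#' @param design,config Optional [population_design()] and [truth_config()]
#'   for a simulated run.
#' @param traits Traits to fit (first entries should include the primary
#'   and supporting traits present in the data).
#' @param primary_trait Trait the screening cascade runs on.
#' @param estimator `"ols"` or `"bayes"`.
#' @param min_events Minimum events with `g > g_WT` per candidate gene.
#' @param min_delta_g_sd Advantage-filter threshold in SD-of-g units.
#' @param outlier_filter Apply the 1.5 IQR filter per trait and year.
#' @param wildtype_id Wild-type line identifier.
#' @param seed Integer seed for simulation and the Bayesian sampler.
#' @param outdir Output directory for tables and the manifest.
#' @param bayes Settings list for [fit_fw_bayes()] (`n_iter`, `burn_in`,
#'   `thin`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, design = NULL, config = truth_config(),
                       traits = "normal kernel number",
                       primary_trait = "normal kernel number",
                       estimator = c("ols", "bayes"),
                       min_events = 3, min_delta_g_sd = 0.25,
                       outlier_filter = TRUE, wildtype_id = "WT",
                       seed = 1, outdir = tempfile("earplast_run_"),
                       bayes = list(n_iter = 30000, burn_in = 5000,
                                    thin = 5)) {
  estimator <- match.arg(estimator)
  if (is.null(input) && is.null(design)) {
    stop("provide either an input path or a simulation design", call. = FALSE)
  }
  registry <- default_trait_registry()
  if (!primary_trait %in% registry$trait) {
    stop("primary trait '", primary_trait, "' is not in the trait registry",
         call. = FALSE)
  }
  structure(
    list(input = input, design = design, config = config, traits = traits,
         primary_trait = primary_trait, estimator = estimator,
         min_events = min_events, min_delta_g_sd = min_delta_g_sd,
         outlier_filter = outlier_filter, wildtype_id = wildtype_id,
         seed = as.integer(seed), outdir = outdir, bayes = bayes),
    class = "run_config"
  )
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  # the hash captures the analysis, not where its outputs land
  keep <- cfg[setdiff(names(cfg), c("design", "config", "outdir"))]
  keep$design <- if (is.null(cfg$design)) NULL else unclass(cfg$design)
  keep$truth_config <- if (is.null(cfg$config)) NULL else unclass(cfg$config)
  jsonlite::write_json(keep, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(f))
}

write_stage_csv <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the end-to-end plasticity pipeline
#'
#' Executes the stages in order: simulate (or read) the phenotype table,
#' filter outliers, fit the Finlay-Wilkinson model per trait and year,
#' summarise per-line plasticity relative to the wild-type, screen candidate
#' genes per year, combine years, apply the advantage filter, check
#' supporting traits, and validate the final candidates with the
#' mean/CV/ASV stability screen. Every output table is written to the
#' configured directory and listed with an MD5 checksum in the run
#' manifest, which also records the seed and a hash of the configuration;
#' identical configurations reproduce identical outputs.
#'
#' @param cfg A [run_config()].
#' @param simulate_only If `TRUE`, stop after writing the simulated dataset
#'   and its ground truth.
#' @return A list with the candidate sets per stage (`per_year`,
#'   `combined`, `final`), the plasticity `summaries`, the `stability`
#'   screen table, `records`, `truth` (simulated runs only) and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, simulate_only = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] rows in: %d, rows out: %d", stage, n_in, n_out))
  }

  # stage: acquire data
  truth <- NULL
  if (!is.null(cfg$input)) {
    records <- read_phenotypes(cfg$input)
  } else {
    sim <- simulate_dataset(cfg$design, cfg$config, seed = cfg$seed,
                            trait_name = cfg$primary_trait)
    records <- sim$records
    truth <- sim$truth
    files <- c(files, write_stage_csv(records, cfg$outdir, "dataset.csv"))
    files <- c(files, write_stage_csv(truth$lines, cfg$outdir,
                                      "truth_lines.csv"))
    files <- c(files, write_stage_csv(truth$envs, cfg$outdir,
                                      "truth_envs.csv"))
    yaml::write_yaml(
      list(seed = cfg$seed, mu = cfg$config$mu, sd_g = cfg$config$sd_g,
           sd_b = cfg$config$sd_b, sd_h = cfg$config$sd_h,
           sigma = cfg$config$sigma, rho_gb = cfg$config$rho_gb),
      file.path(cfg$outdir, "run_params.yaml")
    )
    files <- c(files, file.path(cfg$outdir, "run_params.yaml"))
  }
  log_stage("acquire", nrow(records), nrow(records))
  if (simulate_only) {
    manifest <- write_manifest(cfg, files)
    return(list(records = records, truth = truth, manifest = manifest))
  }

  # stage: preprocess
  n_in <- nrow(records)
  if (cfg$outlier_filter) {
    filt <- filter_records_iqr(records)
    records <- filt$records
  }
  log_stage("preprocess", n_in, nrow(records))

  # stage: fit per trait and year
  years <- sort(unique(records$year))
  traits <- intersect(cfg$traits, unique(records$trait))
  if (!cfg$primary_trait %in% traits) {
    stop("stage fit: primary trait '", cfg$primary_trait,
         "' absent from data", call. = FALSE)
  }
  summaries <- NULL
  for (tr in traits) {
    for (yr in years) {
      rec_y <- records[records$year == yr, , drop = FALSE]
      fit <- if (cfg$estimator == "bayes") {
        fit_fw_bayes(rec_y, tr, n_iter = cfg$bayes$n_iter,
                     burn_in = cfg$bayes$burn_in, thin = cfg$bayes$thin,
                     seed = cfg$seed)
      } else {
        fit_fw_ols(rec_y, tr)
      }
      summaries <- rbind(summaries, line_plasticity(fit, rec_y, year = yr))
    }
  }
  summaries <- wt_relative(summaries, cfg$wildtype_id)
  summaries <- classify_quadrants(summaries)
  files <- c(files, write_stage_csv(summaries, cfg$outdir,
                                    "plasticity_summaries.csv"))
  log_stage("fit", nrow(records), nrow(summaries))

  # stage: screen per year
  per_year <- lapply(years, function(yr) {
    select_candidates_per_year(
      summaries[summaries$year == yr, , drop = FALSE],
      cfg$primary_trait, wildtype_id = cfg$wildtype_id,
      min_events = cfg$min_events
    )
  })
  names(per_year) <- as.character(years)
  screen_tab <- do.call(rbind, lapply(per_year, `[[`, "table"))
  files <- c(files, write_stage_csv(screen_tab, cfg$outdir,
                                    "gene_screen.csv"))

  # stage: combine years + advantage filter
  if (length(years) >= 2) {
    combined <- combine_years(per_year[[1]]$genes, per_year[[2]]$genes,
                              year_labels = as.character(years[1:2]))
  } else {
    combined <- combine_years(per_year[[1]]$genes, character(0),
                              year_labels = c(as.character(years[1]), ""))
  }
  final_genes <- unique(unlist(lapply(names(per_year), function(yr) {
    adv <- advantage_filter(
      summaries[summaries$year == yr, , drop = FALSE],
      per_year[[yr]]$genes, cfg$primary_trait,
      min_delta_g_sd = cfg$min_delta_g_sd, wildtype_id = cfg$wildtype_id
    )
    adv$genes
  })))
  final <- combined$table[combined$table$gene_id %in% final_genes, ,
                          drop = FALSE]
  files <- c(files, write_stage_csv(final, cfg$outdir,
                                    "final_candidates.csv"))
  log_stage("screen", nrow(screen_tab), nrow(final))

  # stage: supporting traits (when fitted)
  support <- NULL
  support_traits <- setdiff(traits, cfg$primary_trait)
  if (length(support_traits) > 0) {
    support <- supporting_trait_check(summaries, final$gene_id,
                                      traits = support_traits,
                                      wildtype_id = cfg$wildtype_id)
    files <- c(files, write_stage_csv(support, cfg$outdir,
                                      "supporting_traits.csv"))
  }

  # stage: AMMI / mean-CV stability validation at gene level
  gene_records <- records[records$gene_id %in%
                            c(final$gene_id, cfg$wildtype_id), , drop = FALSE]
  stability <- NULL
  if (length(unique(gene_records$gene_id)) >= 2) {
    cm <- cell_mean_table(gene_records, cfg$primary_trait, level = "gene")
    stability <- mean_stability_screen(cm, wildtype_id = cfg$wildtype_id)
    files <- c(files, write_stage_csv(stability, cfg$outdir,
                                      "stability_screen.csv"))
    log_stage("validate", nrow(cm), nrow(stability))
  }

  manifest <- write_manifest(cfg, files)
  list(per_year = per_year, combined = combined, final = final,
       summaries = summaries, stability = stability, support = support,
       records = records, truth = truth, manifest = manifest)
}

write_manifest <- function(cfg, files) {
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    estimator = cfg$estimator,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest$path <- path
  manifest
}
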