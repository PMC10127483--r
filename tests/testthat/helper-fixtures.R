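# Noiseless 2-line x 2-environment fixture built from mu = 10, g = (+1, -1),
# b = (+0.5, -0.5), h = (+2, -2); values solve the model exactly.
two_by_two_fixture <- function() {
  data.frame(
    line_id = rep(c("L1", "L2"), each = 2),
    gene_id = rep(c("G1", "G2"), each = 2),
    event_id = "E1",
    material_class = "OE",
    year = 2018,
    site = rep(c("S1", "S2"), 2),
    block = "B1",
    trait = "normal kernel number",
    value = c(14, 8, 10, 8),
    stringsAsFactors = FALSE
  )
}

# Small long-format records from explicit per-line (g, b) and environment h,
# with WT at (0, 0); deterministic (no residual noise).
records_from_params <- function(g, b, h, mu = 10,
                                trait = "normal kernel number") {
  lines <- names(g)
  envs <- paste0("S", seq_along(h))
  grid <- expand.grid(line = lines, env = envs, stringsAsFactors = FALSE)
  data.frame(
    line_id = grid$line,
    gene_id = grid$line,
    event_id = "E1",
    material_class = ifelse(grid$line == "WT", "WT", "OE"),
    year = 2018,
    site = grid$env,
    block = "B1",
    trait = trait,
    value = mu + g[grid$line] + (1 + b[grid$line]) * h[match(grid$env, envs)],
    stringsAsFactors = FALSE
  )
}

# Plasticity summary table built directly from known parameter vectors.
summary_from_params <- function(line_id, gene_id, g, b,
                                nonlinear = rep(0, length(g)),
                                trait = "normal kernel number",
                                year = 2018) {
  data.frame(
    line_id = line_id, gene_id = gene_id, event_id = "E1",
    material_class = ifelse(line_id == "WT", "WT", "OE"),
    trait = trait, year = year, g = g, b = b, nonlinear = nonlinear,
    stringsAsFactors = FALSE
  )
}
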