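# Small in-code fixtures shared across test files.

toy_y_table <- function(pops, haplogroups, profiles) {
  # profiles: matrix/data.frame of repeat counts, one row per individual
  profiles <- as.data.frame(profiles)
  df <- data.frame(individual_id = sprintf("ind%03d", seq_along(pops)),
                   population_id = pops,
                   y_haplogroup = haplogroups,
                   stringsAsFactors = FALSE)
  df <- cbind(df, profiles)
  genotype_table(df, "Y")
}

toy_mt_table <- function(pops, variant_strings) {
  df <- data.frame(individual_id = sprintf("mt%03d", seq_along(pops)),
                   population_id = pops,
                   mt_haplogroup = "H",
                   hvs_variants = variant_strings,
                   stringsAsFactors = FALSE)
  genotype_table(df, "MT")
}

toy_meta <- function(n, lon = NULL, lat = NULL) {
  data.frame(population_id = sprintf("POP%02d", seq_len(n)),
             group_label = "G",
             latitude = if (is.null(lat)) {
               seq(34, 44, length.out = n) +
                 rep_len(c(-1, 0.8, 0.2, -0.5), n)
             } else lat,
             longitude = if (is.null(lon)) {
               seq(-8, 32, length.out = n)
             } else lon,
             sample_size = 50L,
             stringsAsFactors = FALSE)
}

# a clinal count table with strong, known structure
strong_cline <- function(seed = 5, n_pop = 12, n_per_pop = 200,
                         slopes = c(0.25, -0.25, 0.15, -0.15, 0, 0)) {
  hgs <- paste0("HG", seq_along(slopes))
  base <- c(0.25, 0.2, 0.2, 0.15, 0.1, 0.1)[seq_along(slopes)]
  base <- base / sum(base)
  meta <- toy_meta(n_pop)
  simulate_cline_frequencies(n_pop, hgs, base, slopes,
                             data.frame(latitude = meta$latitude,
                                        longitude = meta$longitude),
                             rep(n_per_pop, n_pop), seed = seed)
}
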