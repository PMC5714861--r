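#' Configuration for the end-to-end analysis pipeline
#'
#' Validates every field up front (before any stage runs) and fixes the
#' study grid: which crossing schemes to simulate, population and map sizes,
#' genotyping noise, the line/marker subsampling grid, and the sizes of the
#' resampling and map-resolution stages. One global seed drives every stage
#' through deterministically derived per-stage seeds.
#'
#' @param schemes Character vector of schemes to run (subset of
#'   dh/ril/ibm/magic).
#' @param n_lines Lines per population.
#' @param n_markers Markers on the shared map.
#' @param total_mb,total_cm Genome totals (Mb / cM).
#' @param n_chromosomes Number of chromosomes.
#' @param missing_rate,error_rate Genotyping noise.
#' @param line_counts,marker_counts Subsampling grid for [resample_bins()]
#'   (defaults trimmed to availability).
#' @param R Resamples per grid cell.
#' @param window_mb Window width for [windowed_recfreq()].
#' @param recfreq_lines Lines sampled for the frequency track.
#' @param n_traits Null traits per scheme in the map-resolution stage.
#' @param mapres_lines Lines per scheme in the map-resolution stage.
#' @param threshold,drop,magic_trait_fraction QTL-calling rules.
#' @param seed Global seed.
#' @param out Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(schemes = c("dh", "ril", "ibm", "magic"),
                       n_lines = 200, n_markers = 2000,
                       total_mb = 2300, total_cm = 1600, n_chromosomes = 10,
                       missing_rate = 0.01, error_rate = 0,
                       line_counts = NULL, marker_counts = NULL, R = 100,
                       window_mb = 2, recfreq_lines = NULL,
                       n_traits = 100, mapres_lines = NULL,
                       threshold = 3, drop = 2, magic_trait_fraction = 0.37,
                       seed = 1L, out = tempfile("recombkit_run_")) {
  schemes <- match.arg(schemes, c("dh", "ril", "ibm", "magic"), several.ok = TRUE)
  if (n_lines < 1) abort("`n_lines` must be at least 1 (validated before any stage runs).")
  if (n_markers < 2 * n_chromosomes) abort("`n_markers` must be >= 2 per chromosome.")
  for (r in c(missing_rate, error_rate)) {
    if (r < 0 || r > 0.05) abort("Noise rates must lie in [0, 0.05].")
  }
  if (is.null(line_counts)) {
    line_counts <- c(50, 100, 150, 200)
    line_counts <- line_counts[line_counts <= n_lines]
    if (!length(line_counts)) line_counts <- n_lines
  }
  if (is.null(marker_counts)) {
    marker_counts <- c(200, 500, 1000, 2000, 5000, 7500, 10000)
    marker_counts <- marker_counts[marker_counts <= n_markers]
    if (!length(marker_counts)) marker_counts <- n_markers
  }
  if (any(line_counts > n_lines)) abort("`line_counts` exceed `n_lines`.")
  if (any(marker_counts > n_markers)) abort("`marker_counts` exceed `n_markers`.")
  if (is.null(recfreq_lines)) recfreq_lines <- min(200, n_lines)
  if (recfreq_lines > n_lines) abort("`recfreq_lines` exceeds `n_lines`.")
  if (is.null(mapres_lines)) mapres_lines <- min(200, n_lines)
  if (mapres_lines > n_lines) abort("`mapres_lines` exceeds `n_lines`.")
  if (R < 1 || n_traits < 1) abort("`R` and `n_traits` must be >= 1.")
  if (threshold <= 0 || drop <= 0) abort("`threshold` and `drop` must be positive.")

  structure(
    list(schemes = schemes, n_lines = n_lines, n_markers = n_markers,
         total_mb = total_mb, total_cm = total_cm, n_chromosomes = n_chromosomes,
         missing_rate = missing_rate, error_rate = error_rate,
         line_counts = line_counts, marker_counts = marker_counts, R = R,
         window_mb = window_mb, recfreq_lines = recfreq_lines,
         n_traits = n_traits, mapres_lines = mapres_lines,
         threshold = threshold, drop = drop,
         magic_trait_fraction = magic_trait_fraction,
         seed = as.integer(seed), out = out),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> genotype -> origin assignment -> breakpoints ->
#' event/segment summaries -> windowed recombination frequency -> bin
#' partition and line/marker resampling -> power-law fits and resolution
#' theory -> map-resolution experiment, writing every artifact under
#' `config$out` and returning a manifest (file, stage, md5 checksum). The
#' manifest and all outputs are byte-identical across reruns with the same
#' configuration.
#'
#' @param config A [run_config()].
#' @return A tibble manifest, invisibly written to `manifest.tsv` as well.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must come from run_config().")
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- withr::with_seed(config$seed, sample.int(1e8, 16L))

  cfg_path <- file.path(out, "config.yaml")
  # the output directory is run metadata, not part of the study conditions
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out")], cfg_path)
  files <- tibble(file = "config.yaml", stage = "config")

  spec <- maize_genome_spec(config$n_chromosomes, config$total_mb, config$total_cm)
  map <- build_genetic_map(spec, config$n_markers, placement = "random",
                           seed = seeds[1L])

  summaries <- list()
  pops <- list()
  origins <- list()
  a_hat <- c()
  for (si in seq_along(config$schemes)) {
    sch <- config$schemes[si]
    founders <- founder_set(map, n_founders = if (sch == "magic") 8L else 2L,
                            seed = seeds[2L])
    pop <- simulate_population(sch, founders, map, spec, config$n_lines,
                               seed = seeds[2L] + si)
    pops[[sch]] <- pop
    geno <- genotype_lines(pop, config$missing_rate, config$error_rate,
                           seed = seeds[3L] + si)
    gpath <- sprintf("%s_genotypes.tsv", sch)
    write_genotype_tsv(geno, file.path(out, gpath))
    files <- bind_rows(files,
                       tibble(file = c(gpath, sub("\\.tsv$", ".founders.tsv", gpath)),
                              stage = "simulate"))

    origin <- if (sch == "magic") {
      infer_founder_mosaic_hmm(geno, error_rate = max(config$error_rate, 0.01))
    } else {
      assign_parental_origin(geno)
    }
    origins[[sch]] <- origin
    bps <- detect_breakpoints(origin, quiet = TRUE)
    bpath <- sprintf("%s_breakpoints.bed", sch)
    write_breakpoints_bed(bps, file.path(out, bpath))
    ev <- events_per_line(bps)
    epath <- sprintf("%s_events.tsv", sch)
    readr::write_tsv(ev, file.path(out, epath))
    files <- bind_rows(files, tibble(file = c(bpath, epath), stage = "breakpoints"))

    summaries[[sch]] <- summarize_events(bps)
    a_hat[sch] <- summaries[[sch]]$mean_events

    track <- windowed_recfreq(bps, spec, window_mb = config$window_mb,
                              n_lines_sample = config$recfreq_lines,
                              seed = seeds[4L] + si)
    rpath <- sprintf("%s_recfreq.bedgraph", sch)
    write_recfreq_bedgraph(track, file.path(out, rpath))
    files <- bind_rows(files, tibble(file = rpath, stage = "recfreq"))

    bins <- build_bin_partition(bps, spec)
    binpath <- sprintf("%s_bins.bed", sch)
    write_bins_bed(bins, file.path(out, binpath))
    files <- bind_rows(files, tibble(file = binpath, stage = "bins"))

    grid <- resample_bins(origin, spec, line_counts = config$line_counts,
                          marker_counts = config$marker_counts, R = config$R,
                          seed = seeds[5L] + si)
    gridpath <- sprintf("%s_bin_resample.tsv", sch)
    readr::write_tsv(grid, file.path(out, gridpath))
    files <- bind_rows(files, tibble(file = gridpath, stage = "resample"))

    fits <- fit_bin_power_laws(grid)
    fitpath <- sprintf("%s_power_law_fits.tsv", sch)
    readr::write_tsv(fits, file.path(out, fitpath))
    files <- bind_rows(files, tibble(file = fitpath, stage = "fits"))
  }

  readr::write_tsv(list_rbind(unname(summaries)), file.path(out, "event_summary.tsv"))
  files <- bind_rows(files, tibble(file = "event_summary.tsv", stage = "stats"))

  theory <- resolution_summary(a_hat, line_counts = config$line_counts,
                               genome_length_mb = config$total_mb)
  readr::write_tsv(theory, file.path(out, "resolution_theory.tsv"))
  files <- bind_rows(files, tibble(file = "resolution_theory.tsv", stage = "theory"))

  mapres <- map_resolution_experiment(
    pops, n_traits = config$n_traits, n_lines = config$mapres_lines,
    threshold = config$threshold, drop = config$drop,
    magic_trait_fraction = config$magic_trait_fraction,
    missing_rate = config$missing_rate, error_rate = config$error_rate,
    seed = seeds[6L]
  )
  readr::write_tsv(mapres, file.path(out, "map_resolution.tsv"))
  files <- bind_rows(files, tibble(file = "map_resolution.tsv", stage = "mapres"))

  manifest <- files
  manifest$md5 <- unname(tools::md5sum(file.path(out, manifest$file)))
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  manifest
}

# Power-law fits of the resampled bin statistics against marker number, one
# per (line count, statistic) with >= 3 marker counts.
fit_bin_power_laws <- function(grid) {
  combos <- distinct(grid[, c("scheme", "n_lines", "stat")])
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- grid[grid$n_lines == combos$n_lines[i] & grid$stat == combos$stat[i], ]
    if (length(unique(sub$n_markers)) < 3L || any(sub$mean <= 0)) next
    fit <- fit_power_law(sub, n_markers, mean)
    td <- tidy(fit)
    rows[[i]] <- tibble(
      scheme = combos$scheme[i], n_lines = combos$n_lines[i],
      stat = combos$stat[i],
      m = td$estimate[1L], n = td$estimate[2L],
      m_se = td$std.error[1L], n_se = td$std.error[2L],
      m_p = td$p.value[1L], n_p = td$p.value[2L],
      rss = glance(fit)$rss, converged = fit$converged
    )
  }
  list_rbind(rows)
}
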