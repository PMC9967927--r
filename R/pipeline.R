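#' Configure an end-to-end analysis run
#'
#' A declarative description of a full run: either a simulated panel (via a
#' [simulation_config()]) or input files, plus every filter threshold and the
#' output directory. The defaults are the thresholds the marker-development
#' workflow prescribes: call-rate retention above 0.95, null-allele class
#' boundaries at 0.05 and 0.20, depth/MAF/call-count discovery filters of
#' 8 reads, 5% and 32-of-48.
#'
#' @param simulation A [simulation_config()], or `NULL` to read inputs.
#' @param vcf,ssr_table,ssr_dialect,population_map Input paths used when
#'   `simulation` is `NULL`.
#' @param call_rate_threshold Call-rate retention threshold.
#' @param apply_discovery_filter Run [filter_variants()] on the SNP panel?
#' @param min_depth,min_maf,min_called Discovery-filter thresholds.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed recorded in the manifest (the simulation carries its own).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            vcf = NULL, ssr_table = NULL,
                            ssr_dialect = "genepop", population_map = NULL,
                            call_rate_threshold = 0.95,
                            apply_discovery_filter = FALSE,
                            min_depth = 8, min_maf = 0.05, min_called = 32,
                            out_dir = tempfile("markerdiv_run_"),
                            seed = if (!is.null(simulation)) simulation$seed else 1L) {
  if (is.null(simulation) && (is.null(vcf) || is.null(population_map))) {
    stop("either a simulation config or input paths (vcf + population_map) are required")
  }
  structure(
    list(simulation = simulation, vcf = vcf, ssr_table = ssr_table,
         ssr_dialect = ssr_dialect, population_map = population_map,
         call_rate_threshold = call_rate_threshold,
         apply_discovery_filter = apply_discovery_filter,
         min_depth = min_depth, min_maf = min_maf, min_called = min_called,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Composes the stages in workflow order: acquire the panel (simulate or
#' read), apply the call-rate filter (and optionally the discovery hard
#' filter to the SNP panel), compute per-marker and per-population diversity
#' tables, estimate and correct null alleles on the SSR panel, and build the
#' Nei distance matrices, UPGMA phenograms and PCA for each marker system.
#' All tables are written as TSV, the phenograms as Newick, and a JSON run
#' manifest records the seed, thresholds and analysis conventions in effect,
#' so a run is auditable and reproducible. Two runs with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed objects (`matrix`, `popmap`,
#'   `marker_table`, `population_tables`, `null_table`, `distances`, `trees`,
#'   `ordinations`, `filter_reports`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    sim <- simulate_panel(config$simulation)
    gm <- sim$matrix
    popmap <- sim$popmap
  } else {
    gm <- read_snp_vcf(config$vcf)
    popmap <- read_population_map(config$population_map)
    if (!is.null(config$ssr_table)) {
      ssr <- read_ssr_table(config$ssr_table, dialect = config$ssr_dialect)
      gm <- geno_matrix(dplyr::bind_rows(gm$calls, ssr$calls),
                        loci = dplyr::bind_rows(gm$loci, ssr$loci),
                        individuals = union(gm$individuals, ssr$individuals))
    }
  }

  reports <- list()
  if (config$apply_discovery_filter && any(gm$loci$kind == "SNP")) {
    snp <- filter_kind(gm, "SNP")
    fv <- filter_variants(snp, min_depth = config$min_depth,
                          min_maf = config$min_maf, min_called = config$min_called)
    reports$variant_hard_filter <- fv$report
    keep <- c(fv$matrix$loci$locus, gm$loci$locus[gm$loci$kind == "SSR"])
    gm <- select_loci(gm, keep)
  }
  fc <- filter_call_rate(gm, config$call_rate_threshold)
  reports$call_rate <- fc$report
  gm <- fc$matrix
  if (n_loci(gm) == 0) stop("stage call_rate: no locus survived filtering")

  kinds <- intersect(c("SNP", "SSR"), unique(gm$loci$kind))
  marker_summaries <- locus_summary(gm)
  null_table <- if ("SSR" %in% kinds) null_allele_table(gm) else NULL
  marker_table <- if ("SSR" %in% kinds) {
    render_marker_table(marker_summaries[marker_summaries$kind == "SSR", ], null_table)
  } else NULL

  population_tables <- lapply(stats::setNames(kinds, kinds), function(kd) {
    population_summary_table(filter_kind(gm, kd), popmap,
                             adjust_null = kd == "SSR")
  })
  distances <- lapply(stats::setNames(kinds, kinds), function(kd) {
    distance_matrix(filter_kind(gm, kd), popmap)
  })
  trees <- lapply(distances, upgma)
  ordinations <- lapply(stats::setNames(kinds, kinds), function(kd) {
    pca(filter_kind(gm, kd), popmap)
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wtsv <- function(tbl, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
  }
  if (!is.null(marker_table)) wtsv(marker_table, "marker_table.tsv")
  if (!is.null(null_table)) {
    wtsv(dplyr::select(null_table, -"adjusted_frequencies"), "null_alleles.tsv")
  }
  for (kd in kinds) {
    wtsv(render_population_table(population_tables[[kd]]),
         paste0("population_table_", tolower(kd), ".tsv"))
    dm <- distances[[kd]]
    wtsv(cbind(population = rownames(dm$values), as.data.frame(round(dm$values, 6))),
         paste0("distance_", tolower(kd), ".tsv"))
    tp <- file.path(config$out_dir, paste0("phenogram_", tolower(kd), ".nwk"))
    write_newick(trees[[kd]], tp)
    files[[basename(tp)]] <- tp
    wtsv(ordinations[[kd]]$scores |>
           dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6))),
         paste0("pca_", tolower(kd), ".tsv"))
  }
  for (nm in names(reports)) {
    rp <- reports[[nm]]
    wtsv(tibble::tibble(stage = rp$stage, n_in = rp$n_in, n_out = rp$n_out),
         paste0("filter_", nm, "_counts.tsv"))
    wtsv(rp$removed, paste0("filter_", nm, "_removed.tsv"))
  }
  manifest <- list(
    package = "markerdiv",
    version = as.character(utils::packageVersion("markerdiv")),
    seed = config$seed,
    thresholds = list(call_rate = config$call_rate_threshold,
                      min_depth = config$min_depth, min_maf = config$min_maf,
                      min_called = config$min_called,
                      naf_classes = c(negligible = 0.05, large = 0.20)),
    conventions = list(
      he_correction = "none (plain 1 - sum p^2)",
      fis_aggregation = "unweighted mean of per-locus Fis over loci with He > 0",
      tm_formula = "64.9 + 41 * (GC - 16.4) / length",
      upgma_tie_break = "smallest (row, column) label order",
      ld_collapse = "major-allele dosage per locus",
      pca_missing = "per-column mean imputation, centred, unscaled",
      rounding = "4 decimals, round-half-even"
    )
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files[["manifest.json"]] <- mp

  invisible(list(matrix = gm, popmap = popmap,
                 marker_table = marker_table,
                 marker_summaries = marker_summaries,
                 population_tables = population_tables,
                 null_table = null_table,
                 distances = distances, trees = trees,
                 ordinations = ordinations,
                 filter_reports = reports, files = files))
}

#' Render a publication-shaped per-marker table
#'
#' Formats per-marker summaries (plus optional null-allele estimates) with
#' marker rows followed by unweighted `Mean` and sample (n-1) standard
#' deviation rows, all numerics printed to 4 decimals with round-half-even.
#'
#' @param summaries A [locus_summary()] tibble.
#' @param null_estimates Optional [null_allele_table()] tibble; contributes
#'   the NAF column.
#' @return A character tibble with columns `marker`, `maf`, `n_alleles`,
#'   `n_genotypes`, `he`, `ho`, `pic` (and `naf`), plus `Mean` and
#'   `Standard deviation` rows.
#' @export
render_marker_table <- function(summaries, null_estimates = NULL) {
  stat_cols <- intersect(c("maf", "n_alleles", "n_genotypes", "he", "ho", "pic"),
                         names(summaries))
  tbl <- dplyr::select(summaries, marker = "locus", dplyr::all_of(stat_cols))
  if (!is.null(null_estimates)) {
    tbl <- dplyr::left_join(
      tbl, dplyr::select(null_estimates, marker = "locus", "naf"),
      by = "marker"
    )
  }
  num_cols <- setdiff(names(tbl), "marker")
  fmt <- function(v) formatC(round(v, 4), format = "f", digits = 4)
  body <- dplyr::mutate(tbl, dplyr::across(dplyr::all_of(num_cols), fmt))
  mean_row <- c(marker = "Mean", vapply(tbl[num_cols], function(v) fmt(mean(v)), character(1)))
  sd_row <- c(marker = "Standard deviation",
              vapply(tbl[num_cols], function(v) {
                if (length(v) < 2) "" else fmt(stats::sd(v))
              }, character(1)))
  dplyr::bind_rows(body, tibble::as_tibble_row(mean_row), tibble::as_tibble_row(sd_row))
}

#' Render a per-population summary table
#'
#' @param pop_table A [population_summary_table()] tibble.
#' @return A character tibble formatted to 4 decimals (round-half-even).
#' @export
render_population_table <- function(pop_table) {
  num_cols <- setdiff(names(pop_table), c("population", "n"))
  fmt <- function(v) ifelse(is.na(v), "", formatC(round(v, 4), format = "f", digits = 4))
  dplyr::mutate(pop_table,
                n = ifelse(is.na(.data$n), "", as.character(.data$n)),
                dplyr::across(dplyr::all_of(num_cols), fmt))
}
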