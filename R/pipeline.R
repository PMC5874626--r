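#' Write a synthetic dataset bundle to CSV files
#'
#' Writes the tables of a [generate_scenario()] bundle in the CSV dialects
#' the pipeline reads (comma-separated, UTF-8, header row, '.' decimal,
#' floats at 6 significant digits), a `truth.json` serialization of the
#' ground truth, and a `manifest.json` with configuration echo, seeds and
#' per-file MD5 checksums. Re-running with the same configuration reproduces
#' identical checksums.
#'
#' @param scenario a `"nitroflood_scenario"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
simulate_dataset <- function(scenario, dir) {
  stopifnot(inherits(scenario, "nitroflood_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- scenario$bundle
  files <- c(fluxes = "fluxes.csv", jars = "jars.csv",
             porewater = "porewater.csv", peaks = "peaks.csv",
             qpcr = "qpcr.csv", standards = "standards.csv",
             metadata = "metadata.csv")
  for (nm in names(files))
    write_csv_sig(b[[nm]], file.path(dir, files[[nm]]))
  tr <- scenario$truth
  truth_json <- list(
    seed = tr$config$seed,
    budget = tr$budget,
    volumetric_rates = tr$volumetric_rates,
    inventories = tr$inventories,
    otu_modules = as.list(tr$otu_modules),
    otu_centroids = as.list(tr$otu_centroids),
    gene_copies = tr$gene_copies)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- run_manifest(dir, file.path(dir, files),
                           config = unclass(tr$config)[
                             !vapply(unclass(tr$config), is.matrix, logical(1))],
                           seed = tr$config$seed, stage = "simulate")
  invisible(manifest)
}

#' Read a dataset bundle from a directory of CSVs
#'
#' @param dir directory written by [simulate_dataset()] (or hand-assembled
#'   with the same schemas).
#' @return List of data.frames (`fluxes`, `jars`, `porewater`, `peaks`,
#'   `qpcr`, `standards`, `metadata`; missing optional files are `NULL`).
#' @export
read_dataset <- function(dir) {
  rd <- function(f, cols) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    require_columns(df, cols, f)
    df
  }
  list(
    fluxes = rd("fluxes.csv", c("core_id", "station", "day", "analyte",
                                "c_start_uM", "c_end_uM", "volume_L",
                                "area_m2", "duration_d")),
    jars = rd("jars.csv", c("station", "time_point", "depth_top_cm",
                            "depth_bottom_cm", "day", "nh4_uM", "porosity")),
    porewater = rd("porewater.csv", c("station", "time_point", "depth_top_cm",
                                      "depth_bottom_cm", "analyte", "conc_mM",
                                      "porosity")),
    peaks = rd("peaks.csv", c("sample_id", "size_bp", "area")),
    qpcr = rd("qpcr.csv", c("sample_id", "gene", "cq_rep1", "cq_rep2",
                            "template_uL", "elution_uL", "wet_mass_g",
                            "water_content")),
    standards = rd("standards.csv", c("gene", "copies", "cq")),
    metadata = rd("metadata.csv", "sample_id"))
}

#' Run the nitrogen-budget stage
#'
#' Thin orchestration over [estimate_nitrogen_budgets()]: accepts either a
#' bundle directory or in-memory tables, writes `budget.csv` when an output
#' directory is given, and never drops an incomplete budget silently (the
#' `incomplete` column flags it).
#'
#' @param input a directory path or a list with `fluxes`, `jars`,
#'   `porewater`.
#' @param out_dir optional output directory for `budget.csv` + manifest.
#' @param alpha jar-regression significance level.
#' @return The `"nitrogen_budget_table"` data.frame.
#' @export
run_budget <- function(input, out_dir = NULL, alpha = 0.05) {
  tabs <- if (is.character(input)) read_dataset(input) else input
  budget <- estimate_nitrogen_budgets(tabs$fluxes, tabs$jars, tabs$porewater,
                                      alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "budget.csv")
    write_csv_sig(as.data.frame(budget), path)
    run_manifest(out_dir, path, config = list(alpha = alpha),
                 stage = "budget")
  }
  budget
}

#' Run the community stage end-to-end
#'
#' Executes size filter -> noise filter -> binning -> standardization ->
#' singleton/1% filter -> log transform -> Bray-Curtis -> UPGMA clustering,
#' NMDS, PERMANOVA, optional environmental vector fit, sharing counts and
#' module detection, writing every intermediate table when `out_dir` is
#' given. With fewer than 3 samples the statistics stages are skipped with
#' an explicit notice in the returned `skipped` element.
#'
#' @param peaks peak table or bundle directory.
#' @param metadata sample metadata (`sample_id`, `station`, `time_point`,
#'   `depth_band`, ...); taken from the bundle when `peaks` is a directory.
#' @param config a [trflp_config()].
#' @param env optional data.frame of environmental variables per sample for
#'   vector fitting.
#' @param formula PERMANOVA formula (default `~ station + time_point`).
#' @param k,n_restarts,n_perm,seed ordination and permutation settings.
#' @param n_modules modules for OTU abundance-pattern detection.
#' @param out_dir optional output directory.
#' @return List with the OTU tables, distance matrix, clustering, NMDS,
#'   PERMANOVA, vector fit, sharing counts, module map and stage log.
#' @export
run_community <- function(peaks, metadata = NULL, config = trflp_config(),
                          env = NULL, formula = ~ station + time_point,
                          k = 2, n_restarts = 20, n_perm = 999, seed = 1,
                          n_modules = 4, out_dir = NULL) {
  if (is.character(peaks)) {
    tabs <- read_dataset(peaks)
    metadata <- metadata %||% tabs$metadata
    peaks <- tabs$peaks
  }
  tr <- run_trflp(peaks, config)
  tab <- tr$log
  skipped <- character(0)
  d <- hc <- ord <- pmv <- vf <- mods <- NULL
  if (nrow(tab$abundance) < 3) {
    skipped <- c(skipped,
                 "fewer than 3 samples: distance/ordination/PERMANOVA skipped")
  } else {
    d <- bray_curtis(tab)
    hc <- hierarchical_cluster(d)
    ord <- nmds(d, k = k, n_restarts = n_restarts, seed = seed)
    if (!is.null(metadata)) {
      md <- metadata[match(rownames(tab$abundance), metadata$sample_id), ,
                     drop = FALSE]
      vars <- all.vars(formula)
      usable <- vars[vapply(vars, function(v)
        v %in% names(md) && !anyNA(md[[v]]) &&
          length(unique(md[[v]])) >= 2, logical(1))]
      if (length(usable) == length(vars)) {
        pmv <- permanova(d, formula, md, n_perm = n_perm, seed = seed)
      } else skipped <- c(skipped, "PERMANOVA skipped: unusable factor(s)")
      if (!is.null(env)) {
        ev <- env[match(rownames(tab$abundance), env$sample_id), ,
                  drop = FALSE]
        vf <- fit_env_vectors(ord, ev[setdiff(names(ev), "sample_id")],
                              n_perm = n_perm, seed = seed)
      }
    }
    if (ncol(tab$abundance) >= max(2, n_modules))
      mods <- detect_modules(tab, k = n_modules)
  }
  share <- NULL
  if (!is.null(metadata) && "station" %in% names(metadata)) {
    md <- metadata[match(rownames(tab$abundance), metadata$sample_id), ]
    groups <- split(rownames(tab$abundance), md$station)
    if (length(groups) >= 2) {
      share <- sharing_counts(lapply(groups, function(ids)
        colnames(tab$abundance)[colSums(
          tab$abundance[ids, , drop = FALSE] > 0) > 0]))
    }
  }
  log_lines <- sprintf("stage=%s rows_in=%d rows_out=%d",
                       c("size_filter", "noise_filter", "binning",
                         "otu_filter"),
                       c(tr$counts[["input"]], tr$counts[["in_window"]],
                         tr$counts[["signal"]], tr$counts[["otus_binned"]]),
                       c(tr$counts[["in_window"]], tr$counts[["signal"]],
                         tr$counts[["otus_binned"]],
                         tr$counts[["otus_retained"]]))
  out <- list(trflp = tr, otu_table = tab, distance = d, clustering = hc,
              nmds = ord, permanova = pmv, env_vectors = vf,
              sharing = share, modules = mods, skipped = skipped,
              log = log_lines, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    w <- function(df, f) {
      p <- file.path(out_dir, f); write_csv_sig(df, p); paths <<- c(paths, p)
    }
    ab <- tab$abundance
    w(data.frame(sample_id = rownames(ab),
                 as.data.frame(signif(ab, 6)), check.names = FALSE),
      "otu_table_log.csv")
    w(tab$otus, "otu_info.csv")
    if (!is.null(tab$removed)) w(tab$removed, "otu_removed.csv")
    if (!is.null(d)) w(data.frame(sample_id = rownames(d),
                                  as.data.frame(signif(unclass(d), 6)),
                                  check.names = FALSE), "bray_curtis.csv")
    if (!is.null(ord)) w(data.frame(sample_id = rownames(ord$points),
                                    ord$points, stress = ord$stress),
                         "nmds_scores.csv")
    if (!is.null(pmv)) w(pmv$table, "permanova.csv")
    if (!is.null(vf)) w(vf$vectors, "env_vectors.csv")
    if (!is.null(share)) w(share, "sharing_counts.csv")
    if (!is.null(mods)) w(data.frame(otu = names(mods), module = mods),
                          "modules.csv")
    writeLines(log_lines, file.path(out_dir, "community.log"))
    run_manifest(out_dir, paths, config = unclass(config), seed = seed,
                 stage = "community")
  }
  out
}

#' Write a run manifest with checksums
#'
#' Records a configuration snapshot, package version, seeds, timestamps and
#' MD5 checksums of the stage's output files; deterministic stages re-run
#' with an identical manifest reproduce identical checksums.
#'
#' @param dir directory in which to write `manifest.json` (`manifest_<stage>`
#'   when a stage is given).
#' @param files files to checksum.
#' @param config configuration snapshot (list).
#' @param seed seed(s) used.
#' @param stage stage label.
#' @return Invisibly, the manifest list.
#' @export
run_manifest <- function(dir, files, config = list(), seed = NULL,
                         stage = "run") {
  sums <- tools::md5sum(files)
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("nitroflood")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, config = config,
                   checksums = as.list(sums))
  jsonlite::write_json(manifest,
                       file.path(dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
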