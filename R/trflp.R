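#' Configuration for the T-RFLP fragment-to-OTU pipeline
#'
#' @param size_min,size_max fragment-size window in bp (closed interval,
#'   defaults 50 and 550).
#' @param noise_factor multiplier of the iterative zero-mean RMS threshold
#'   used by the peak-area noise filter (default 1.15).
#' @param cluster_threshold single-linkage gap (bp) above which a new OTU bin
#'   starts when aligning fragments across samples (default 0.6).
#' @param min_total_abundance OTUs whose mean per-sample relative abundance
#'   falls below this fraction are filtered out (default 0.01, i.e. 1%).
#' @param abundance_rule how "total abundance" is measured: `"mean"` (mean
#'   per-sample relative abundance, default), `"grand_total"` (summed share
#'   of the whole table) or `"max"` (per-sample maximum).
#' @param singleton_min_samples OTUs present in fewer samples than this are
#'   filtered as singletons (default 2).
#' @param sigma_estimator `"rms"` (zero-mean root mean square, default) or
#'   `"sd"` (sample standard deviation) for the noise filter.
#' @param log_scale multiplier applied to relative abundances before the
#'   log(1 + x) transform (default 100, i.e. percentage scale).
#' @return A list of class `"trflp_config"`.
#' @export
trflp_config <- function(size_min = 50, size_max = 550, noise_factor = 1.15,
                         cluster_threshold = 0.6, min_total_abundance = 0.01,
                         abundance_rule = c("mean", "grand_total", "max"),
                         singleton_min_samples = 2,
                         sigma_estimator = c("rms", "sd"),
                         log_scale = 100) {
  if (size_min >= size_max) stop_input("size_min must be < size_max")
  check_number(noise_factor, "noise_factor", 0, strict_lower = TRUE)
  check_number(cluster_threshold, "cluster_threshold", 0, strict_lower = TRUE)
  check_number(min_total_abundance, "min_total_abundance", 0, 1,
               strict_upper = TRUE)
  structure(list(size_min = size_min, size_max = size_max,
                 noise_factor = noise_factor,
                 cluster_threshold = cluster_threshold,
                 min_total_abundance = min_total_abundance,
                 abundance_rule = match.arg(abundance_rule),
                 singleton_min_samples = singleton_min_samples,
                 sigma_estimator = match.arg(sigma_estimator),
                 log_scale = log_scale),
            class = "trflp_config")
}

check_peaks <- function(peaks) {
  require_columns(peaks, c("sample_id", "size_bp", "area"), "peak table")
  if (any(peaks$area <= 0)) stop_input("peak areas must be > 0")
  if (any(peaks$size_bp <= 0)) stop_input("fragment sizes must be > 0")
  peaks
}

#' Restrict peaks to the instrument size window
#'
#' Keeps peaks with `size_min <= size <= size_max` (closed interval).
#'
#' @param peaks data.frame with `sample_id`, `size_bp`, `area`.
#' @param config a [trflp_config()].
#' @return The filtered peak table (possibly empty).
#' @export
filter_size_range <- function(peaks, config = trflp_config()) {
  if (nrow(peaks) == 0) return(peaks)
  check_peaks(peaks)
  peaks[peaks$size_bp >= config$size_min & peaks$size_bp <= config$size_max, ,
        drop = FALSE]
}

#' Iterative peak-area noise filtration for one sample
#'
#' Separates signal from baseline noise by the iterative threshold procedure:
#' starting with every peak unclassified (the noise set), compute sigma as
#' the zero-mean RMS of the noise-set areas, promote to signal every peak
#' with area > `noise_factor` x sigma, and repeat on the shrunken noise set
#' until no peak is promoted. The procedure converges in at most n passes
#' (peaks only ever leave the noise set) and is invariant to input order. A
#' sample may end with zero signal peaks (e.g. all areas equal), which is
#' flagged rather than an error.
#'
#' @param peaks peak table of a single sample.
#' @param config a [trflp_config()].
#' @return List with `signal` and `noise` peak tables, `iterations`, and
#'   `all_noise` flag.
#' @export
filter_noise <- function(peaks, config = trflp_config()) {
  check_peaks(peaks)
  if (nrow(peaks) == 0) stop_input("at least one peak is required")
  if (length(unique(peaks$sample_id)) > 1)
    stop_input("filter_noise operates on one sample at a time")
  area <- peaks$area
  signal <- logical(length(area))
  iterations <- 0L
  repeat {
    noise_areas <- area[!signal]
    sigma <- if (config$sigma_estimator == "rms")
      sqrt(mean(noise_areas^2)) else stats::sd(noise_areas)
    if (is.na(sigma)) break  # single remaining peak under "sd"
    promote <- !signal & area > config$noise_factor * sigma
    iterations <- iterations + 1L
    if (!any(promote)) break
    signal <- signal | promote
  }
  list(signal = peaks[signal, , drop = FALSE],
       noise = peaks[!signal, , drop = FALSE],
       iterations = iterations,
       all_noise = !any(signal))
}

#' Align fragments across samples into OTU bins
#'
#' Sorts all (noise-filtered) fragment observations by size and applies
#' single-linkage chaining: a new OTU bin starts whenever the gap to the
#' previous observation exceeds `cluster_threshold` bp. Each bin becomes an
#' OTU with an area-weighted mean centroid size; multiple peaks of the same
#' sample falling into one bin have their areas summed.
#'
#' @param peaks combined peak table of all samples (post noise filtering).
#' @param config a [trflp_config()].
#' @return An object of class `"trf_otu_table"`: list with `abundance`
#'   (samples x OTUs matrix of raw areas), `otus` (id, centroid_bp,
#'   size_min_bp, size_max_bp, n_members), `samples`, and `state = "raw"`.
#' @export
bin_fragments <- function(peaks, config = trflp_config()) {
  check_peaks(peaks)
  if (nrow(peaks) == 0) stop_input("no peaks to bin")
  ord <- order(peaks$size_bp)
  p <- peaks[ord, , drop = FALSE]
  newbin <- c(TRUE, diff(p$size_bp) > config$cluster_threshold)
  bin <- cumsum(newbin)
  samples <- sort(unique(p$sample_id))
  n_otu <- max(bin)
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otu))
  mat <- matrix(0, length(samples), n_otu,
                dimnames = list(samples, otu_ids))
  centroid <- smin <- smax <- nmem <- numeric(n_otu)
  for (b in seq_len(n_otu)) {
    sel <- bin == b
    centroid[b] <- sum(p$size_bp[sel] * p$area[sel]) / sum(p$area[sel])
    smin[b] <- min(p$size_bp[sel]); smax[b] <- max(p$size_bp[sel])
    nmem[b] <- sum(sel)
    a <- tapply(p$area[sel], p$sample_id[sel], sum)
    mat[names(a), b] <- a
  }
  structure(list(
    abundance = mat,
    otus = data.frame(id = otu_ids, centroid_bp = centroid,
                      size_min_bp = smin, size_max_bp = smax,
                      n_members = nmem, stringsAsFactors = FALSE),
    samples = samples, state = "raw"),
    class = "trf_otu_table")
}

#' @export
print.trf_otu_table <- function(x, ...) {
  cat(sprintf("T-RFLP OTU table (%s): %d samples x %d OTUs\n",
              x$state, nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$removed))
    cat(sprintf("  %d OTUs removed by filtering\n", nrow(x$removed)))
  invisible(x)
}

#' Standardize an OTU table to relative abundance
#'
#' Divides each sample row by its total area so rows sum to 1.
#'
#' @param table a raw-state `"trf_otu_table"`.
#' @return The table in `"relative"` state.
#' @export
standardize_relative <- function(table) {
  stopifnot(inherits(table, "trf_otu_table"))
  if (table$state != "raw") stop_input("table is already standardized")
  tot <- rowSums(table$abundance)
  if (any(tot <= 0))
    stop_input("sample(s) with zero total area: ",
               paste(rownames(table$abundance)[tot <= 0], collapse = ", "))
  table$abundance <- sweep(table$abundance, 1, tot, "/")
  table$state <- "relative"
  table
}

#' Remove singleton and low-abundance OTUs
#'
#' Removes OTUs present (nonzero) in fewer than `singleton_min_samples`
#' samples, and OTUs whose overall relative abundance (by the configured
#' rule, default the mean per-sample relative abundance) is below
#' `min_total_abundance`. Rows are deliberately not re-normalized after
#' filtering, so retained entries keep their original relative scale.
#'
#' @param table a relative-state `"trf_otu_table"`.
#' @param config a [trflp_config()].
#' @return The filtered table; removed OTUs and the reason are recorded in
#'   `$removed`.
#' @export
filter_otus <- function(table, config = trflp_config()) {
  stopifnot(inherits(table, "trf_otu_table"))
  if (table$state != "relative")
    stop_input("filter_otus expects a relative-abundance table")
  m <- table$abundance
  presence <- colSums(m > 0)
  overall <- switch(config$abundance_rule,
                    mean = colMeans(m),
                    grand_total = colSums(m) / sum(m),
                    max = apply(m, 2, max))
  singleton <- presence < config$singleton_min_samples
  low <- overall < config$min_total_abundance
  drop <- singleton | low
  if (all(drop)) stop_input("all OTUs removed by filtering (degenerate table)")
  removed <- data.frame(
    id = colnames(m)[drop],
    reason = ifelse(singleton[drop] & low[drop], "singleton+low_abundance",
                    ifelse(singleton[drop], "singleton", "low_abundance")),
    n_samples_present = presence[drop],
    overall_abundance = overall[drop],
    stringsAsFactors = FALSE)
  table$abundance <- m[, !drop, drop = FALSE]
  table$otus <- table$otus[!drop, , drop = FALSE]
  table$removed <- rbind(table$removed, removed)
  table
}

#' Log-transform relative abundances
#'
#' Maps each relative abundance x to log(1 + `log_scale` * x) (default
#' percentage-scale, ln(1 + 100x)), which is zero-preserving and monotone.
#'
#' @param table a relative-state `"trf_otu_table"`.
#' @param config a [trflp_config()].
#' @return The table in `"log"` state.
#' @export
log_transform <- function(table, config = trflp_config()) {
  stopifnot(inherits(table, "trf_otu_table"))
  if (table$state != "relative")
    stop_input("log_transform expects a relative-abundance table")
  if (any(table$abundance < 0)) stop_input("negative abundances")
  table$abundance <- log1p(config$log_scale * table$abundance)
  table$state <- "log"
  table
}

#' Run the complete fragment-to-OTU pipeline
#'
#' Size-window gating, per-sample iterative noise filtration, cross-sample
#' single-linkage binning, relative-abundance standardization,
#' singleton/low-abundance OTU filtering and log transformation, with
#' per-stage bookkeeping.
#'
#' @param peaks peak table (`sample_id`, `size_bp`, `area`).
#' @param config a [trflp_config()].
#' @param filter_low_abundance apply the singleton/1% OTU filter (default
#'   TRUE).
#' @return List with the `raw`, `relative` and `log` state tables, the noise
#'   partition per sample, per-stage counts, and samples flagged all-noise.
#' @export
run_trflp <- function(peaks, config = trflp_config(),
                      filter_low_abundance = TRUE) {
  check_peaks(peaks)
  gated <- filter_size_range(peaks, config)
  if (nrow(gated) == 0) stop_input("no peaks inside the size window")
  sids <- unique(gated$sample_id)
  signal <- noise <- NULL
  all_noise <- character(0)
  for (s in sids) {
    fn <- filter_noise(gated[gated$sample_id == s, , drop = FALSE], config)
    signal <- rbind(signal, fn$signal)
    noise <- rbind(noise, fn$noise)
    if (fn$all_noise) all_noise <- c(all_noise, s)
  }
  if (is.null(signal) || nrow(signal) == 0)
    stop_input("no signal peaks left after noise filtration")
  raw <- bin_fragments(signal, config)
  rel <- standardize_relative(raw)
  if (filter_low_abundance) rel <- filter_otus(rel, config)
  lg <- log_transform(rel, config)
  list(raw = raw, relative = rel, log = lg,
       noise_peaks = noise, signal_peaks = signal,
       all_noise_samples = all_noise,
       counts = c(input = nrow(peaks), in_window = nrow(gated),
                  signal = nrow(signal), noise = nrow(noise),
                  otus_binned = ncol(raw$abundance),
                  otus_retained = ncol(rel$abundance)))
}
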