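.pipeline_defaults <- function() list(
  vcf = NULL,                 # input VCF; NULL = simulate
  panels = NULL,              # panel TSV; NULL = simulate's panels
  contig_lengths = NULL,      # TSV fallback when the VCF header has none
  mask = NULL,                # callable BED; NULL = whole contigs
  simulate = list(),          # sim_params() overrides (used when vcf NULL)
  write_sim_vcf = FALSE,      # also save the simulated callset as VCF
  out_dir = NULL,
  seed = 1L,
  max_missing_frac = 0.1,     # site filter before any analysis
  min_donor_carriers = 1,
  max_exclusion_freq = 0,
  max_missing_per_panel = 0.5,
  window_size = 5000,
  window_step = NULL,         # NULL = window_size (tiling)
  scan_mode = "haplotype",
  freq_threshold = 0.5,
  min_support_sites = 2,
  min_consecutive_windows = 2,
  max_merge_gap_windows = 1,
  min_carriers = 2,
  pi_window_size = 50000,
  block_size_bp = 5e5,
  mu = 1.26e-8,
  generation_years = 6,
  date_correction = "ancestral",
  date_trim_bp = NULL,        # NULL = one window size from each segment end
  n_boot = 200,
  tree_boot = 100,
  verbose = TRUE)

#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list of overrides; unknown keys are
#' rejected so every effective parameter is visible in the manifest.
#'
#' @param config named list or YAML path.
#' @param ... further overrides (applied after `config`).
#' @return list of class `run_config` with all defaults filled in.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, list(...))
  base <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(base, config)
  if (is.null(out$out_dir)) .stopf("config needs an out_dir")
  structure(out, class = "run_config")
}

.stage <- function(verbose, name, expr) {
  if (verbose) .msg("stage ", name)
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full introgression analysis
#'
#' Orchestrates simulate/load -> site filter -> diagnostic alleles ->
#' window scan -> segment calling -> shared intervals -> genome fraction ->
#' f3/D statistics -> NJ haplotype tree -> clock dating, writing all tables
#' to `config$out_dir` together with a machine-readable manifest whose hash
#' covers the configuration and every output file.  Reruns with the same
#' configuration and inputs are bit-identical for all deterministic stages
#' (the whole pipeline seeds the RNG from `config$seed`).
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return report list with the main in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  vb <- cfg$verbose
  clock <- clock_params(mu = cfg$mu, g = cfg$generation_years)
  report <- list(config = cfg)

  truth <- NULL
  if (is.null(cfg$vcf)) {
    sim <- .stage(vb, "simulate", {
      sp <- do.call(sim_params, c(cfg$simulate, list(seed = cfg$seed)))
      simulate_introgression(sp)
    })
    gm <- sim$genotypes; panels <- sim$panels; truth <- sim$truth
    write_sim_truth(truth, file.path(cfg$out_dir, "truth.bed"),
                    file.path(cfg$out_dir, "truth.json"))
    if (cfg$write_sim_vcf) write_vcf(gm, file.path(cfg$out_dir, "sim.vcf"))
  } else {
    gm <- .stage(vb, "load", read_vcf(cfg$vcf))
    if (is.null(cfg$panels)) .stopf("a panel file is required with a VCF input")
    panels <- read_panels(cfg$panels)
  }
  validate_panels(panels, gm, require = c("donor", "recipient", "exclusion"))
  lens <- gm$contig_lengths
  if (is.null(lens) && !is.null(cfg$contig_lengths))
    lens <- read_contig_lengths(cfg$contig_lengths)
  if (is.null(lens)) .stopf("contig lengths unavailable (VCF header or TSV)")
  mask <- if (is.null(cfg$mask)) callable_mask(contig_lengths = lens) else
    callable_mask(read_bed(cfg$mask))

  gm <- .stage(vb, "filter", filter_sites(gm, cfg$max_missing_frac))
  report$n_sites <- n_sites(gm)

  das <- .stage(vb, "diagnostics", find_diagnostic_alleles(
    gm, panels, min_donor_carriers = cfg$min_donor_carriers,
    max_exclusion_freq = cfg$max_exclusion_freq,
    max_missing_per_panel = cfg$max_missing_per_panel))
  write_diagnostics(das, file.path(cfg$out_dir, "diagnostics.tsv"))
  report$n_diagnostic <- nrow(das)

  windows <- make_windows(lens, size = cfg$window_size,
                          step = cfg$window_step %||% cfg$window_size)
  ws <- .stage(vb, "scan", window_scan(gm, das, panels$recipient, windows,
                                       mode = cfg$scan_mode))
  utils::write.table(ws, file.path(cfg$out_dir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  segments <- .stage(vb, "segments", call_segments(
    ws, freq_threshold = cfg$freq_threshold,
    min_support_sites = cfg$min_support_sites,
    min_consecutive_windows = cfg$min_consecutive_windows,
    max_merge_gap_windows = cfg$max_merge_gap_windows))
  write_bed(segments, file.path(cfg$out_dir, "segments.bed"),
            extra_columns = c("carrier", "n_windows", "support", "mean_freq"))
  report$segments <- segments

  shared <- .stage(vb, "shared", shared_filter(segments, cfg$min_carriers))
  write_bed(shared, file.path(cfg$out_dir, "shared.bed"))
  report$shared <- shared

  frac <- .stage(vb, "fraction", genome_fraction(
    segments, mask, panels$recipient,
    mode = if (cfg$scan_mode == "haplotype") "haplotype" else "sample"))
  utils::write.table(frac$per_genome, file.path(cfg$out_dir, "fraction.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$fraction <- frac

  stats_rows <- list()
  ex <- exclusion_panels(panels)
  sister <- if (length(ex) >= 2L) ex[[2L]] else ex[[1L]]
  f3r <- .stage(vb, "f3", f3_stat(gm, panels, target = "recipient",
                                  source_a = sister, source_b = "donor",
                                  block_size_bp = cfg$block_size_bp))
  stats_rows$f3 <- f3r
  if (!is.null(panels$outgroup)) {
    dr <- .stage(vb, "dstat", d_stat(gm, panels, p1 = sister,
                                     p2 = "recipient", p3 = "donor",
                                     outgroup = "outgroup",
                                     block_size_bp = cfg$block_size_bp))
    stats_rows$d <- dr
  }
  stats_tab <- do.call(rbind, lapply(stats_rows, function(s) data.frame(
    statistic = s$statistic, estimate = s$estimate, se = s$se, z = s$z,
    n_sites = s$n_sites, n_blocks = s$n_blocks,
    significant = is.finite(s$z) && abs(s$z) > 3)))
  utils::write.table(stats_tab, file.path(cfg$out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stats <- stats_tab

  report$tree <- NULL
  if (nrow(shared)) {
    tree <- .stage(vb, "tree", {
      top <- shared[which.max(shared$end - shared$start), , drop = FALSE]
      carriers <- unique(segments$carrier[
        segments$contig == top$contig & segments$start < top$end &
          segments$end > top$start])
      carriers <- carriers[seq_len(min(length(carriers), 6L))]
      others <- c(hap_ids(panels$donor),
                  vapply(ex, function(e) hap_ids(panels[[e]])[1L], ""))
      hap_tree(gm, c(carriers, others), top, n_boot = cfg$tree_boot)
    })
    ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
    report$tree <- tree
  }

  report$dating <- NULL
  if (nrow(segments)) {
    dt <- .stage(vb, "dating", date_segments(
      gm, segments, panels$donor, clock = clock,
      correction = cfg$date_correction,
      trim_bp = cfg$date_trim_bp %||% cfg$window_size,
      n_boot = cfg$n_boot))
    jsonlite::write_json(
      list(generations = dt$generations, years = dt$years, d_net = dt$d_net,
           correction = dt$correction,
           ci_years = if (!is.null(dt$ci_years)) dt$ci_years),
      file.path(cfg$out_dir, "dating.json"), auto_unbox = TRUE, digits = NA)
    report$dating <- dt
  }

  if (!is.null(truth)) {
    report$evaluation <- .stage(vb, "evaluate",
                                evaluate_calls(segments, truth))
  }

  report$manifest <- .write_manifest(cfg, report)
  invisible(report)
}

.write_manifest <- function(cfg, report) {
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  md5 <- tools::md5sum(file.path(cfg$out_dir, files))
  names(md5) <- files
  cfg_echo <- unclass(cfg)
  cfg_echo$out_dir <- NULL  # location-independent hash
  canon <- jsonlite::toJSON(list(config = cfg_echo, files = as.list(md5),
                                 n_sites = report$n_sites,
                                 n_diagnostic = report$n_diagnostic,
                                 n_segments = nrow(report$segments)),
                            auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(canon, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(hash = hash, config = cfg_echo, files = as.list(md5),
                   n_sites = report$n_sites,
                   n_diagnostic = report$n_diagnostic,
                   n_segments = nrow(report$segments))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
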