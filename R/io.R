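#' Read a flat key = value run configuration
#'
#' Single flat configuration file per run: one `key = value` pair per line,
#' `#` comments.  Values are parsed as numbers where possible, otherwise
#' kept as strings.  Unknown keys are errors.
#'
#' @param path configuration file
#' @param known character vector of allowed keys (default: the fields of
#'   [simulation_config()] plus cavity/theory keys used by the CLI)
#' @return named list
#' @export
read_run_config <- function(path, known = NULL) {
  if (is.null(known))
    known <- c("temperature", "pressure", "n_particles", "solvent_model",
               "seed", "passes_equilibration", "passes_production",
               "volume_move_interval", "target_acceptance", "hs_diameter",
               "init_density", "sample_every", "frame_every", "tune_every",
               "R", "k0", "n0", "rho", "kappa_T", "d_ww", "gamma", "delta",
               "bin_width", "half_width", "min_frames")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  vals <- lapply(trimws(vapply(kv, `[`, "", 2L)), function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, keys)
}

#' Write an occupancy distribution to TSV
#'
#' Columns: `n`, `p_n`, `ln_p`, `ln_K` (NA in the last row), `stderr`
#' (of `ln p_n`, when available).
#'
#' @param p a [pn_distribution()]
#' @param path output file
#' @export
write_pn_tsv <- function(p, path) {
  stopifnot(inherits(p, "pn_distribution"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  se <- if (!is.null(p$se)) p$se else rep(NA_real_, length(p$p))
  lines <- c("n\tp_n\tln_p\tln_K\tstderr",
             paste(p$n_values, fmt(p$p), fmt(p$ln_p),
                   fmt(c(p$ln_K, NA)), fmt(se), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an occupancy distribution from TSV
#' @param path file written by [write_pn_tsv()]
#' @param provenance provenance tag for the result
#' @return a [pn_distribution()]
#' @export
read_pn_tsv <- function(path, provenance = "wham") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  se <- if (all(is.na(d$stderr))) NULL else d$stderr
  pn_distribution(d$p_n, d$n, provenance = provenance, se = se)
}

#' Write an occupancy-resolved RDF set to a directory
#'
#' One TSV per occupancy state (columns `r`, `g`, `count`) plus a JSON
#' manifest with the grid, radius, density and frame counts.
#'
#' @param gset an [occupancy_rdf_set()]
#' @param dir output directory (created if needed)
#' @export
write_rdf_set <- function(gset, dir) {
  stopifnot(inherits(gset, "occupancy_rdf_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(gset$n_values)) {
    d <- data.frame(r = gset$r_grid, g = gset$g[i, ],
                    count = gset$counts[i, ])
    utils::write.table(d, file.path(dir, sprintf("g_n%03d.tsv",
                                                 gset$n_values[i])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(R = gset$R, rho = gset$rho,
                   bin_width = gset$r_grid[2] - gset$r_grid[1],
                   n_values = gset$n_values,
                   frame_counts = gset$frame_counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an occupancy-resolved RDF set from a directory
#' @param dir directory written by [write_rdf_set()]
#' @return an [occupancy_rdf_set()]
#' @export
read_rdf_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ns <- as.integer(manifest$n_values)
  tabs <- lapply(ns, function(n)
    utils::read.table(file.path(dir, sprintf("g_n%03d.tsv", n)),
                      header = TRUE, sep = "\t"))
  occupancy_rdf_set(tabs[[1]]$r,
                    do.call(rbind, lapply(tabs, `[[`, "g")),
                    do.call(rbind, lapply(tabs, `[[`, "count")),
                    as.numeric(manifest$frame_counts), ns,
                    manifest$R, manifest$rho)
}

#' Write a window's occupancy samples to TSV
#'
#' Sidecar series for a [run_window()] result: columns `pass`, `n`,
#' `volume`, `energy`.
#'
#' @param run a `window_run`
#' @param path output file
#' @export
write_window_tsv <- function(run, path) {
  utils::write.table(run$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record tying every artifact of a run to its configuration:
#' config hash, master seed, package version, per-stage input/output paths
#' and timestamps.
#'
#' @param config named list (or `simulation_config`) the run used
#' @param seed master seed
#' @param stages named list mapping stage name to list(inputs, outputs)
#' @return object of class `run_manifest`
#' @export
run_manifest <- function(config, seed, stages = list()) {
  cfg <- unclass(config)
  hash <- sprintf("%08x",
                  sum(utf8ToInt(paste(names(cfg), sapply(cfg, paste,
                                                         collapse = ","),
                                      collapse = ";", sep = "="))) %%
                    .Machine$integer.max)
  structure(list(config = cfg, config_hash = hash, seed = seed,
                 package_version = as.character(utils::packageVersion(
                   "cavityfluct")),
                 stages = stages,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "run_manifest")
}

#' Write/read a run manifest as JSON
#' @param manifest a [run_manifest()]
#' @param path JSON path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "run_manifest")
}
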