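#' Default end-to-end run configuration
#'
#' A small simulated screen: one or more plates, each with control and
#' treated conditions differing in the peripheral allocation of ER
#' intensity, a few wells per condition and one or more simulated fields per
#' well. All module parameters are exposed and serialized with every run.
#'
#' @param plates number of plates.
#' @param seed base RNG seed; all per-field seeds derive from it.
#' @return nested list of class `RunConfig`.
#' @export
default_run_config <- function(plates = 1L, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(
      plates = as.integer(plates),
      fields_per_well = 1L,
      conditions = list(
        list(name = "control", control = TRUE, wells = 4L,
             er_peripheral_fraction = 0.30),
        list(name = "er_expanded", control = FALSE, wells = 4L,
             er_peripheral_fraction = 0.60)),
      field = list(image_shape = c(512L, 512L), n_cells = 10L,
                   cell_radius_range = c(28, 38),
                   ridge_density = 3L, hole_density = 3L,
                   noise = c(poisson_scale = 4, gaussian_sd = 25))),
    segmentation = list(smoothing = 2, min_area = 80, split = TRUE),
    cells = list(threshold = "otsu", method = "srg"),
    qc = list(min_area = 400, max_area = 50000, focus_threshold = 0.04),
    features = list(f_pn = 0.25, f_pe = 0.25),
    stats = list(stat = "mean", distance = "correlation",
                 linkage = "average"))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Load / save a run configuration
#'
#' Configurations round-trip through YAML: `load_run_config(save_run_config(
#' cfg, path))` reproduces `cfg`.
#'
#' @param x a `RunConfig`, plain list, or path to a YAML/JSON file.
#' @return a validated `RunConfig`.
#' @export
load_run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a list or a file path", call. = FALSE)
  base <- default_run_config()
  cfg <- utils::modifyList(base, x, keep.null = TRUE)
  # modifyList merges by name; the conditions list is unnamed and must be
  # replaced wholesale when the input provides one
  if (!is.null(x$simulate$conditions))
    cfg$simulate$conditions <- lapply(x$simulate$conditions, function(cn) {
      cn$wells <- as.integer(cn$wells); cn
    })
  # YAML may round-trip the named noise vector as a list or drop its names
  nz <- unlist(cfg$simulate$field$noise)
  if (is.null(names(nz)) && length(nz) == 2L)
    names(nz) <- c("poisson_scale", "gaussian_sd")
  cfg$simulate$field$noise <- nz
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' @rdname load_run_config
#' @param cfg a `RunConfig`.
#' @param path output YAML path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Polynomial rolling hash of the serialized config, for stamping output
# tables (stability matters, cryptographic strength does not).
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(unclass(cfg))),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full simulate - segment - features - stats pipeline
#'
#' Generates the configured plates of synthetic fields, segments nuclei and
#' cells, applies QC, computes per-cell ER and shape features, aggregates to
#' wells, computes control-referenced Z-scores, per-condition t-tests on
#' well means and a hierarchical clustering of condition profiles. The run
#' is deterministic given the config and its seed; every output table
#' carries the config hash. When `out` is given, all tables, the resolved
#' config and a run log are written there.
#'
#' @param config `RunConfig`, plain list, or YAML path ([load_run_config()]).
#' @param out optional output directory.
#' @param quiet suppress progress messages.
#' @return list: `cell_features`, `wells`, `zscores` (`ScreenMatrix`),
#'   `ttests`, `clustering`, `layout`, `config`, `config_hash`, `log`.
#' @export
run_pipeline <- function(config = default_run_config(), out = NULL,
                         quiet = FALSE) {
  cfg <- load_run_config(config)
  hash <- config_hash(cfg)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  say("run config hash %s, seed %d", hash, cfg$seed)

  sim <- cfg$simulate
  conds <- sim$conditions
  n_fields_total <- sim$plates * sim$fields_per_well *
    sum(vapply(conds, function(cn) cn$wells, numeric(1)))
  seeds <- derive_seeds(cfg$seed, n_fields_total)

  layout <- list(); cell_rows <- list()
  fi <- 0L
  for (plate in seq_len(sim$plates)) {
    for (cn in conds) {
      for (wi in seq_len(cn$wells)) {
        well <- sprintf("p%d_%s_w%d", plate, cn$name, wi)
        layout[[length(layout) + 1L]] <- data.frame(
          plate = plate, well = well, condition = cn$name,
          replicate = wi, control = isTRUE(cn$control))
        for (fd in seq_len(sim$fields_per_well)) {
          fi <- fi + 1L
          fargs <- sim$field
          over <- cn[setdiff(names(cn), c("name", "control", "wells"))]
          fargs[names(over)] <- over
          fargs$seed <- seeds[fi]
          spec <- do.call(field_spec, fargs)
          stage <- sprintf("%s field %d", well, fd)
          res <- withCallingHandlers(
            tryCatch(pipeline_one_field(spec, cfg),
                     error = function(e) stop(sprintf(
                       "stage failed at %s: %s", stage, conditionMessage(e)),
                       call. = FALSE)),
            warning = function(w) {
              say("warning at %s: %s", stage, conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          if (nrow(res)) {
            res$plate <- plate; res$well <- well; res$field <- fd
            cell_rows[[length(cell_rows) + 1L]] <- res
          }
          say("%s: %d cells, %d pass QC", stage, nrow(res), sum(res$qc_pass))
        }
      }
    }
  }
  layout <- do.call(rbind, layout)
  cell_features <- do.call(rbind, cell_rows)

  wells <- aggregate_wells(cell_features, layout)
  ctrl_names <- vapply(conds[vapply(conds, function(cn) isTRUE(cn$control),
                                    logical(1))],
                       function(cn) cn$name, character(1))
  if (!length(ctrl_names)) stop("config defines no control condition",
                                call. = FALSE)
  z <- zscore_matrix(wells, controls = ctrl_names, stat = cfg$stats$stat)

  stat_col <- cfg$stats$stat
  feats <- unique(wells$feature)
  tt_rows <- list()
  for (cn in setdiff(unique(wells$condition), ctrl_names)) {
    for (f in feats) {
      a <- wells[[stat_col]][wells$condition %in% ctrl_names &
                             wells$feature == f]
      b <- wells[[stat_col]][wells$condition == cn & wells$feature == f]
      if (length(a) >= 2L && length(b) >= 2L) {
        tt <- ttest_conditions(b, a)
        tt_rows[[length(tt_rows) + 1L]] <-
          cbind(data.frame(condition = cn, feature = f), tt)
      }
    }
  }
  ttests <- if (length(tt_rows)) do.call(rbind, tt_rows) else NULL

  clustering <- if (nrow(z) >= 2L && ncol(z) >= 2L)
    tryCatch(cluster_profiles(z, distance = cfg$stats$distance,
                              linkage = cfg$stats$linkage),
             error = function(e) { say("clustering skipped: %s",
                                       conditionMessage(e)); NULL })
    else NULL

  say("pipeline complete: %d wells, %d cells (%d pass QC)",
      length(unique(cell_features$well)), nrow(cell_features),
      sum(cell_features$qc_pass))

  result <- list(cell_features = cell_features, wells = wells, zscores = z,
                 ttests = ttests, clustering = clustering, layout = layout,
                 config = cfg, config_hash = hash, log = log_lines)
  if (!is.null(out)) write_pipeline_outputs(result, out)
  invisible(result)
}

# segment + QC + features for one simulated field; returns the per-cell table
pipeline_one_field <- function(spec, cfg) {
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field$channels$dna,
                        smoothing = cfg$segmentation$smoothing,
                        min_area = cfg$segmentation$min_area,
                        split = cfg$segmentation$split)
  cells <- segment_cells(nuc, sim$field$channels$cyto,
                         threshold = cfg$cells$threshold,
                         method = cfg$cells$method)
  qc <- qc_filter(cells, sim$field, min_area = cfg$qc$min_area,
                  max_area = cfg$qc$max_area,
                  focus_threshold = cfg$qc$focus_threshold)
  compute_cell_features(sim$field, nuc, cells, qc,
                        f_pn = cfg$features$f_pn, f_pe = cfg$features$f_pe)
}

write_pipeline_outputs <- function(result, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- result$config_hash; df }
  utils::write.csv(stamp(result$cell_features),
                   file.path(out, "cell_features.csv"), row.names = FALSE)
  utils::write.csv(stamp(result$wells), file.path(out, "well_summary.csv"),
                   row.names = FALSE)
  zdf <- as.data.frame(unclass(result$zscores))
  zdf <- cbind(condition = rownames(zdf), zdf)
  utils::write.csv(stamp(zdf), file.path(out, "zscores.csv"),
                   row.names = FALSE)
  if (!is.null(result$ttests))
    utils::write.csv(stamp(result$ttests), file.path(out, "ttests.csv"),
                     row.names = FALSE)
  if (!is.null(result$clustering))
    writeLines(result$clustering$newick,
               file.path(out, "dendrogram.newick"))
  utils::write.csv(stamp(result$layout), file.path(out, "layout.csv"),
                   row.names = FALSE)
  save_run_config(result$config, file.path(out, "config.yaml"))
  writeLines(result$log, file.path(out, "run.log"))
  invisible(out)
}
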