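# Config-driven entry points: read a plain YAML run configuration, execute
# the fitting or prediction workflow, and write TSV reports plus a JSON run
# manifest (inputs, hashes, seed, package version) into a fresh output
# directory. inst/scripts/allometry.R wraps these for shell use.

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

write_manifest <- function(out_dir, command, config_path, config, seed) {
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 &&
                     file.exists(p), config)
  hashes <- vapply(inputs, function(p)
    as.character(tools::md5sum(p)), character(1))
  manifest <- list(command = command, config = config_path,
                   input_md5 = as.list(hashes), seed = seed,
                   package = "carapace",
                   version = as.character(packageVersion("carapace")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

prepare_out_dir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", out_dir,
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

#' Run a model-fitting workflow from a configuration file
#'
#' The YAML configuration names the inputs and the model set:
#' `tree` (Newick path), either `species_csv` (species-level table) or
#' `specimen_csv` + `maxima_csv` (raw specimens, filtered and aggregated
#' first), `response`, `predictor`, optional `covariates` (list),
#' `bootstrap` (replicates, 0 to skip), and `seed`. Writes `models.tsv`
#' (ranked coefficient report), `selection.tsv`, `exclusions.csv` when
#' filtering ran, and `manifest.json`.
#'
#' @param config_path path to the YAML configuration.
#' @param out_dir output directory (must be empty unless `overwrite`).
#' @param overwrite allow writing into a non-empty directory.
#' @return (invisibly) the selection object from [select_best_model()].
#' @export
run_fit <- function(config_path, out_dir, overwrite = FALSE) {
  cfg <- read_run_config(config_path)
  for (need in c("tree", "response", "predictor"))
    if (is.null(cfg[[need]])) stop("config missing field: ", need, call. = FALSE)
  if (!file.exists(cfg$tree)) stop("tree not found: ", cfg$tree, call. = FALSE)
  prepare_out_dir(out_dir, overwrite)
  seed <- cfg$seed %||% 1L
  set.seed(seed)
  tree <- read_phylogeny(cfg$tree)

  if (!is.null(cfg$species_csv)) {
    species <- read.csv(cfg$species_csv, stringsAsFactors = FALSE)
  } else if (!is.null(cfg$specimen_csv)) {
    if (is.null(cfg$maxima_csv))
      stop("specimen input requires maxima_csv", call. = FALSE)
    specimens <- read.csv(cfg$specimen_csv, stringsAsFactors = FALSE)
    maxima <- read.csv(cfg$maxima_csv, stringsAsFactors = FALSE)
    flt <- apply_maturity_filter(specimens, maxima,
                                 threshold = cfg$threshold %||% 0.6)
    write.csv(flt$exclusions, file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
    species <- aggregate_species(flt$retained)
  } else stop("config needs species_csv or specimen_csv", call. = FALSE)

  covs <- as.character(cfg$covariates %||% character())
  specs <- build_model_set(cfg$response, cfg$predictor, covs, data = species)
  fits <- fit_model_set(specs, species, tree)
  sel <- select_best_model(fits[vapply(fits, function(f) f$k > 1, logical(1))])

  B <- cfg$bootstrap %||% 0
  cis <- NULL
  if (B > 0) {
    cis <- list()
    cis[[sel$best$model]] <- suppressWarnings(
      bootstrap_cis(sel$best$formula, species, tree, B = B, seed = seed))
  }
  tab <- fit_table(fits, cis = cis)
  utils::write.table(tab, file.path(out_dir, "models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sel$table, file.path(out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "fit", config_path, cfg, seed)
  invisible(sel)
}

#' Run a shell-length prediction workflow from a configuration file
#'
#' The configuration names `input_csv` (columns `taxon`, `specimen`,
#' `element`, `length_mm`, optional `clade`, `terrestrial`, `trionychid`)
#' and optional `seed`. Each row is evaluated against the shipped global
#' equation and, where a clade label is given, the clade-specific equation;
#' rows with unknown clade labels are reported and skipped, the run
#' continues. Writes `predictions.tsv` and `manifest.json`.
#'
#' @inheritParams run_fit
#' @return (invisibly) the predictions data frame.
#' @export
run_predict <- function(config_path, out_dir, overwrite = FALSE) {
  cfg <- read_run_config(config_path)
  if (is.null(cfg$input_csv)) stop("config missing field: input_csv", call. = FALSE)
  if (!file.exists(cfg$input_csv))
    stop("input not found: ", cfg$input_csv, call. = FALSE)
  prepare_out_dir(out_dir, overwrite)
  inp <- read.csv(cfg$input_csv, stringsAsFactors = FALSE)
  known <- unique(scl_equations()$clade)
  rows <- lapply(seq_len(nrow(inp)), function(i) {
    r <- inp[i, ]
    terr <- if ("terrestrial" %in% names(inp)) r$terrestrial else NA
    trio <- if ("trionychid" %in% names(inp)) r$trionychid else NA
    glob <- predict_scl(r$length_mm, element = r$element,
                        clade = "Testudinata", terrestrial = terr)
    clade_est <- NA_real_
    note <- ""
    cl <- if ("clade" %in% names(inp)) r$clade else NA
    if (!is.na(cl) && nzchar(cl) && cl != "Testudinata") {
      if (!cl %in% known) {
        note <- paste0("unknown clade '", cl, "'")
      } else {
        ce <- tryCatch(predict_scl(r$length_mm, element = r$element,
                                   clade = cl, terrestrial = terr,
                                   trionychid = trio),
                       error = function(e) NULL)
        if (is.null(ce)) note <- "clade equation failed (missing covariate?)"
        else clade_est <- ce$scl_mm
      }
    }
    data.frame(taxon = r$taxon, specimen = r$specimen, element = r$element,
               length_mm = r$length_mm, scl_global_mm = glob$scl_mm,
               scl_clade_mm = clade_est, note = note,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(), specimen = character(),
               element = character(), length_mm = numeric(),
               scl_global_mm = numeric(), scl_clade_mm = numeric(),
               note = character())
  utils::write.table(out, file.path(out_dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "predict", config_path, cfg, cfg$seed %||% 1L)
  invisible(out)
}
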