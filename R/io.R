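# Readers and writers for the delimited formats shared across modules.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name, description,
#' member...`.
#'
#' @param path GMT file path.
#' @return named list of member vectors, with descriptions as the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions per-set description strings (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Read functional gene classes from a two-column TSV
#'
#' @param path TSV with header `gene`, `class`.
#' @return named character vector gene -> class.
#' @export
read_gene_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene", "class") %in% names(df)),
              "gene class file needs 'gene' and 'class' columns")
  stats::setNames(df$class, df$gene)
}

#' Read an in vitro response table
#'
#' Tidy TSV with columns `drug`, `gene`, `level`, `conc_um`, `time_h`,
#' `log2fc` (and optionally `replicate`, averaged out).
#'
#' @param path TSV file path.
#' @return data.frame in the tensor layout used by the pipeline.
#' @export
read_response_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("drug", "gene", "level", "conc_um", "time_h", "log2fc")
  assert_that(all(needed %in% names(df)),
              "response table lacks columns: %s",
              paste(setdiff(needed, names(df)), collapse = ", "))
  if ("replicate" %in% names(df)) {
    df <- stats::aggregate(log2fc ~ drug + gene + level + conc_um + time_h,
                           data = df, FUN = mean)
  }
  df
}

#' Write a tidy table with a unit-documenting header comment
#'
#' @param df data.frame.
#' @param path output path (`.csv` or `.tsv` by extension).
#' @param stage generating pipeline stage, recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(df, path, stage = "picdtox") {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s | units: time h, dose mg, conc umol/L, response abs-log2FC",
                     stage), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read known DDI reference pairs
#'
#' CSV with columns `drug_a`, `drug_b` and optional `interaction_type`,
#' `source`.
#'
#' @param path CSV file path.
#' @return data.frame of unordered reference pairs.
#' @export
read_reference_ddis <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  assert_that(all(c("drug_a", "drug_b") %in% names(df)),
              "reference DDI file needs 'drug_a' and 'drug_b' columns")
  df
}

#' Load and validate a study configuration
#'
#' YAML (or JSON) study file. Recognized keys: `seed`, `out_dir`,
#' `thresholds` (alpha, key_process_fraction, perturbation,
#' responder_log2fc, common_mean_mult, common_sd_mult, individual_mult,
#' differential, biomarker_alpha), `synthetic` (any
#' [synthetic_study_spec()] argument) and `paths` (compounds, gene_sets,
#' classes, responses, reference_ddis). Unknown keys are rejected so
#' typos cannot silently fall back to defaults; every applied default is
#' reported via `message()`.
#'
#' @param path config file path.
#' @return a validated `study_config` list.
#' @export
load_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw <- raw %||% list()
  known_top <- c("seed", "out_dir", "thresholds", "synthetic", "paths")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  thr_defaults <- list(alpha = 0.01, key_process_fraction = 1/3,
                       perturbation = 0.10, responder_log2fc = 1,
                       common_mean_mult = 1.5, common_sd_mult = 0.5,
                       individual_mult = 7, differential = 0.15,
                       biomarker_alpha = 0.05)
  thr <- raw$thresholds %||% list()
  unknown <- setdiff(names(thr), names(thr_defaults))
  if (length(unknown))
    stop_config("unknown threshold key(s): %s",
                paste(unknown, collapse = ", "))
  for (k in names(thr_defaults)) {
    if (is.null(thr[[k]])) {
      thr[[k]] <- thr_defaults[[k]]
      message(sprintf("config default applied: thresholds.%s = %s",
                      k, format(thr_defaults[[k]])))
    }
    assert_that(thr[[k]] > 0, "threshold %s must be positive", k)
  }
  syn <- raw$synthetic %||% list()
  known_syn <- names(formals(synthetic_study_spec))
  unknown <- setdiff(names(syn), known_syn)
  if (length(unknown))
    stop_config("unknown synthetic key(s): %s",
                paste(unknown, collapse = ", "))
  paths <- raw$paths %||% list()
  known_paths <- c("compounds", "gene_sets", "classes", "responses",
                   "reference_ddis")
  unknown <- setdiff(names(paths), known_paths)
  if (length(unknown))
    stop_config("unknown path key(s): %s", paste(unknown, collapse = ", "))
  missing <- names(paths)[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop_config("config path(s) not resolvable: %s",
                paste(missing, collapse = ", "))
  if (is.null(raw$seed)) message("config default applied: seed = 1")
  structure(list(seed = raw$seed %||% 1L,
                 out_dir = raw$out_dir,
                 thresholds = thr, synthetic = syn, paths = paths),
            class = "study_config")
}

#' Write a study configuration to YAML
#'
#' @param config a `study_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
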