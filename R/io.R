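.TRIAL_SCHEMA_VERSION <- "1"
.TRIAL_COLUMNS <- c("t_s", "s_x_deg", "s_y_deg", "p_x_deg", "p_y_deg",
                    "occluded")

#' Write a tracking record to a trial file
#'
#' Tab-separated UTF-8 body (one row per sample, columns `t_s`, `s_x_deg`,
#' `s_y_deg`, `p_x_deg`, `p_y_deg`, `occluded`) preceded by a `#`-prefixed
#' JSON manifest line holding the trial configuration, scotoma
#' specification, identifiers and schema version.
#'
#' @param record A `tracking_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(record, path) {
  stopifnot(inherits(record, "tracking_record"))
  header <- list(schema_version = .TRIAL_SCHEMA_VERSION,
                 participant_id = record$participant_id,
                 trial_id = record$trial_id,
                 config = unclass(record$config),
                 scotoma = unclass(record$scotoma))
  n <- length(record$s_x)
  body <- data.frame(
    t_s = (seq_len(n) - 1) / record$config$sample_rate,
    s_x_deg = record$s_x, s_y_deg = record$s_y,
    p_x_deg = record$p_x, p_y_deg = record$p_y,
    occluded = record$occluded)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE,
                                           digits = NA)), con)
  writeLines(paste(.TRIAL_COLUMNS, collapse = "\t"), con)
  write.table(format(body, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trial file
#'
#' Validates the schema version, column set, row count against the recorded
#' configuration, value finiteness and flag domain; errors are descriptive
#' and name the offending column or line.
#'
#' @param path Trial file written by [write_trial()].
#' @return A `tracking_record`.
#' @export
read_trial <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2 || !startsWith(lines[1], "# ")) {
    stop("parse error at line 1: missing '# ' JSON manifest header",
         call. = FALSE)
  }
  header <- jsonlite::fromJSON(substring(lines[1], 3))
  if (!identical(header$schema_version, .TRIAL_SCHEMA_VERSION)) {
    stop("unknown schema version '", header$schema_version,
         "' (reader supports version ", .TRIAL_SCHEMA_VERSION, ")",
         call. = FALSE)
  }
  cols <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(.TRIAL_COLUMNS, cols)
  if (length(missing) > 0) {
    stop("parse error at line 2: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  body <- read.table(text = lines[-(1:2)], sep = "\t", header = FALSE,
                     col.names = cols, colClasses = "numeric")
  cfg <- do.call(trial_config, header$config[setdiff(names(header$config),
                                                     "rng_seed")])
  expected <- n_samples(cfg)
  if (nrow(body) != expected) {
    stop("length mismatch: expected ", expected, " rows (",
         cfg$duration, " s x ", cfg$sample_rate, " Hz), found ", nrow(body),
         call. = FALSE)
  }
  num <- body[, setdiff(.TRIAL_COLUMNS, "occluded")]
  if (any(!is.finite(as.matrix(num)))) {
    bad <- which(!stats::complete.cases(num) |
                   !apply(is.finite(as.matrix(num)), 1, all))[1]
    stop("parse error at line ", bad + 2, ": non-finite value",
         call. = FALSE)
  }
  if (!all(body$occluded %in% c(0, 1))) {
    stop("parse error: `occluded` must be 0 or 1", call. = FALSE)
  }
  spec <- scotoma_spec(header$scotoma$kind, header$scotoma$size_deg)
  structure(list(config = cfg, scotoma = spec,
                 s_x = body$s_x_deg, s_y = body$s_y_deg,
                 p_x = body$p_x_deg, p_y = body$p_y_deg,
                 occluded = as.integer(body$occluded),
                 participant_id = header$participant_id,
                 trial_id = header$trial_id),
            class = "tracking_record")
}

#' Write / read a visual field map
#'
#' The map matrix is stored as a row-per-grid-row text table (unsampled
#' cells as NA) alongside a JSON sidecar (`<path>.json`) with grid extent,
#' counts and provenance.
#'
#' @param map A `field_map`.
#' @param path Output path for the matrix; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_field_map <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  write.table(map$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(schema_version = .TRIAL_SCHEMA_VERSION,
               ex = map$grid$ex, ey = map$grid$ey,
               min_count = map$grid$min_count,
               flip_sign = map$grid$flip_sign,
               dropped = map$dropped,
               counts = map$counts, flagged = map$flagged)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_field_map
#' @export
read_field_map <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  if (!identical(as.character(meta$schema_version), .TRIAL_SCHEMA_VERSION)) {
    stop("unknown schema version", call. = FALSE)
  }
  grid <- field_grid(meta$ex, meta$ey, meta$min_count, meta$flip_sign)
  counts <- matrix(meta$counts, grid$ny, grid$nx, byrow = FALSE)
  flagged <- matrix(meta$flagged, grid$ny, grid$nx, byrow = FALSE)
  .new_field_map(counts, flagged, meta$dropped, grid)
}

#' Write / read a normative distribution
#'
#' Values as a flat one-per-line text file plus a JSON sidecar with source
#' participant ids.
#'
#' @param norms A `normative_distribution`.
#' @param path Output path; sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_normative <- function(norms, path) {
  stopifnot(inherits(norms, "normative_distribution"))
  writeLines(format(norms$values, digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  jsonlite::write_json(list(schema_version = .TRIAL_SCHEMA_VERSION,
                            source_ids = norms$source_ids,
                            n_values = length(norms$values)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  if (!identical(as.character(meta$schema_version), .TRIAL_SCHEMA_VERSION)) {
    stop("unknown schema version", call. = FALSE)
  }
  vals <- as.numeric(readLines(path))
  if (length(vals) != meta$n_values) {
    stop("length mismatch against sidecar metadata", call. = FALSE)
  }
  structure(list(values = sort(vals), source_ids = meta$source_ids),
            class = "normative_distribution")
}

#' Write a cohort to a directory of trial files plus a manifest
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$records))
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    files[i] <- file.path(dir, sprintf("%s_%s.tsv", r$participant_id,
                                       r$trial_id))
    write_trial(r, files[i])
  }
  man <- cohort$manifest
  man$file <- basename(files)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(schema_version = .TRIAL_SCHEMA_VERSION,
                            seed = cohort$seed, trials = man),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(as.character(meta$schema_version), .TRIAL_SCHEMA_VERSION)) {
    stop("unknown schema version", call. = FALSE)
  }
  man <- meta$trials
  records <- lapply(file.path(dir, man$file), read_trial)
  man$file <- NULL
  man$index <- seq_len(nrow(man))
  structure(list(records = records, manifest = man,
                 seed = meta$seed),
            class = "cohort")
}
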