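#' Column inventory of the cohort data model
#'
#' The canonical column groups of a subject table: eight symptom subscales
#' (five from the Autism-Spectrum Quotient, three from SNAP-IV), the
#' neurocognition battery, and tract-mean fractional anisotropy (FA) values.
#'
#' @name column_sets
NULL

#' @rdname column_sets
#' @export
symptom_columns <- function() {
  c("socialness", "mindreading", "patterns", "details", "perseveration",
    "inattention", "hyperactivity", "odd")
}

#' @rdname column_sets
#' @export
cognition_columns <- function() {
  c("iq", "ppt_hands", "ppt_assemble", "vp", "mc", "vmi",
    "vf_se", "vf_ph", "rvp", "soc", "swm", "ied")
}

#' @rdname column_sets
#' @export
fa_columns <- function() {
  c("fa_cc_body", "fa_cc_splenium", "fa_ic")
}

#' Declare the expected layout of a subject table
#'
#' @param symptoms,cognition,fa Character vectors of numeric column names.
#'   FA columns are additionally range-checked to `[0, 1]`.
#' @param diagnosis_levels Allowed diagnosis labels.
#' @param extra Further required columns (not type-checked).
#' @return A `subject_schema` list.
#' @export
subject_schema <- function(symptoms = symptom_columns(),
                           cognition = cognition_columns(),
                           fa = fa_columns(),
                           diagnosis_levels = c("ASD", "ADHD", "TDC"),
                           extra = character()) {
  structure(list(symptoms = symptoms, cognition = cognition, fa = fa,
                 diagnosis_levels = diagnosis_levels, extra = extra),
            class = "subject_schema")
}

#' Read and validate a subject-by-variable table
#'
#' Reads a UTF-8 comma-separated table (header row, `NA` token for missing
#' values) and validates it against a schema. Rows with missing values are
#' retained; complete-case filtering happens per analysis.
#'
#' @param path Path to a CSV file.
#' @param schema A [subject_schema()].
#' @return A validated `subject_table` (a `data.frame` with the schema
#'   attached as attribute `"schema"`).
#' @export
read_subject_table <- function(path, schema = subject_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  as_subject_table(raw, schema, parse = TRUE)
}

#' @rdname read_subject_table
#' @param data A data frame to validate in place of a file.
#' @param parse Parse character columns to numeric (used by the reader).
#' @export
as_subject_table <- function(data, schema = subject_schema(), parse = FALSE) {
  numeric_cols <- c(schema$symptoms, schema$cognition, schema$fa)
  required <- c("subject_id", "diagnosis", numeric_cols, schema$extra)
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(names(data))) {
    stop("schema error: duplicated column name(s): ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  }
  if (parse) {
    for (col in numeric_cols) {
      x <- data[[col]]
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "NA" & is.na(parsed))
      if (length(bad) > 0) {
        stop("parse error: non-numeric value in column '", col,
             "' at row ", bad[1], ": '", x[bad[1]], "'")
      }
      data[[col]] <- parsed
    }
  }
  if (anyDuplicated(data$subject_id)) {
    stop("validation error: duplicate subject_id: ",
         paste(unique(data$subject_id[duplicated(data$subject_id)]),
               collapse = ", "))
  }
  bad_dx <- setdiff(unique(stats::na.omit(data$diagnosis)),
                    schema$diagnosis_levels)
  if (length(bad_dx) > 0) {
    stop("validation error: unknown diagnosis label(s): ",
         paste(bad_dx, collapse = ", "))
  }
  for (col in schema$fa) {
    v <- data[[col]]
    out <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(out) > 0) {
      stop("range error: column '", col, "' has value ", v[out[1]],
           " at row ", out[1], " outside the FA bound [0,1]")
    }
  }
  structure(data, schema = schema, class = c("subject_table", "data.frame"))
}

#' Write a subject table as CSV
#'
#' Full-precision round trip: values are written with 17 significant digits.
#'
#' @param table A `subject_table` or data frame.
#' @param path Output path.
#' @export
write_subject_table <- function(table, path) {
  tab <- as.data.frame(table)
  for (col in names(tab)) {
    if (is.numeric(tab[[col]])) {
      tab[[col]] <- ifelse(is.na(tab[[col]]), NA,
                           format(tab[[col]], digits = 17, trim = TRUE,
                                  scientific = FALSE))
    }
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Holds every tunable of the subtyping pipeline; all downstream randomness
#' is derived from `seed` via [child_seed()].
#'
#' @param feature_columns Ordered clustering features (default: the eight
#'   symptom subscales).
#' @param k_max Largest cluster count scanned by the gap statistic.
#' @param n_reference Gap-statistic reference draws B.
#' @param n_stability_reps Stability subsampling replicates.
#' @param subsample_fraction Fraction of subjects per stability subsample.
#' @param n_bootstrap Bootstrap draws for mediation confidence intervals.
#' @param seed Master integer seed.
#' @param linkage Agglomeration criterion: `"ward"`, `"complete"` or
#'   `"average"`.
#' @param n_subjects Optional cohort size used to validate `k_max`.
#' @return A `run_config` list.
#' @export
run_config <- function(feature_columns = symptom_columns(),
                       k_max = 15L, n_reference = 100L,
                       n_stability_reps = 1000L, subsample_fraction = 0.8,
                       n_bootstrap = 10000L, seed = 1L,
                       linkage = c("ward", "complete", "average"),
                       n_subjects = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(k_max >= 2, n_reference >= 10, n_stability_reps >= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            n_bootstrap >= 1, length(feature_columns) >= 1)
  if (!is.null(n_subjects)) {
    if (k_max > n_subjects - 1) {
      stop("k_max must be at most n_subjects - 1")
    }
    if (subsample_fraction * n_subjects < k_max + 2) {
      stop("subsample_fraction * n must be at least k_max + 2")
    }
  }
  structure(list(feature_columns = feature_columns, k_max = as.integer(k_max),
                 n_reference = as.integer(n_reference),
                 n_stability_reps = as.integer(n_stability_reps),
                 subsample_fraction = subsample_fraction,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), linkage = linkage),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys match the `run_config`
#'   arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a bundle of results to a directory
#'
#' Data frames are written as CSV, ggplot objects as PNG; a `metadata.txt`
#' file records the configuration, seed and session versions. Returns a
#' manifest of everything written.
#'
#' @param bundle Named list of data frames and/or ggplot objects.
#' @param out_dir Output directory (created if needed).
#' @param config Optional [run_config()] echoed into the metadata.
#' @return Data frame manifest with columns `name`, `file`, `kind`.
#' @export
write_results <- function(bundle = list(), out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  manifest <- data.frame(name = character(), file = character(),
                         kind = character(), stringsAsFactors = FALSE)
  for (nm in names(bundle)) {
    obj <- bundle[[nm]]
    if (inherits(obj, "ggplot")) {
      file <- file.path(out_dir, paste0(nm, ".png"))
      ggplot2::ggsave(file, obj, width = 6, height = 4.5, dpi = 150)
      kind <- "figure"
    } else {
      file <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(obj), file, row.names = FALSE, na = "NA")
      kind <- "table"
    }
    manifest <- rbind(manifest, data.frame(name = nm, file = file,
                                           kind = kind))
  }
  meta_file <- file.path(out_dir, "metadata.txt")
  meta <- c(paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            paste0("r_version: ", R.version.string),
            paste0("package: transdx ",
                   as.character(utils::packageVersion("transdx"))))
  if (!is.null(config)) {
    meta <- c(meta, "config:",
              paste0("  ", names(config), ": ",
                     vapply(config, function(v) paste(v, collapse = ","),
                            character(1))))
  }
  writeLines(meta, meta_file)
  manifest <- rbind(manifest, data.frame(name = "metadata",
                                         file = meta_file, kind = "metadata"))
  manifest
}
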