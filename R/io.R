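# Readers and writers for the tabular study inputs.
#
# CSV dialect throughout: comma separated, UTF-8, mandatory header row,
# '.' decimal separator. Compound and condition order is preserved exactly
# as found in the input files so downstream splits are reproducible.

read_conditions <- function(path) {
  if (!file.exists(path)) qstop("conditions file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "temperature_c", "tg_min", "pctb_start", "pctb_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) qstop("conditions CSV missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$condition_id)) qstop("duplicate condition id in %s", path)
  for (col in need[-1]) {
    if (!is.numeric(df[[col]])) qstop("conditions CSV: column %s is not numeric", col)
  }
  if (any(df$temperature_c <= -273.15)) qstop("condition temperature below absolute zero")
  if (any(df$tg_min <= 0)) qstop("condition gradient time tG must be > 0")
  if (any(df$pctb_start < 0 | df$pctb_start >= df$pctb_end | df$pctb_end > 100)) {
    qstop("conditions must satisfy 0 <= %%B start < %%B end <= 100")
  }
  df$condition_id <- as.character(df$condition_id)
  df$temp_k <- celsius_to_kelvin(df$temperature_c)
  df
}

read_descriptors <- function(path) {
  if (!file.exists(path)) qstop("descriptor file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "compound_id") {
    qstop("descriptor CSV: first column must be 'compound_id'")
  }
  ids <- as.character(df$compound_id)
  if (anyDuplicated(ids)) {
    qstop("duplicate compound id in descriptor matrix: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (ncol(df) < 2) qstop("descriptor CSV has no descriptor columns")
  if (anyDuplicated(names(df)[-1])) qstop("duplicate descriptor column name")
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    # name the first offending cell for the user
    for (j in seq_len(ncol(df) - 1) + 1) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(v) & !is.na(df[[j]]))
      if (length(bad)) {
        qstop("non-numeric descriptor value at row '%s', column '%s'",
              ids[bad[1]], names(df)[j])
      }
    }
    qstop("descriptor matrix is not numeric")
  }
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    qstop("missing descriptor value at row '%s', column '%s'",
          ids[idx[1]], colnames(X)[idx[2]])
  }
  rownames(X) <- ids
  X
}

read_retention <- function(path) {
  if (!file.exists(path)) qstop("retention file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "condition_id", "tr_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) qstop("retention CSV missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0) qstop("no retention records")
  df$compound_id <- as.character(df$compound_id)
  df$condition_id <- as.character(df$condition_id)
  if (!is.numeric(df$tr_min)) qstop("retention CSV: tr_min is not numeric")
  if (any(!is.finite(df$tr_min) | df$tr_min <= 0)) {
    bad <- which(!is.finite(df$tr_min) | df$tr_min <= 0)[1]
    qstop("retention time must be > 0 (compound '%s', condition '%s')",
          df$compound_id[bad], df$condition_id[bad])
  }
  if (anyDuplicated(df[, c("compound_id", "condition_id")])) {
    qstop("duplicate (compound, condition) retention entry")
  }
  df[, need]
}

read_smiles <- function(path) {
  if (!file.exists(path)) qstop("SMILES file not found: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("compound_id", "smiles"))
  if (anyDuplicated(df$compound_id)) qstop("duplicate compound id in SMILES file")
  df
}

#' Load and validate a complete study
#'
#' Reads the descriptor matrix, the retention table, the experiment-design
#' table and an optional YAML configuration, cross-checks their references
#' and returns a single validated bundle. Compounds present in the retention
#' table but absent from the descriptor matrix are reported on stderr and
#' kept (they still support the experimental retention model); the reverse
#' direction is an error.
#'
#' @param descriptor_csv,retention_csv,conditions_csv input file paths (see
#'   the package README for the column contracts).
#' @param config a `qsrr_config`, or a path to a YAML config file, or `NULL`
#'   for defaults.
#' @param smiles_tsv optional two-column tab-separated file
#'   (`compound_id<TAB>smiles`).
#' @return an object of class `qsrr_study`: a list with `compounds`
#'   (data.frame id/smiles), `conditions`, `descriptors` (numeric matrix),
#'   `retention` (long data.frame) and `config`.
#' @export
load_study <- function(descriptor_csv, retention_csv, conditions_csv,
                       config = NULL, smiles_tsv = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config)) config <- qsrr_config()
  stopifnot(inherits(config, "qsrr_config"))
  descriptors <- read_descriptors(descriptor_csv)
  retention <- read_retention(retention_csv)
  conditions <- read_conditions(conditions_csv)

  comp_ids <- unique(c(rownames(descriptors), retention$compound_id))
  smiles <- rep(NA_character_, length(comp_ids))
  if (!is.null(smiles_tsv)) {
    sm <- read_smiles(smiles_tsv)
    smiles[match(sm$compound_id, comp_ids)] <- sm$smiles
  }
  compounds <- data.frame(id = comp_ids, smiles = smiles,
                          stringsAsFactors = FALSE)

  unknown_cond <- setdiff(retention$condition_id, conditions$condition_id)
  if (length(unknown_cond)) {
    qstop("retention table references unknown condition(s): %s",
          paste(unknown_cond, collapse = ", "))
  }
  no_desc <- setdiff(retention$compound_id, rownames(descriptors))
  if (length(no_desc)) {
    qlog("load", "%d compound(s) have retention data but no descriptors: %s",
         length(no_desc), paste(no_desc, collapse = ", "))
  }
  study <- structure(list(compounds = compounds, conditions = conditions,
                          descriptors = descriptors, retention = retention,
                          config = config),
                     class = "qsrr_study")
  study
}

#' @export
print.qsrr_study <- function(x, ...) {
  cat(sprintf("qsrr_study: %d compounds, %d conditions, %d descriptors, %d retention records\n",
              nrow(x$compounds), nrow(x$conditions), ncol(x$descriptors),
              nrow(x$retention)))
  invisible(x)
}

#' Retention matrix (compounds x conditions)
#'
#' Pivot of the long retention table; missing cells are `NA`.
#'
#' @param study a `qsrr_study`.
#' @return numeric matrix, rows in compound order, columns in condition order.
#' @export
retention_matrix <- function(study) {
  ids <- study$compounds$id
  conds <- study$conditions$condition_id
  M <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(ids, conds))
  M[cbind(match(study$retention$compound_id, ids),
          match(study$retention$condition_id, conds))] <- study$retention$tr_min
  M
}

#' Write a study back to the standard CSV trio
#'
#' Inverse of [load_study()]; the written files round-trip to an identical
#' bundle (full double precision, stable row order).
#'
#' @param study a `qsrr_study`.
#' @param out_dir output directory, created if absent.
#' @return invisibly, the written file paths.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(descriptors = file.path(out_dir, "descriptors.csv"),
             retention = file.path(out_dir, "retention.csv"),
             conditions = file.path(out_dir, "conditions.csv"))
  dd <- data.frame(compound_id = rownames(study$descriptors),
                   study$descriptors, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_canonical(dd, paths["descriptors"])
  write_table_canonical(study$retention, paths["retention"])
  cc <- study$conditions[, c("condition_id", "temperature_c", "tg_min",
                             "pctb_start", "pctb_end")]
  write_table_canonical(cc, paths["conditions"])
  invisible(paths)
}

# Canonical CSV writer: fixed column order as given, 17 significant digits
# for doubles (round-trip exact), no quoting surprises, no row names.
write_table_canonical <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) {
      df2[[j]] <- sprintf("%.17g", df2[[j]])
    }
  }
  write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline results and a checksum manifest
#'
#' Data frames in `results` are written as CSV, everything else as JSON with
#' fixed key order. Two runs on identical inputs produce byte-identical data
#' files. The manifest (`manifest.json`) lists every file with its MD5
#' checksum and size.
#'
#' @param results a named list; each element a data.frame (CSV) or any
#'   JSON-serialisable object.
#' @param out_dir output directory, created if absent.
#' @return data.frame manifest (file, md5, bytes), invisibly written to
#'   `manifest.json` as well.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results))) {
    qstop("results must be a named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) qstop("output directory not writable: %s", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_table_canonical(x, p)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    files <- c(files, p)
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = if (length(files)) unname(tools::md5sum(files)) else character(0),
    bytes = if (length(files)) unname(file.size(files)) else numeric(0),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
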