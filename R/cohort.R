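#' Construct a cohort frequency table
#'
#' The central container of the package: a subjects x variables matrix of
#' percent-of-parent population frequencies with explicit `NA` for missing
#' cells. Variable names are the hierarchical gating labels
#' (e.g. `"B/naive/transitional"`).
#'
#' @param values numeric matrix, subjects in rows, variables in columns.
#'   Row and column names are used as subject ids / variable names unless
#'   given explicitly.
#' @param subject_ids character vector of unique subject ids.
#' @param variable_names character vector of unique variable names.
#' @param provenance free-text provenance string carried through outputs.
#' @param standardized set `TRUE` for transformed (z-scored) tables, which
#'   are allowed negative values; raw frequency tables must be >= 0.
#' @return An object of class `cohort_table` with elements `values`
#'   (named matrix), `subject_ids`, `variable_names`, `provenance`.
#' @export
cohort_table <- function(values, subject_ids = rownames(values),
                         variable_names = colnames(values),
                         provenance = "", standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) stop("subject ids are required")
  if (is.null(variable_names)) stop("variable names are required")
  rownames(values) <- subject_ids
  colnames(values) <- variable_names
  x <- structure(
    list(values = values, subject_ids = as.character(subject_ids),
         variable_names = as.character(variable_names),
         provenance = provenance),
    class = "cohort_table"
  )
  attr(x, "standardized") <- standardized
  validate_cohort(x)
  x
}

#' Validate a cohort table's invariants
#'
#' Checks for duplicate subject ids, duplicate variable names, and
#' negative non-missing frequencies.
#'
#' @param x a `cohort_table`.
#' @return `x`, invisibly, or an error.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  dup <- x$subject_ids[duplicated(x$subject_ids)]
  if (length(dup)) stop("duplicate subject ids: ", paste(unique(dup), collapse = ", "))
  dupv <- x$variable_names[duplicated(x$variable_names)]
  if (length(dupv)) stop("duplicate variable names: ", paste(unique(dupv), collapse = ", "))
  v <- x$values
  if (!isTRUE(attr(x, "standardized")) && any(v < 0, na.rm = TRUE)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop("negative frequency for subject ", rownames(v)[bad[1]],
         ", variable ", colnames(v)[bad[2]])
  }
  invisible(x)
}

#' @export
#' @method print cohort_table
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects x %d variables (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Subset a cohort table by subjects and/or variables
#'
#' @param x a `cohort_table`.
#' @param subjects subject ids (or logical/integer index) to keep.
#' @param variables variable names (or index) to keep.
#' @return A `cohort_table`.
#' @export
subset_cohort <- function(x, subjects = NULL, variables = NULL) {
  v <- x$values
  if (!is.null(subjects)) v <- v[subjects, , drop = FALSE]
  if (!is.null(variables)) v <- v[, variables, drop = FALSE]
  cohort_table(v, provenance = x$provenance,
               standardized = isTRUE(attr(x, "standardized")))
}

.read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
           colClasses = "character")
}

.id_column <- function(df, path) {
  nm <- names(df)
  if ("subject_id" %in% nm) return("subject_id")
  nm[1]
}

#' Validate subject metadata records
#'
#' Enforces the clinical-record invariants: required columns present, ages
#' numeric, groups in \{AD, HC\}, sex in \{M, F\}, spouse linkage symmetric
#' with spouses in opposite groups, and MMSE band only present for AD
#' subjects.
#'
#' @param meta data.frame with columns `subject_id`, `group`, `age`, `sex`
#'   and optional `spouse_id`, `mmse_band`, `apoe_e4`, `ebv_pos`, `cmv_pos`
#'   plus numeric biomarker columns.
#' @return `meta` with typed columns (`mmse_band` as an ordered factor),
#'   invisibly erroring on invariant violations.
#' @export
validate_subjects <- function(meta) {
  req <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing required columns: ", paste(miss, collapse = ", "))
  dup <- meta$subject_id[duplicated(meta$subject_id)]
  if (length(dup)) stop("duplicate subject ids in metadata: ", paste(unique(dup), collapse = ", "))
  if (!all(meta$group %in% c("AD", "HC"))) {
    stop("group must be 'AD' or 'HC'; offending: ",
         paste(unique(setdiff(meta$group, c("AD", "HC"))), collapse = ", "))
  }
  if (!all(meta$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  meta$age <- as.numeric(meta$age)
  if (anyNA(meta$age)) stop("non-numeric or missing age for: ",
                            paste(meta$subject_id[is.na(meta$age)], collapse = ", "))
  if ("spouse_id" %in% names(meta)) {
    sp <- meta$spouse_id
    sp[!is.na(sp) & sp == ""] <- NA
    meta$spouse_id <- sp
    has <- which(!is.na(sp))
    for (i in has) {
      j <- match(sp[i], meta$subject_id)
      if (is.na(j)) stop("spouse id ", sp[i], " of subject ", meta$subject_id[i],
                         " not present in metadata")
      if (is.na(meta$spouse_id[j]) || meta$spouse_id[j] != meta$subject_id[i]) {
        stop("asymmetric spouse linkage between ", meta$subject_id[i],
             " and ", sp[i])
      }
      if (meta$group[i] == meta$group[j]) {
        stop("spouses ", meta$subject_id[i], " and ", sp[i],
             " are in the same group (", meta$group[i], ")")
      }
    }
  }
  if ("mmse_band" %in% names(meta)) {
    mb <- meta$mmse_band
    mb[!is.na(mb) & mb == ""] <- NA
    bad <- !is.na(mb) & meta$group == "HC"
    if (any(bad)) stop("mmse_band present for HC subjects: ",
                       paste(meta$subject_id[bad], collapse = ", "))
    meta$mmse_band <- factor(mb, levels = mmse_bands(), ordered = TRUE)
    if (any(!is.na(mb) & is.na(meta$mmse_band))) {
      stop("unrecognised mmse_band values: ",
           paste(unique(mb[!is.na(mb) & is.na(meta$mmse_band)]), collapse = ", "))
    }
  }
  for (b in c("apoe_e4", "ebv_pos", "cmv_pos")) {
    if (b %in% names(meta)) meta[[b]] <- as.logical(meta[[b]])
  }
  invisible(meta)
}

#' Ordered MMSE band labels
#'
#' Mini-Mental State Examination score bands from best to worst cognition.
#' @return `c("25-30", "20-24", "10-19", "<10")`
#' @export
mmse_bands <- function() c("25-30", "20-24", "10-19", "<10")

#' Read a cohort frequency table and subject metadata
#'
#' Reads CSV or TSV (sniffed from the header line). Missing frequency cells
#' may be empty or `"NA"`. Subjects present in only one of the two files
#' are reported and dropped; non-numeric frequency cells raise an error
#' naming the row and column.
#'
#' @param freq_path path to the frequency table; first column (or a column
#'   named `subject_id`) holds subject ids, remaining columns are variables.
#' @param meta_path path to the metadata table.
#' @return A list with elements `table` (a [cohort_table()]) and `meta`
#'   (a validated metadata data.frame in the same subject order).
#' @export
read_cohort <- function(freq_path, meta_path) {
  if (!file.exists(freq_path)) stop("frequency file not found: ", freq_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  fr <- .read_table_auto(freq_path)
  idc <- .id_column(fr, freq_path)
  ids <- fr[[idc]]
  vals <- fr[setdiff(names(fr), idc)]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, names(vals)))
  for (j in seq_along(vals)) {
    cell <- vals[[j]]
    empty <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("non-numeric frequency '%s' at subject %s, variable %s",
                   cell[i], ids[i], names(vals)[j]))
    }
    m[, j] <- ifelse(empty, NA_real_, num)
  }
  meta <- .read_table_auto(meta_path)
  names(meta)[match(.id_column(meta, meta_path), names(meta))] <- "subject_id"
  # numeric conversion for non-structural columns (biomarkers etc.)
  chr_cols <- c("subject_id", "group", "sex", "spouse_id", "mmse_band")
  lgl_cols <- c("apoe_e4", "ebv_pos", "cmv_pos")
  for (nm in setdiff(names(meta), c(chr_cols, lgl_cols))) {
    meta[[nm]] <- suppressWarnings(as.numeric(meta[[nm]]))
  }
  meta <- validate_subjects(meta)

  only_freq <- setdiff(ids, meta$subject_id)
  only_meta <- setdiff(meta$subject_id, ids)
  if (length(only_freq)) {
    message("dropping ", length(only_freq),
            " subject(s) absent from metadata: ", paste(only_freq, collapse = ", "))
  }
  if (length(only_meta)) {
    message("dropping ", length(only_meta),
            " subject(s) absent from frequency table: ", paste(only_meta, collapse = ", "))
  }
  keep <- intersect(ids, meta$subject_id)
  if (!length(keep)) stop("no subjects shared between frequency table and metadata")
  m <- m[keep, , drop = FALSE]
  meta <- meta[match(keep, meta$subject_id), , drop = FALSE]
  rownames(meta) <- NULL
  # drop dangling spouse links to excluded subjects
  if ("spouse_id" %in% names(meta)) {
    dangling <- !is.na(meta$spouse_id) & !(meta$spouse_id %in% keep)
    if (any(dangling)) {
      message("clearing spouse links to dropped subjects for: ",
              paste(meta$subject_id[dangling], collapse = ", "))
      meta$spouse_id[dangling] <- NA
    }
  }
  list(table = cohort_table(m, provenance = basename(freq_path)), meta = meta)
}

#' Write a cohort table and metadata to disk
#'
#' Missing cells are written as empty strings, the convention accepted by
#' [read_cohort()].
#'
#' @param table a `cohort_table`.
#' @param meta a metadata data.frame (may be `NULL` to skip).
#' @param freq_path,meta_path output file paths; extension `.tsv` selects
#'   tab separation, anything else comma.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(table, meta, freq_path, meta_path = NULL) {
  sep <- if (grepl("\\.tsv$", freq_path)) "\t" else ","
  df <- data.frame(subject_id = table$subject_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, freq_path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  if (!is.null(meta) && !is.null(meta_path)) {
    msep <- if (grepl("\\.tsv$", meta_path)) "\t" else ","
    utils::write.table(meta, meta_path, sep = msep, row.names = FALSE,
                       quote = FALSE, na = "")
  }
  invisible(c(freq_path, meta_path))
}
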