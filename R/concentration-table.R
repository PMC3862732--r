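#' @keywords internal
"_PACKAGE"

META_COLS <- c("patient_id", "compartment", "day")
COMPARTMENTS <- c("BM", "PB")
DAYS <- c(0L, 8L, 29L)
METABOLITE_CLASSES <- c("lipid_metabolism", "amino_acid", "other")

normalize_metabolite_name <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

#' Validate a data frame as a concentration table
#'
#' A concentration table holds one row per sample, keyed by
#' `patient_id`, `compartment` (`"BM"` bone marrow or `"PB"` peripheral
#' blood) and `day` (0, 8 or 29 of induction therapy), followed by one
#' numeric column per metabolite (concentrations in uM). Missing cells are
#' `NA`, never zero: downstream filters count truly nonzero values.
#'
#' Metabolite names are whitespace-normalized; names that collide
#' case-insensitively after normalization are an error, as are duplicate
#' sample keys, negative concentrations, and compartments or days outside
#' the study design.
#'
#' @param df A data frame with the metadata columns named above followed by
#'   metabolite columns.
#' @return The validated table, classed `conc_table`.
#' @export
as_concentration_table <- function(df) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  df <- as.data.frame(df, check.names = FALSE)
  miss <- setdiff(META_COLS, names(df))
  if (length(miss)) {
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  }
  mets <- setdiff(names(df), META_COLS)
  df <- df[c(META_COLS, mets)]
  df$patient_id <- as.character(df$patient_id)
  df$compartment <- as.character(df$compartment)
  bad_comp <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad_comp)) {
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "))
  }
  day <- suppressWarnings(as.integer(df$day))
  if (anyNA(day) || !all(day %in% DAYS)) {
    stop("`day` must be one of ", paste(DAYS, collapse = ", "))
  }
  df$day <- day
  key <- paste(df$patient_id, df$compartment, df$day, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate sample key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  mets_norm <- normalize_metabolite_name(mets)
  if (anyDuplicated(tolower(mets_norm))) {
    dup <- mets_norm[duplicated(tolower(mets_norm))]
    stop("metabolite names collide after normalization: ",
         paste(unique(dup), collapse = ", "))
  }
  names(df) <- c(META_COLS, mets_norm)
  for (m in mets_norm) df[[m]] <- as.numeric(df[[m]])
  if (length(mets_norm)) {
    vals <- as.matrix(df[mets_norm])
    if (any(vals < 0, na.rm = TRUE)) {
      stop("negative concentration(s) found; concentrations must be >= 0")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("conc_table", "data.frame")
  df
}

#' Metabolite names of a concentration table
#' @param x A `conc_table`.
#' @return Character vector of metabolite column names.
#' @export
ct_metabolites <- function(x) {
  setdiff(names(x), META_COLS)
}

#' Extract a samples-by-metabolites matrix from a concentration table
#'
#' @param x A `conc_table`.
#' @param compartment,day Optional filters; `NULL` keeps all samples.
#' @return Numeric matrix; row names are patient ids when the selection is
#'   unique per patient, otherwise `patient/compartment/day` keys.
#' @export
ct_matrix <- function(x, compartment = NULL, day = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(compartment)) keep <- keep & x$compartment %in% compartment
  if (!is.null(day)) keep <- keep & x$day %in% day
  sub <- x[keep, , drop = FALSE]
  m <- as.matrix(sub[ct_metabolites(x)])
  ids <- sub$patient_id
  rownames(m) <- if (anyDuplicated(ids)) {
    paste(ids, sub$compartment, sub$day, sep = "/")
  } else ids
  m
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a concentration table from delimited text
#'
#' Expects a header row naming `patient_id`, `compartment`, `day` and then
#' the metabolites. Empty cells and `"NA"` are read as missing. The
#' delimiter is inferred from the extension (`.csv` comma, otherwise tab)
#' unless given.
#'
#' @param path File path.
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @return A validated `conc_table`.
#' @export
read_concentration_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  as_concentration_table(df)
}

#' Write a concentration table to delimited text
#'
#' Missing values are written as `NA`; the file round-trips through
#' [read_concentration_table()].
#'
#' @param x A `conc_table`.
#' @param path Output path.
#' @param sep Field delimiter; `NULL` to infer from the extension.
#' @export
write_concentration_table <- function(x, path, sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(path)
  utils::write.table(x, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("Concentration table: %d samples x %d metabolites\n",
              nrow(x), length(ct_metabolites(x))))
  tab <- table(x$compartment, x$day)
  print(tab)
  invisible(x)
}

#' Build a metabolite annotation map
#'
#' Maps each metabolite to one of the three classes used for edge
#' classification and enrichment: `lipid_metabolism`, `amino_acid`
#' (amino acids plus derivatives and analogues) or `other`.
#'
#' @param metabolite Character vector of metabolite names.
#' @param class Character vector of class tokens, one per metabolite.
#' @return Named character vector (names = normalized metabolite names).
#' @export
annotation_map <- function(metabolite, class) {
  metabolite <- normalize_metabolite_name(metabolite)
  if (length(metabolite) != length(class)) {
    stop("`metabolite` and `class` lengths differ")
  }
  bad <- setdiff(unique(class), METABOLITE_CLASSES)
  if (length(bad)) {
    stop("unknown class token(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(METABOLITE_CLASSES, collapse = ", "), ")")
  }
  if (anyDuplicated(tolower(metabolite))) {
    stop("duplicate metabolite(s) in annotation: ",
         paste(unique(metabolite[duplicated(tolower(metabolite))]),
               collapse = ", "))
  }
  stats::setNames(as.character(class), metabolite)
}

#' Read an annotation map from a two-column delimited file
#'
#' @param path File with columns `metabolite` and `class`.
#' @param sep Delimiter; `NULL` to infer from the extension.
#' @return Named character vector as from [annotation_map()].
#' @export
read_annotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("metabolite", "class")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  annotation_map(df$metabolite, df$class)
}

#' Write an annotation map
#' @param ann Named character vector from [annotation_map()].
#' @param path Output path.
#' @param sep Delimiter; `NULL` to infer from the extension.
#' @export
write_annotation <- function(ann, path, sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(path)
  utils::write.table(
    data.frame(metabolite = names(ann), class = unname(ann)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that an annotation map covers a metabolite panel
#'
#' Matching is case-insensitive after whitespace normalization. Errors
#' listing every uncovered metabolite; returns the classes aligned to
#' `metabolites` on success.
#'
#' @param ann Annotation map.
#' @param metabolites Character vector of panel metabolite names.
#' @return Character vector of classes, named by `metabolites`.
#' @export
check_annotation <- function(ann, metabolites) {
  metabolites <- normalize_metabolite_name(metabolites)
  idx <- match(tolower(metabolites), tolower(names(ann)))
  if (anyNA(idx)) {
    stop("metabolite(s) missing from annotation map: ",
         paste(metabolites[is.na(idx)], collapse = ", "))
  }
  stats::setNames(unname(ann[idx]), metabolites)
}
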