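# Readers and writers for the plain-text interchange formats: tab-separated
# matrices (probes/probe sets/genes x samples), the 3-column chip-definition
# table, gene lists (one identifier per line) and the clinical CSV.
# All readers validate their structural invariants and fail with a
# descriptive error rather than silently repairing the input.

#' Read a chip-definition table
#'
#' A chip definition maps every probe to one probe set (an exon) and every
#' probe set to one transcript cluster (a gene). The file is tab-separated
#' with a header line `probe_id  probe_set_id  gene_id`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of class `chipdef` with columns `probe_id`,
#'   `probe_set_id`, `gene_id`, in file order.
#' @export
read_chipdef <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  new_chipdef(df, source = path)
}

#' Construct and validate a chip definition
#'
#' @param df Data frame with columns `probe_id`, `probe_set_id`, `gene_id`.
#' @param source Optional label used in error messages.
#' @return A validated `chipdef` tibble.
#' @export
new_chipdef <- function(df, source = "chip definition") {
  need <- c("probe_id", "probe_set_id", "gene_id")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s must have columns %s", source, paste(need, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)[need]
  if (nrow(df) == 0L) abort(sprintf("%s is empty", source))
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) {
    abort(sprintf("duplicate probe_id in %s: %s", source,
                  paste(utils::head(unique(dup), 5), collapse = ", ")))
  }
  genes_per_set <- tapply(df$gene_id, df$probe_set_id,
                          function(g) length(unique(g)))
  bad <- names(genes_per_set)[genes_per_set > 1L]
  if (length(bad)) {
    abort(sprintf("probe set(s) mapped to more than one gene in %s: %s",
                  source, paste(utils::head(bad, 5), collapse = ", ")))
  }
  class(df) <- c("chipdef", class(df))
  df
}

#' Write a chip definition
#' @param chipdef A `chipdef` tibble.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_chipdef <- function(chipdef, path) {
  readr::write_tsv(tibble::as_tibble(unclass(chipdef)), path, progress = FALSE)
  invisible(path)
}

#' Read a probe-level intensity matrix
#'
#' Tab-separated file whose first column holds probe identifiers and whose
#' remaining columns hold one sample each. Intensities must be strictly
#' positive (raw linear scale).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (probes x samples) with identifier dimnames.
#' @export
read_intensity_matrix <- function(path) {
  m <- read_matrix(path)
  if (any(!is.finite(m))) abort(sprintf("non-finite intensity in %s", path))
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-positive intensity at probe %s, sample %s in %s",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  }
  m
}

#' Read a numeric matrix with identifier rows and columns
#'
#' Generic TSV reader used for FIRMA scores and gene-expression matrices:
#' first column = row identifier, remaining columns = samples.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  # columns are read as text and converted with strtod (via as.numeric),
  # which is correctly rounded; this keeps write -> read -> write
  # reproductions bit-identical
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("malformed matrix file %s (e.g. row %d: %s)", path,
                  prob$row[1], prob$expected[1]))
  }
  if (ncol(df) < 2L) abort(sprintf("%s has no sample columns", path))
  if (anyNA(df)) abort(sprintf("ragged or missing entries in %s", path))
  ids <- df[[1]]
  if (anyDuplicated(ids)) abort(sprintf("duplicate row identifiers in %s", path))
  vals <- vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, names(df)[-1]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric value at row %s, column %s in %s",
                  ids[bad[1]], colnames(vals)[bad[2]], path))
  }
  vals
}

#' Write a numeric matrix as TSV
#'
#' The first column (named by `id_col`) carries row identifiers; remaining
#' columns are samples. Values are written with full round-trip precision.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  m <- as_id_matrix(m)
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(df, !!id_col := rownames(m), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with columns `sample_id,time_years,event,stage,msi,age,sex,location`.
#' Follow-up time must be positive; `event` is 1 for a disease-specific
#' death and 0 for a censored observation; stage is II or III; `msi` is
#' 0 (MSS) or 1 (MSI); location is right, left or rectum.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), time_years = readr::col_double(),
    event = readr::col_integer(), stage = readr::col_character(),
    msi = readr::col_integer(), age = readr::col_double(),
    sex = readr::col_character(), location = readr::col_character()
  ), progress = FALSE)
  new_clinical(df, source = path)
}

#' Construct and validate a clinical table
#' @param df Data frame with the clinical columns (see [read_clinical()]).
#' @param source Optional label used in error messages.
#' @return A validated `clinical_table` tibble.
#' @export
new_clinical <- function(df, source = "clinical table") {
  need <- c("sample_id", "time_years", "event", "stage", "msi", "age", "sex",
            "location")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s must have columns %s", source, paste(need, collapse = ",")))
  }
  df <- tibble::as_tibble(df)[need]
  if (anyDuplicated(df$sample_id)) abort(sprintf("duplicate sample_id in %s", source))
  if (any(!is.finite(df$time_years)) || any(df$time_years <= 0)) {
    abort(sprintf("non-positive follow-up time in %s (sample %s)", source,
                  df$sample_id[which(!(df$time_years > 0))[1]]))
  }
  if (!all(df$event %in% c(0L, 1L))) abort(sprintf("event must be 0/1 in %s", source))
  check_levels <- function(x, levels, name) {
    bad <- setdiff(unique(x), levels)
    if (length(bad)) {
      abort(sprintf("unknown %s level in %s: %s", name, source,
                    paste(bad, collapse = ", ")))
    }
  }
  check_levels(df$stage, c("II", "III"), "stage")
  check_levels(df$msi, c(0L, 1L), "msi")
  check_levels(df$sex, c("F", "M"), "sex")
  check_levels(df$location, c("right", "left", "rectum"), "location")
  class(df) <- c("clinical_table", class(df))
  df
}

#' Write a clinical table
#' @param clinical A `clinical_table` tibble.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(tibble::as_tibble(unclass(clinical)), path, progress = FALSE)
  invisible(path)
}

#' Read a gene list
#'
#' One gene identifier per line; blank lines are ignored.
#'
#' @param path Path to a text file.
#' @param universe Optional character vector of known gene identifiers.
#'   Members of the list absent from the universe trigger an error that
#'   names them (they are never silently dropped).
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path, universe = NULL) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) abort(sprintf("gene list %s is empty", path))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate gene identifiers in %s", path))
  }
  if (!is.null(universe)) {
    missing <- setdiff(ids, universe)
    if (length(missing)) {
      abort(sprintf("%d gene(s) in %s absent from the chip definition: %s",
                    length(missing), path,
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  ids
}

#' Write a gene list
#' @param gene_ids Character vector of identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(gene_ids, path) {
  readr::write_lines(gene_ids, path)
  invisible(path)
}

# fixed column order shared by the profile writer/reader
tin_profile_cols <- c("sample_id", "n_skip", "n_incl", "rel_skip", "rel_incl",
                      "rel_total", "skew", "is_sTIN", "is_oTIN")

#' Write per-sample TIN profiles
#'
#' Columns, in fixed order: `sample_id, n_skip, n_incl, rel_skip, rel_incl,
#' rel_total, skew, is_sTIN, is_oTIN`.
#'
#' @param profiles A `tin_profiles` tibble (see [tin_profiles()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_tin_profiles <- function(profiles, path) {
  if (!all(tin_profile_cols %in% names(profiles))) {
    abort("profiles is missing TIN profile columns")
  }
  readr::write_tsv(tibble::as_tibble(unclass(profiles))[tin_profile_cols],
                   path, progress = FALSE)
  invisible(path)
}

#' Read per-sample TIN profiles written by [write_tin_profiles()]
#' @param path Path to a TSV file.
#' @return A `tin_profiles` tibble.
#' @export
read_tin_profiles <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), n_skip = readr::col_integer(),
    n_incl = readr::col_integer(), rel_skip = readr::col_double(),
    rel_incl = readr::col_double(), rel_total = readr::col_double(),
    skew = readr::col_double(), is_sTIN = readr::col_logical(),
    is_oTIN = readr::col_logical()
  ), progress = FALSE)
  class(df) <- c("tin_profiles", class(df))
  df
}

#' Write a gene-correlation table
#'
#' Columns, in fixed order: `gene_id, r, p, significant`.
#'
#' @param correlations A `correlation_table` tibble (see [correlate_genes()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_correlations <- function(correlations, path) {
  cols <- c("gene_id", "r", "p", "significant")
  if (!all(cols %in% names(correlations))) {
    abort("correlations is missing required columns")
  }
  readr::write_tsv(tibble::as_tibble(unclass(correlations))[cols], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a tumor-normal pairing table
#'
#' TSV with header `tumor  normal`, one pair per line.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `tumor` and `normal`.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("tumor", "normal") %in% names(df))) {
    abort(sprintf("%s must have columns `tumor` and `normal`", path))
  }
  tibble::as_tibble(df)[c("tumor", "normal")]
}
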