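# Internal helpers: logging, seeded evaluation, validation utilities.

tin_log <- function(fmt, ...) {
  message(sprintf(paste0("[tinarray] ", fmt), ...))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL runs in the ambient stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

# Coerce to a plain numeric matrix with rownames/colnames, or fail loudly.
as_id_matrix <- function(x, what = "matrix") {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort(sprintf("%s must be numeric", what))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("%s must carry row and column identifiers", what))
  }
  if (anyDuplicated(rownames(m))) abort(sprintf("duplicate row identifiers in %s", what))
  if (anyDuplicated(colnames(m))) abort(sprintf("duplicate column identifiers in %s", what))
  m
}

# Extract the per-sample rel_total vector from a tin_profiles tibble or a
# named numeric, aligned to `sample_ids` when given.
rel_total_vector <- function(x, sample_ids = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "rel_total") %in% names(x))) {
      abort("profiles must contain `sample_id` and `rel_total` columns")
    }
    v <- setNames(x$rel_total, x$sample_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    v <- x
  } else {
    abort("expected a tin_profiles data frame or a named numeric vector")
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(v))
    if (length(missing)) {
      abort(sprintf("no deviation profile for sample(s): %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    v <- v[sample_ids]
  }
  v
}
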