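# Internal helpers shared across modules.

# Convert a wide counts tibble (feature column + one column per sample)
# to an integer matrix with feature rownames. Validates as it goes.
counts_to_matrix <- function(counts, feature_col = "feature") {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame with a feature column.")
  }
  if (!feature_col %in% names(counts)) {
    abort(sprintf("`counts` must contain a '%s' column.", feature_col))
  }
  feats <- as.character(counts[[feature_col]])
  if (anyDuplicated(feats)) {
    dups <- unique(feats[duplicated(feats)])
    abort(sprintf("Duplicate feature ids: %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  m <- as.matrix(counts[setdiff(names(counts), feature_col)])
  if (!is.numeric(m)) abort("Count columns must be numeric.")
  rownames(m) <- feats
  m
}

matrix_to_counts <- function(m, feature_col = "feature") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!feature_col := rownames(m)), out)
  out
}

# Validate a counts tibble against its sample table; returns the matrix.
validate_counts <- function(counts, samples = NULL) {
  m <- counts_to_matrix(counts)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    abort(sprintf(
      "Counts must be finite non-negative integers; offending entry: feature '%s', sample '%s' (value %s).",
      rownames(m)[i[1]], colnames(m)[i[2]], format(m[i[1], i[2]])))
  }
  if (!is.null(samples)) {
    req <- c("sample_id", "strain", "tissue", "age_months", "sex")
    miss_col <- setdiff(req, names(samples))
    if (length(miss_col) > 0) {
      abort(sprintf("Sample table missing columns: %s",
                    paste(miss_col, collapse = ", ")))
    }
    if (anyDuplicated(samples$sample_id)) {
      abort("Sample table has duplicated sample_id values.")
    }
    missing <- setdiff(colnames(m), samples$sample_id)
    extra <- setdiff(samples$sample_id, colnames(m))
    if (length(missing) > 0) {
      abort(sprintf("Samples in counts but absent from metadata: %s",
                    paste(missing, collapse = ", ")))
    }
    if (length(extra) > 0) {
      abort(sprintf("Samples in metadata but absent from counts: %s",
                    paste(extra, collapse = ", ")))
    }
    if (any(!is.finite(samples$age_months) | samples$age_months <= 0)) {
      abort("age_months must be positive and finite for every sample.")
    }
  }
  m
}

# Replace top-level entries wholesale (unlike modifyList, which merges
# nested lists element-wise).
shallow_modify <- function(defaults, user) {
  if (length(user) == 0) return(defaults)
  defaults[names(user)] <- user
  defaults
}

# Deterministic child seeds derived from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000L * seq_len(n)) %% .Machine$integer.max
}

# Run code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stratum_label <- function(strain, tissue) paste(strain, tissue, sep = ":")
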