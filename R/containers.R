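# Lightweight containers for count/expression matrices and usage profiles.
# Samples are identified as "<tissue>.<stage>.rep<k>"; stage order is always
# supplied explicitly (configuration), never inferred from lexical sort,
# because developmental labels such as E15.5 and P0.5 do not sort as text.

sample_id <- function(tissue, stage, replicate) {
  paste0(tissue, ".", stage, ".rep", replicate)
}

parse_sample_id <- function(ids) {
  m <- regmatches(ids, regexec("^([^.]+)\\.(.+)\\.rep([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stopf("malformed sample id(s): %s (expected tissue.stage.repN)",
          paste(ids[bad], collapse = ", "))
  }
  data.frame(
    sample_id = ids,
    tissue    = vapply(m, `[`, character(1), 2L),
    stage     = vapply(m, `[`, character(1), 3L),
    replicate = as.integer(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a count matrix with sample metadata
#'
#' A genes x samples matrix of non-negative integer counts together with the
#' (tissue, stage, replicate) design and the ordered list of developmental
#' stages. Column names must follow the `tissue.stage.repN` convention.
#'
#' @param counts integer matrix, rows = genes (rownames required), columns =
#'   samples (colnames `tissue.stage.repN`).
#' @param stages character vector giving the developmental stage order; must
#'   cover every stage present in the columns.
#' @return An object of class `count_matrix`: list with `counts`, `samples`
#'   (data.frame sample_id/tissue/stage/replicate) and `stages`.
#' @export
count_matrix <- function(counts, stages) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  if (!is_count_vector(as.vector(counts))) {
    stopf("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  samples <- parse_sample_id(colnames(counts))
  missing_stage <- setdiff(samples$stage, stages)
  if (length(missing_stage) > 0) {
    stopf("stage(s) %s not in the supplied stage order",
          paste(missing_stage, collapse = ", "))
  }
  structure(list(counts = counts, samples = samples, stages = stages),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      length(unique(x$samples$tissue)), "tissues,",
      length(x$stages), "stages )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

expression_matrix <- function(values, samples, stages, size_factors) {
  structure(list(values = values, samples = samples, stages = stages,
                 size_factors = size_factors),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; size factors in [",
      round(min(x$size_factors), 3), ",", round(max(x$size_factors), 3), "]\n")
  invisible(x)
}

#' Construct a usage profile
#'
#' A keyed non-negative vector of codon, amino-acid, anticodon-family or
#' isotype usage. Normalized profiles sum to 1 (tolerance 1e-9).
#'
#' @param values named non-negative numeric vector.
#' @param kind one of `"codon"`, `"amino_acid"`, `"anticodon"`, `"isotype"`.
#' @param normalized logical; if `TRUE` the values are checked to sum to 1.
#' @return An object of class `usage_profile`.
#' @export
usage_profile <- function(values,
                          kind = c("codon", "amino_acid", "anticodon", "isotype"),
                          normalized = FALSE) {
  kind <- match.arg(kind)
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stopf("usage profile values must have unique names")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("usage profile values must be finite and non-negative")
  }
  if (normalized && abs(sum(values) - 1) > 1e-9) {
    stopf("normalized profile must sum to 1 (got %.12f)", sum(values))
  }
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  cat("usage_profile (", x$kind, if (x$normalized) ", normalized" else "",
      "): ", length(x$values), " keys, total ", format(sum(x$values)),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.usage_profile <- function(x, ...) x$values
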