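# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so seeded helpers do not perturb the
#' surrounding random stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Reverse complement of DNA strings (vectorised, base alphabet only).
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# One-letter -> three-letter amino-acid codes (tRNA isotype notation).
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  U = "SeC"
)
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
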