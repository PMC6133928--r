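#' @useDynLib ionpairdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Physical constants in the package's internal units (nm, ps, kJ/mol, e, K).
# f_C = e^2 N_A / (4 pi eps0 1e-9 m), frozen so the reference Coulomb curve
# is bit-stable; kB in kJ mol^-1 K^-1 (CODATA 2018 exact).
.const <- list(
  coulomb = 138.935458,        # kJ mol^-1 nm e^-2
  kB      = 0.008314462618,    # kJ mol^-1 K^-1
  avogadro = 6.02214076e23     # mol^-1
)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route through this, which makes them pure functions of
# their spec (seed included).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage sub-seed derived from a master seed, kept below
# 2^31. Stage names are hashed by character codes so the derivation is
# documented and stable.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  invisible(x)
}

#' Write a data frame as deterministic TSV
#'
#' Fixed-format writer used for all tabular pipeline outputs: numeric
#' columns are formatted with a fixed significant-digit count, so
#' identical inputs always produce byte-identical files (the property the
#' reproducibility checks rely on).
#'
#' @param df data.frame.
#' @param path output path.
#' @param digits significant digits (default 10).
#' @return `path`, invisibly.
#' @export
write_tsv_fixed <- function(df, path, digits = 10) {
  out <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = digits, format = "g") else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
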