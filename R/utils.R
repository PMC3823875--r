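# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state so package functions never
# disturb (or depend on) the caller's global seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds, kept below 2^31 so they are valid R integers.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetry check used by similarity-matrix validators.
max_asymmetry <- function(m) {
  if (nrow(m) != ncol(m)) return(Inf)
  max(abs(m - t(m)))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# A pair list is a data.frame with character columns drug, disease.
pair_frame <- function(drug, disease) {
  data.frame(drug = as.character(drug), disease = as.character(disease),
             stringsAsFactors = FALSE)
}

pair_key <- function(pairs) paste(pairs$drug, pairs$disease, sep = "\r")
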