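#' Sleep stage vocabulary
#'
#' The five AASM sleep stages used throughout the package, in fixed order.
#' Stage codes are the zero-based positions in this vector: W=0, N1=1, N2=2,
#' N3=3, REM=4. The mapping is stable across generation, modelling,
#' serialization and evaluation.
#'
#' @return Character vector `c("W","N1","N2","N3","REM")`.
#' @export
stageLevels <- function() c("W", "N1", "N2", "N3", "REM")

#' Convert stage labels to integer codes and back
#'
#' @param x character vector of stage labels, or a factor.
#' @return `stageCodes`: integer vector (W=0 ... REM=4).
#' @export
stageCodes <- function(x) {
  f <- stageFactor(x)
  as.integer(f) - 1L
}

#' @rdname stageCodes
#' @param codes integer vector of stage codes in 0..4.
#' @return `stageFromCodes`: factor with the five stage levels.
#' @export
stageFromCodes <- function(codes) {
  codes <- as.integer(codes)
  if (any(is.na(codes)) || any(codes < 0L | codes > 4L))
    stop("stage codes must be integers in 0..4")
  factor(stageLevels()[codes + 1L], levels = stageLevels())
}

#' @rdname stageCodes
#' @export
stageFactor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- !(x %in% stageLevels())
  if (any(bad))
    stop("unknown stage label(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = stageLevels())
}

# Deterministic seed splitting. All randomness in the package flows through
# seeds derived from one user seed with this scheme, so a whole experiment
# is reproducible from (config, seed). Values stay below 2^31 - 1.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629  # largest prime < 2^31
  s <- as.double(seed %% m)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 104729 + 1) %% m
  }
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
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
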