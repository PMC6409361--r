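#' @keywords internal
"_PACKAGE"

# status labels used throughout: "abnormal" is the positive class
# (CSF amyloid-beta 1-42 below the clinical threshold)
.status_levels <- c("normal", "abnormal")

status_factor <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "abnormal", "normal")
  factor(as.character(x), levels = .status_levels)
}

#' Derive a deterministic child seed
#'
#' Combines a base seed with an arbitrary set of stage labels (strings or
#' integers) into a new seed in `[1, 2^31 - 2]`. Used so that every random
#' draw in the pipeline descends from one global seed and adding a stage
#' never perturbs the draws of earlier stages.
#'
#' @param base integer base seed.
#' @param ... stage labels (character or integer scalars).
#' @return an integer seed.
#' @export
derive_seed <- function(base, ...) {
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(base) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(part) else as.numeric(part)
    for (cc in codes) h <- (h * 48271 + cc + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# evaluate an expression with a private RNG stream, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single fraction in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(x)
}
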