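# Internal helpers shared across modules.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Sex factor with female as the reference level, as in the growth models.
sex_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("F", "M"))
  if (length(bad) > 0) {
    stop("sex must be coded 'F' or 'M'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = c("F", "M"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be strictly positive and finite.", call. = FALSE)
  }
  invisible(x)
}
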