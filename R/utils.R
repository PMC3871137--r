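# internal helpers shared across modules

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("`%s` must be a single number", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("`%s` must be an integer count", name)
  invisible(as.integer(x))
}

# Pearson correlation that flags the degenerate constant-vector case instead
# of raising; returns NA_real_ with attribute "undefined" = TRUE.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(x, y)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
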