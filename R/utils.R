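# Internal helpers: seed management and input checks.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed fan-out from one pipeline seed. Offsets are
# small fixed integers per stage; results stay inside the 32-bit range.
stage_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 104729) * 19993 + as.numeric(offset) * 127) %% 2147483562 + 1
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number, got %s", name, x), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_binary_labels <- function(y) {
  if (!all(y %in% c(0, 1))) {
    stop("labels must be binary with case = 1 and control = 0", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; both cases and controls are required",
         call. = FALSE)
  }
  as.integer(y)
}

check_finite_matrix <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(X)
}

# Ensure a feature matrix carries usable column names.
feature_names <- function(X) {
  if (is.null(colnames(X))) sprintf("f%03d", seq_len(ncol(X))) else colnames(X)
}
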