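#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across count rename pull distinct slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @keywords internal
"_PACKAGE"

# Derive a reproducible integer substream seed (< 2^31) from a base seed and a
# string tag. Substreams keep tissue-level determinism independent of the order
# in which zones/stages/modalities are simulated.
rz_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_substream <- function(seed, expr) {
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
  force(expr)
}

# Zone labels used throughout: class I ORs are their own category ("I"),
# class II ORs carry integer zones 1..5 stored as character for labelling.
zone_levels <- function(include_class_i = TRUE) {
  if (include_class_i) c("I", "1", "2", "3", "4", "5") else as.character(1:5)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
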