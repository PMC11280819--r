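# Internal helpers shared across modules.

abort_if <- function(cond, msg, class = "aquarisk_error") {
  if (cond) rlang::abort(msg, class = class)
  invisible(NULL)
}

# Population (divide-by-N) variance; the geodetector q is defined with it.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Derive a child seed from a global seed and a stage label
#'
#' One global seed fans out deterministically to per-stage seeds, so toggling
#' one pipeline stage never perturbs another stage's random stream. The rule
#' hashes the stage label into an offset below 2^31.
#'
#' @param seed Non-negative integer global seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
#' @examples
#' child_seed(1, "hra")
child_seed <- function(seed, stage) {
  abort_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0,
           "`seed` must be a single non-negative number.")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  abort_if(length(missing) > 0,
           paste0("Missing column(s) in ", what, ": ",
                  paste(missing, collapse = ", ")),
           class = "aquarisk_missing_column")
  invisible(df)
}

`%||%` <- rlang::`%||%`
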