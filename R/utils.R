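#' Evaluate an expression under a local random seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded internals (Monte-Carlo overlap, cohort simulation) never
#' perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(
    class = c("tonellipse_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_invalid(...)
  invisible(TRUE)
}

hz_to_semitone <- function(f0, ref) 12 * log2(f0 / ref)
semitone_to_hz <- function(st, ref) ref * 2^(st / 12)

#' Tone contrast labels
#'
#' The six unordered Mandarin tone pairs, in canonical order.
#' @return character vector `c("1v2","1v3","1v4","2v3","2v4","3v4")`.
#' @export
tone_contrasts <- function() {
  c("1v2", "1v3", "1v4", "2v3", "2v4", "3v4")
}

contrast_tones <- function(contrast) {
  as.integer(strsplit(contrast, "v", fixed = TRUE)[[1]])
}
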