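#' Round half away from zero
#'
#' Commercial ("round half up") rounding used for all table-style reports,
#' so that e.g. 0.375 prints as 0.38 regardless of the platform's
#' banker's-rounding behaviour.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards so seeded package
#' functions do not perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Polynomial rolling hash of a character scalar; used only to stamp
# configs into run logs for provenance, not for security.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("snpbarcode_undefined", "error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("snpbarcode_validation", "error")))
}
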