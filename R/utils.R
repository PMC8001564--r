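#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component-specific seed from a root seed
#'
#' Deterministic stream splitting: every stochastic component draws its own
#' seed from the run's root seed plus a label, so adding a new generator never
#' perturbs the draws of existing ones. The hash is a 31-bit polynomial
#' rolling hash, exact in double arithmetic.
#'
#' @param seed integer root seed.
#' @param stream character label of the consuming component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483629 # largest prime < 2^31 keeps h * 31 exact in doubles
  h <- 17
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m + h) %% m)
}

# 31-bit rolling hash of a deparsed R object; provenance fingerprint only,
# not cryptographic.
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  m <- 2147483629
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% m
  sprintf("%08x", h)
}

stop_mrkit <- function(msg, class) {
  stop(structure(class = c(class, "mrkit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
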