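#' @importFrom stats approx dnorm lm coef rnorm rgamma rpois runif setNames
#' @importFrom utils read.csv write.csv packageVersion head
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# Deterministic fingerprint of a run configuration (polynomial rolling hash),
# embedded in output file headers so runs can be matched to their settings.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(cfg = NULL) {
  ver <- as.character(utils::packageVersion("venomcomp"))
  if (is.null(cfg)) {
    sprintf("# venomcomp %s", ver)
  } else {
    sprintf("# venomcomp %s config=%s", ver, config_hash(cfg))
  }
}

# Full-precision decimal rendering that survives a write/read round trip.
num_chr <- function(x) sprintf("%.17g", x)

stop_venomcomp <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "venomcomp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
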