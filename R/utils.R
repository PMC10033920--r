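#' Structured error conditions
#'
#' All errors raised by the package carry a condition class of the form
#' `dicomslide_<kind>` (plus the generic classes) so callers can handle
#' specific failure modes programmatically.
#'
#' @param class Condition subclass, e.g. "missing_attribute".
#' @param message Human-readable message.
#' @param ... Extra fields attached to the condition.
#' @keywords internal
dcmCondition <- function(class, message, ...) {
  structure(
    class = c(paste0("dicomslide_", class), "dicomslide_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

dcmStop <- function(class, fmt, ...) {
  stop(dcmCondition(class, sprintf(fmt, ...)))
}

dcmWarn <- function(class, fmt, ...) {
  warning(structure(
    class = c(paste0("dicomslide_", class), "dicomslide_warning",
              "warning", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

dcmNotice <- function(fmt, ...) {
  message(sprintf(paste0("[dicomslide] ", fmt), ...))
}

#' Round half away from zero
#'
#' Display-pipeline quantization (palette indexing, alpha compositing)
#' rounds halves away from zero rather than to even, so that 0.5 maps
#' up for non-negative display values.
#'
#' @param x Numeric vector or array.
#' @return Rounded values, same shape as `x`.
#' @export
roundHalfAway <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Seeded UID factory
#'
#' Returns a generator of DICOM-conformant unique identifiers under a
#' fixed numeric root. Successive calls yield distinct UIDs; the whole
#' stream is a pure function of `seed`, which is what makes fixture
#' generation byte-reproducible. With `seed = NULL` the stream is
#' drawn from the time and process id (production use).
#'
#' @param seed Integer seed, or `NULL` for non-reproducible UIDs.
#' @return A function that returns one new UID string per call.
#' @examples
#' f <- uidFactory(1)
#' f(); f()
#' @export
uidFactory <- function(seed = NULL) {
  if (is.null(seed)) {
    seed <- (as.numeric(Sys.time()) * 1000 + Sys.getpid()) %% 2147483563
  }
  state <- as.double((abs(as.double(seed)) %% 2147483562) + 1)
  counter <- 0L
  function() {
    # Lehmer generator, modulus 2^31-69; deterministic in `seed`
    state <<- (state * 40014) %% 2147483563
    counter <<- counter + 1L
    sprintf("1.2.826.0.1.3680043.10.1081.%.0f.%d", state, counter)
  }
}

# Evaluate `expr` with the base RNG temporarily seeded; restores any
# pre-existing RNG state so fixture generation never perturbs user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pack non-negative (or two's-complement signed) integers little-endian.
packIntLE <- function(values, size, signed = FALSE) {
  v <- as.double(values)
  if (signed) v <- ifelse(v < 0, v + 2^(8 * size), v)
  if (any(v < 0 | v >= 2^(8 * size)))
    dcmStop("value_range", "integer value out of range for %d-byte field", size)
  out <- raw(length(v) * size)
  for (i in seq_len(size)) {
    out[seq(i, length(out), by = size)] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

unpackIntLE <- function(bytes, size, signed = FALSE) {
  n <- length(bytes) %/% size
  if (n == 0L) return(integer(0))
  m <- matrix(as.double(as.integer(bytes[seq_len(n * size)])),
              nrow = size)
  v <- as.vector(2^(8 * (seq_len(size) - 1)) %*% m)
  if (signed) v <- ifelse(v >= 2^(8 * size - 1), v - 2^(8 * size), v)
  v
}
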