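# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' `.Random.seed`, so seeded operations (subsampling, simulation) do not
#' perturb the session RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
.withSeed <- function(seed, code) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(as.integer(seed))
    code
}

# Derive a stream-specific seed from a master seed, kept inside 32-bit range.
.deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483629)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be > 0", name), call. = FALSE)
    invisible(x)
}

.readTsv <- function(path, ...) {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
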