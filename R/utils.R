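# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils read.delim write.table
.readTsv <- function(path) {
  if (!file.exists(path)) {
    csStop("io_error", sprintf("file not found: '%s'", path))
  }
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# Classed conditions so callers can distinguish user errors from internal ones.
csStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "comboscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

csWarn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Derive named independent sub-seeds from one master seed so each random
# component (guide efficiency, pDNA representation, per-replicate counts, ...)
# has its own reproducible stream. Seeds stay within 32-bit integer range.
deriveSeeds <- function(seed, names) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- sample.int(.Machine$integer.max - 1L, length(names))
  names(out) <- names
  out
}

# Grouped sums over a numeric vector; returns named vector over group levels.
.groupSum <- function(x, g) {
  rowsum(x, g, reorder = FALSE)[, 1L]
}
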