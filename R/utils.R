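`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-task seed stream derived from a master seed.
# Keeps every derived seed inside the 32-bit signed range so the same
# streams come out of serial and parallel execution.
deriveSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 104729
  as.integer(s %% 2147483629 + 1)
}

# qc counter bookkeeping on the KinomeSignal@qc list
bumpQc <- function(ds, field, by) {
  ds@qc[[field]] <- as.integer((ds@qc[[field]] %||% 0L) + by)
  ds
}

recordThreshold <- function(ds, ...) {
  ds@qc$thresholds <- utils::modifyList(ds@qc$thresholds %||% list(),
                                        list(...))
  ds
}

stopIfEmpty <- function(ds, context) {
  if (nrow(ds@records) == 0L)
    stop("no signal records remain after ", context, call. = FALSE)
  invisible(ds)
}

writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
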