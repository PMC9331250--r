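# Internal helpers: classed error conditions, seed fan-out, TSV I/O.

.err <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("crossGRN_", class), "crossGRN_error")))
}

# One user-facing seed, fanned out to independent stage substreams.
# Offsets are fixed primes so stages never share a stream; result kept
# strictly below 2^31 so it is a valid R integer seed.
.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 104729L, simulate2 = 1299709L, deg = 15485863L,
               grn = 32452843L, null = 49979687L, noise = 67867967L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path) {
  if (!file.exists(path)) .err("missing_file", "file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.writeMatrixTsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  .writeTsv(df, path)
}

.readMatrixTsv <- function(path) {
  df <- .readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
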